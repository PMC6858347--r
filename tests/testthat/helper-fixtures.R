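# Small in-code fixtures shared by the module tests.

tiny_expression <- function() {
  m <- matrix(c(1, 2, 3, 4,
                2, 2, 2, 2,
                5, 4, 3, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"),
                              c("s1", "s2", "s3", "s4")))
  m
}

tiny_alterations <- function(samples = c("s1", "s2", "s3", "s4")) {
  status <- matrix(c(1L, 0L, 1L, 0L,
                     0L, 0L, 1L, 1L), nrow = 2, byrow = TRUE,
                   dimnames = list(c("amp1", "del1"), samples))
  alteration_set(
    tibble::tibble(alt_id = c("amp1", "del1"),
                   direction = c("amplification", "deletion")),
    status,
    list(amp1 = c("gA"), del1 = c("gB"))
  )
}

# A compact planted study used where full-size simulation would be slow.
small_study <- function(seed = 1, ...) {
  generate_synthetic_study(
    n_samples = 120, n_alterations = 1, cis_per_alt = 4, trans_per_alt = 12,
    n_background = 30, seed = seed, ...
  )
}

write_tiny_expression_tsv <- function(path) {
  writeLines(c(
    "gene_id\ts1\ts2\ts3\ts4",
    "gA\t1\t2\t3\t4",
    "gB\t2\t2\t2\t2",
    "gC\t5\t4\t3\t2"
  ), path)
  path
}
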