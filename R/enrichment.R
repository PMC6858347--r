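#' Hypergeometric over-representation test of a signature in a gene set
#'
#' Upper-tail hypergeometric probability of seeing at least the observed
#' overlap between a signature and a gene set drawn from a finite universe.
#' Genes outside the universe are dropped with a warning.
#'
#' @param signature Character vector of signature genes.
#' @param geneset Character vector of gene-set members.
#' @param universe Character vector: the expressed-gene universe.
#' @return One-row tibble: `overlap`, `signature_size`, `set_size`,
#'   `universe_size`, `p`.
#' @export
hypergeom_enrich <- function(signature, geneset, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  sig_out <- setdiff(signature, universe)
  set_out <- setdiff(geneset, universe)
  if (length(sig_out) || length(set_out)) {
    warning(length(sig_out) + length(set_out),
            " gene(s) outside the universe dropped", call. = FALSE)
  }
  signature <- intersect(unique(signature), universe)
  geneset <- intersect(unique(geneset), universe)
  k <- length(intersect(signature, geneset))
  tibble::tibble(
    overlap = k,
    signature_size = length(signature),
    set_size = length(geneset),
    universe_size = length(universe),
    p = stats::phyper(k - 1L, length(geneset),
                      length(universe) - length(geneset),
                      length(signature), lower.tail = FALSE)
  )
}

#' Enrichment of alteration signatures in a gene-set collection
#'
#' Tests each alteration's significant-gene signature against every set of a
#' collection, with BH-FDR across all (alteration, set) pairs. With
#' `mode = "union"` the signature is the union of the cis and trans
#' significant genes (the default reporting mode); `"separate"` tests the
#' cis and trans signatures individually.
#'
#' @param signatures Named list (by `alt_id`) with elements `cis` and
#'   `trans`, each a character vector of significant genes.
#' @param collection Named list of gene sets, e.g. from [read_gmt()].
#' @param universe Expressed-gene universe.
#' @param mode `"union"` or `"separate"`.
#' @param report_fdr_max Reporting cutoff stored in the `significant` column
#'   (default 0.25).
#' @return Tibble: `alt_id`, `signature` (union/cis/trans), `set_name`,
#'   overlap and size columns, `p`, `fdr`, `significant`.
#' @export
enrich_signatures <- function(signatures, collection, universe,
                              mode = c("union", "separate"),
                              report_fdr_max = 0.25) {
  mode <- match.arg(mode)
  per_alt <- purrr::imap(signatures, function(sig, alt) {
    parts <- if (mode == "union") {
      list(union = union(sig$cis, sig$trans))
    } else {
      list(cis = sig$cis, trans = sig$trans)
    }
    purrr::imap_dfr(parts, function(genes, label) {
      rows <- purrr::imap_dfr(collection, function(set, set_name) {
        res <- suppressWarnings(hypergeom_enrich(genes, set, universe))
        dplyr::mutate(res, set_name = set_name, .before = 1L)
      })
      if (!length(genes)) rows$p <- 1
      dplyr::mutate(rows, alt_id = alt, signature = label, .before = 1L)
    })
  })
  out <- dplyr::bind_rows(per_alt)
  out$fdr <- bh_fdr(out$p)
  out$significant <- out$fdr < report_fdr_max
  out
}

fisher_one_sided <- function(tab) {
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Subtype-specific alterations
#'
#' One-sided Fisher exact test of each alteration's occurrence inside versus
#' outside each sample subtype, FDR-adjusted across all (alteration,
#' subtype) pairs; an alteration is subtype-specific at `fdr < fdr_max`.
#'
#' @param alts An `alteration_set`.
#' @param labels Named character vector of subtype labels, names = sample
#'   identifiers covering all samples of `alts`.
#' @param fdr_max Specificity cutoff (default 0.05).
#' @return Tibble: `alt_id`, `subtype`, the 2x2 counts
#'   (`altered_in`, `altered_out`, `unaltered_in`, `unaltered_out`), `p`,
#'   `fdr`, `specific`, `degenerate`.
#' @export
subtype_specific_alterations <- function(alts, labels, fdr_max = 0.05) {
  missing <- setdiff(alts$sample_ids, names(labels))
  if (length(missing)) {
    stop("unlabeled sample(s): ", paste(utils::head(missing, 5L),
                                        collapse = ", "), call. = FALSE)
  }
  labels <- labels[alts$sample_ids]
  subtypes <- sort(unique(labels))
  degenerate_all <- length(subtypes) < 2L
  grid <- tidyr::expand_grid(alt_id = alts$info$alt_id, subtype = subtypes)
  out <- purrr::pmap_dfr(grid, function(alt_id, subtype) {
    st <- alts$status[alt_id, ]
    inside <- labels == subtype
    tab <- matrix(c(sum(st == 1 & inside), sum(st == 1 & !inside),
                    sum(st == 0 & inside), sum(st == 0 & !inside)),
                  nrow = 2L, byrow = TRUE)
    degen <- degenerate_all || all(st == st[1L])
    tibble::tibble(
      alt_id = alt_id, subtype = subtype,
      altered_in = tab[1, 1], altered_out = tab[1, 2],
      unaltered_in = tab[2, 1], unaltered_out = tab[2, 2],
      p = if (degen) NA_real_ else fisher_one_sided(tab),
      degenerate = degen
    )
  })
  out$fdr <- bh_fdr(out$p[!out$degenerate]) |>
    (\(adj) replace(rep(NA_real_, nrow(out)), !out$degenerate, adj))()
  out$specific <- !is.na(out$fdr) & out$fdr < fdr_max
  out
}

#' Subtype-specific pathway enrichments
#'
#' Cross-tabulates, per (pathway, subtype), how many alterations are
#' pathway-enriched versus subtype-specific and applies a one-sided Fisher
#' exact test, FDR-adjusted over all pairs.
#'
#' @param enrichments Output of [enrich_signatures()] (uses `significant`).
#' @param subtype_assoc Output of [subtype_specific_alterations()] (uses
#'   `specific`).
#' @param fdr_max Cutoff for the reported `significant` flag (default 0.05).
#' @return Tibble: `set_name`, `subtype`, 2x2 counts, `p`, `fdr`,
#'   `significant`.
#' @export
subtype_specific_pathways <- function(enrichments, subtype_assoc,
                                      fdr_max = 0.05) {
  alt_ids <- sort(unique(subtype_assoc$alt_id))
  stopifnot(setequal(alt_ids, unique(enrichments$alt_id)))
  enriched_by_set <- enrichments |>
    dplyr::group_by(.data$set_name, .data$alt_id) |>
    dplyr::summarise(enriched = any(.data$significant), .groups = "drop")
  specific_by_subtype <- subtype_assoc |>
    dplyr::group_by(.data$subtype, .data$alt_id) |>
    dplyr::summarise(specific = any(.data$specific), .groups = "drop")
  sets <- sort(unique(enriched_by_set$set_name))
  subtypes <- sort(unique(specific_by_subtype$subtype))
  enr_mat <- matrix(FALSE, length(sets), length(alt_ids),
                    dimnames = list(sets, alt_ids))
  enr_mat[cbind(enriched_by_set$set_name, enriched_by_set$alt_id)] <-
    enriched_by_set$enriched
  spc_mat <- matrix(FALSE, length(subtypes), length(alt_ids),
                    dimnames = list(subtypes, alt_ids))
  spc_mat[cbind(specific_by_subtype$subtype, specific_by_subtype$alt_id)] <-
    specific_by_subtype$specific
  grid <- tidyr::expand_grid(set_name = sets, subtype = subtypes)
  out <- purrr::pmap_dfr(grid, function(set_name, subtype) {
    enr <- enr_mat[set_name, ]
    spc <- spc_mat[subtype, ]
    tab <- matrix(c(sum(enr & spc), sum(enr & !spc),
                    sum(!enr & spc), sum(!enr & !spc)), nrow = 2L,
                  byrow = TRUE)
    tibble::tibble(
      set_name = set_name, subtype = subtype,
      enriched_specific = tab[1, 1], enriched_other = tab[1, 2],
      not_enriched_specific = tab[2, 1], not_enriched_other = tab[2, 2],
      p = fisher_one_sided(tab)
    )
  })
  out$fdr <- bh_fdr(out$p)
  out$significant <- out$fdr < fdr_max
  out
}
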