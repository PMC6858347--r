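#' Enrichment of Rank-1 cis genes in a driver reference
#'
#' One-sided Fisher exact test of the over-representation of known drivers
#' among Rank-1 versus non-Rank-1 cis genes, conditional on the direction of
#' change: `"OG"` restricts to amplification cis genes versus the oncogene
#' list, `"TN"` to deletion cis genes versus tumor suppressors,
#' `"COMBINED"` takes the union of both restricted comparisons' driver
#' lists on the full universe, and `"ANY"` ignores class entirely.
#'
#' @param rank1 Character vector of Rank-1 cis genes.
#' @param cis_universe All significant cis genes of the run. A gene that is
#'   Rank-1 in any alteration counts as Rank-1.
#' @param reference Driver reference tibble (`gene`, `class`, `source`), as
#'   from [read_driver_reference()].
#' @param direction One of `"OG"`, `"TN"`, `"COMBINED"`, `"ANY"`.
#' @param amp_genes,del_genes Cis genes of amplifications / deletions; used
#'   by the direction-restricted modes (default: the whole universe).
#' @return One-row tibble with the 2x2 counts, `p` and the mode label.
#' @export
driver_enrichment <- function(rank1, cis_universe, reference,
                              direction = c("ANY", "OG", "TN", "COMBINED"),
                              amp_genes = cis_universe,
                              del_genes = cis_universe) {
  direction <- match.arg(direction)
  stopifnot(all(rank1 %in% cis_universe))
  universe <- switch(direction,
    OG = intersect(cis_universe, amp_genes),
    TN = intersect(cis_universe, del_genes),
    cis_universe
  )
  drivers <- switch(direction,
    OG = reference$gene[reference$class == "oncogene"],
    TN = reference$gene[reference$class == "tumor_suppressor"],
    unique(reference$gene)
  )
  if (!length(universe) || !length(drivers)) {
    return(tibble::tibble(direction = direction, rank1_driver = NA_integer_,
                          rank1_other = NA_integer_,
                          nonrank1_driver = NA_integer_,
                          nonrank1_other = NA_integer_, p = NA_real_,
                          degenerate = TRUE))
  }
  r1 <- universe %in% rank1
  drv <- universe %in% drivers
  tab <- matrix(c(sum(r1 & drv), sum(r1 & !drv),
                  sum(!r1 & drv), sum(!r1 & !drv)), nrow = 2L, byrow = TRUE)
  tibble::tibble(
    direction = direction,
    rank1_driver = tab[1, 1], rank1_other = tab[1, 2],
    nonrank1_driver = tab[2, 1], nonrank1_other = tab[2, 2],
    p = fisher_one_sided(tab), degenerate = FALSE
  )
}

#' Copy-number-associated gene dependencies
#'
#' Per gene, regresses the dependency score on copy number across cell lines
#' (`Y = alpha X + beta`) and reports the one-sided p-value for `alpha < 0`
#' (higher copy number associated with stronger essentiality, i.e. more
#' negative dependency score), with BH-FDR across genes.
#'
#' @param dep Genes x cell lines matrix of dependency scores.
#' @param cn Genes x cell lines matrix of copy-number levels (same dimnames).
#' @return Tibble: `gene`, `n`, `alpha`, `se`, `t_stat`, `p`, `fdr`,
#'   `degenerate` (constant copy number or fewer than 3 paired values).
#' @export
dependency_regression <- function(dep, cn) {
  stopifnot(is.matrix(dep), is.matrix(cn),
            identical(dimnames(dep), dimnames(cn)))
  rows <- purrr::map_dfr(rownames(dep), function(g) {
    y <- dep[g, ]
    x <- cn[g, ]
    ok <- is.finite(y) & is.finite(x)
    y <- y[ok]
    x <- x[ok]
    if (length(x) < 3L || stats::var(x) == 0) {
      return(tibble::tibble(gene = g, n = length(x), alpha = NA_real_,
                            se = NA_real_, t_stat = NA_real_, p = NA_real_,
                            degenerate = TRUE))
    }
    xc <- x - mean(x)
    alpha <- sum(xc * y) / sum(xc^2)
    resid <- y - mean(y) - alpha * xc
    se <- sqrt(sum(resid^2) / (length(x) - 2) / sum(xc^2))
    t_stat <- alpha / se
    tibble::tibble(gene = g, n = length(x), alpha = alpha, se = se,
                   t_stat = t_stat,
                   p = stats::pt(t_stat, length(x) - 2), degenerate = FALSE)
  })
  ok <- !rows$degenerate
  rows$fdr <- NA_real_
  rows$fdr[ok] <- bh_fdr(rows$p[ok])
  rows
}

#' Enrichment of dependency hits among Rank-1 cis genes
#'
#' One-sided Fisher test of the 2x2 of Rank-1 membership against membership
#' in the set of copy-number-dependent genes.
#'
#' @param rank1,cis_universe As in [driver_enrichment()].
#' @param dependent_genes Genes with significant copy-number-associated
#'   dependency.
#' @return One-row tibble with 2x2 counts and `p`.
#' @export
dependency_enrichment <- function(rank1, cis_universe, dependent_genes) {
  ref <- tibble::tibble(gene = unique(dependent_genes), class = "oncogene",
                        source = "dependency")
  out <- driver_enrichment(rank1, cis_universe, ref, "ANY")
  dplyr::mutate(out, direction = "DEPENDENCY")
}

#' Recurrence ranking of genes across cohorts
#'
#' Orders genes by the number of cohorts in which they occur (descending,
#' ties lexicographic). The per-cohort lists can be Rank-1 genes, top
#' differentially expressed cis genes, or all significant cis genes,
#' enabling comparison of the three ranking strategies.
#'
#' @param cohort_lists Named list (by cohort) of character vectors.
#' @return Tibble: `gene`, `n_cohorts`, `rank`.
#' @export
recurrence_rank <- function(cohort_lists) {
  stopifnot(length(cohort_lists) >= 1L)
  counts <- table(unlist(purrr::map(cohort_lists, unique)))
  out <- tibble::tibble(gene = names(counts),
                        n_cohorts = as.integer(counts)) |>
    dplyr::arrange(dplyr::desc(.data$n_cohorts), .data$gene)
  out$rank <- seq_len(nrow(out))
  out
}

#' One-sample Kolmogorov-Smirnov test against Uniform(0, 1)
#'
#' Aggregates a vector of per-cohort enrichment p-values by testing their
#' departure from uniformity.
#'
#' @param pvals Numeric vector of p-values, length >= 2.
#' @return One-row tibble: `statistic` (D), `p`, `n`.
#' @export
ks_uniform <- function(pvals) {
  if (!length(pvals)) stop("no p-values supplied", call. = FALSE)
  stopifnot(length(pvals) >= 2L, all(pvals >= 0 & pvals <= 1))
  res <- suppressWarnings(stats::ks.test(pvals, "punif", 0, 1))
  tibble::tibble(statistic = unname(res$statistic), p = res$p.value,
                 n = length(pvals))
}
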