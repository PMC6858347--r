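#' Tidy a differential-expression table
#'
#' @param x A `de_table` from [run_de()].
#' @param ... Unused.
#' @return The per-gene statistics as a plain tibble.
#' @method tidy de_table
#' @export
tidy.de_table <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a differential-expression table
#'
#' @param x A `de_table`.
#' @param ... Unused.
#' @return Tibble: `alt_id`, `role`, `n_tested`, `n_significant`, `fc_min`,
#'   `fdr_max`, `sided`.
#' @method glance de_table
#' @export
glance.de_table <- function(x, ...) {
  tibble::tibble(
    alt_id = attr(x, "alt_id"), role = attr(x, "role"),
    n_tested = nrow(x), n_significant = sum(x$significant),
    fc_min = attr(x, "fc_min"), fdr_max = attr(x, "fdr_max"),
    sided = attr(x, "sided")
  )
}

#' Tidy a mediation fit into its triplet table
#'
#' @param x A `mediation_fit` from [run_mediation()].
#' @param ... Unused.
#' @return The per-(cis, trans) Sobel statistics tibble.
#' @method tidy mediation_fit
#' @export
tidy.mediation_fit <- function(x, ...) {
  x$triplets
}

#' One-row summary of a mediation fit
#'
#' @param x A `mediation_fit`.
#' @param ... Unused.
#' @return Tibble: `alt_id`, `n_cis`, `m`, `n_assigned`, `rank1_gene`,
#'   `rank1_wftm`, `wftm_entropy`.
#' @method glance mediation_fit
#' @export
glance.mediation_fit <- function(x, ...) {
  tibble::tibble(
    alt_id = x$alt_id, n_cis = nrow(x$ranking), m = x$m,
    n_assigned = sum(x$assignment$assigned), rank1_gene = x$rank1_gene,
    rank1_wftm = x$ranking$wftm[x$ranking$is_rank1],
    wftm_entropy = if (any(x$ranking$wftm > 0))
      wftm_entropy(x$ranking$wftm) else NA_real_
  )
}

#' Tidy a bootstrap reproducibility report
#'
#' @param x A `bootstrap_report` from [bootstrap_rank1()].
#' @param ... Unused.
#' @return The per-gene inclusion-fraction tibble.
#' @method tidy bootstrap_report
#' @export
tidy.bootstrap_report <- function(x, ...) {
  x$scores
}

#' One-row summary of a bootstrap report
#'
#' @param x A `bootstrap_report`.
#' @param ... Unused.
#' @return Tibble with `B`, gene counts, median inclusion, and the two
#'   regression slopes/p-values (NA when not fitted).
#' @method glance bootstrap_report
#' @export
glance.bootstrap_report <- function(x, ...) {
  tibble::tibble(
    B = x$B, n_rank1 = nrow(x$scores),
    median_inclusion = stats::median(x$scores$inclusion_fraction,
                                     na.rm = TRUE),
    slope_wftm = if (is.null(x$fit_wftm)) NA_real_ else x$fit_wftm$slope,
    p_wftm = if (is.null(x$fit_wftm)) NA_real_ else x$fit_wftm$p,
    slope_entropy = if (is.null(x$fit_entropy)) NA_real_ else
      x$fit_entropy$slope,
    p_entropy = if (is.null(x$fit_entropy)) NA_real_ else x$fit_entropy$p
  )
}
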