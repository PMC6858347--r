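#' Sobel mediation test for one (status, cis, trans) triplet
#'
#' Fits the three ordinary least-squares regressions of the mediation model:
#' `trans ~ status` (total effect tau), `trans ~ status + cis` (direct effect
#' tau_prime and mediator coefficient b), and `cis ~ status` (path a). The
#' mediated effect is `delta_tau = tau - tau_prime` (algebraically equal to
#' `a * b`), its first-order Sobel standard error is
#' `sqrt(b^2 SE(a)^2 + a^2 SE(b)^2)`, and `t = delta_tau / se` is referred to
#' the standard normal for a two-sided p-value.
#'
#' @param status Binary 0/1 vector, not constant, length >= 4.
#' @param cis,trans Numeric vectors of mediator and outcome expression.
#' @return One-row tibble: `tau`, `tau_prime`, `delta_tau`, `a_hat`, `b_hat`,
#'   `se`, `t_stat`, `p`, `degenerate`.
#' @examples
#' set.seed(1)
#' s <- rep(0:1, each = 25)
#' cis <- 0.7 * s + rnorm(50, sd = 0.5)
#' trans <- 0.7 * cis + rnorm(50, sd = 0.5)
#' sobel_triplet(s, cis, trans)
#' @export
sobel_triplet <- function(status, cis, trans) {
  n <- length(status)
  stopifnot(n >= 4L, length(cis) == n, length(trans) == n,
            all(status %in% c(0, 1)))
  if (stats::var(status) == 0) {
    stop("status is constant; mediation model undefined", call. = FALSE)
  }
  core <- sobel_core(status, cbind(cis), cbind(trans))
  tibble::tibble(
    tau = core$tau[1L], tau_prime = core$tau_prime[1L, 1L],
    delta_tau = core$delta_tau[1L, 1L], a_hat = core$a_hat[1L],
    b_hat = core$b_hat[1L, 1L], se = core$se[1L, 1L],
    t_stat = core$t_stat[1L, 1L], p = core$p[1L, 1L],
    degenerate = core$degenerate[1L]
  )
}

# Vectorized Sobel machinery: one status vector, cis matrix (n x p) and trans
# matrix (n x q); returns p x q matrices of triplet statistics.
sobel_core <- function(status, cis_mat, trans_mat) {
  n <- length(status)
  s <- status - mean(status)
  sxx <- sum(s^2)

  # total effect tau_j: trans_j ~ 1 + status
  tc <- sweep(trans_mat, 2L, colMeans(trans_mat))
  tau <- as.vector(crossprod(s, tc)) / sxx          # length q

  # path a_i and SE(a_i): cis_i ~ 1 + status
  cc <- sweep(cis_mat, 2L, colMeans(cis_mat))
  a_hat <- as.vector(crossprod(s, cc)) / sxx        # length p
  rss_a <- colSums(cc^2) - a_hat^2 * sxx
  rss_a[rss_a < 0] <- 0
  se_a <- sqrt(rss_a / pmax(n - 2, 1) / sxx)

  p <- ncol(cis_mat)
  q <- ncol(trans_mat)
  tau_prime <- matrix(NA_real_, p, q)
  b_hat <- matrix(NA_real_, p, q)
  se_b <- matrix(NA_real_, p, q)
  degenerate <- rep(FALSE, p)

  tc_ss <- colSums(tc^2)
  st_cross <- as.vector(crossprod(s, tc))           # length q
  for (i in seq_len(p)) {
    ci <- cc[, i]
    scc <- sum(s * ci)
    ccc <- sum(ci^2)
    # 2x2 normal equations in the centered (status, cis) design
    det2 <- sxx * ccc - scc^2
    if (det2 <= .Machine$double.eps * sxx * max(ccc, 1)) {
      degenerate[i] <- TRUE
      next
    }
    ct_cross <- as.vector(crossprod(ci, tc))        # length q
    tp <- (ccc * st_cross - scc * ct_cross) / det2
    bh <- (sxx * ct_cross - scc * st_cross) / det2
    rss <- tc_ss - tp * st_cross - bh * ct_cross
    rss[rss < 0] <- 0
    sigma2 <- rss / pmax(n - 3, 1)
    tau_prime[i, ] <- tp
    b_hat[i, ] <- bh
    se_b[i, ] <- sqrt(sigma2 * sxx / det2)
  }

  delta_tau <- matrix(tau, p, q, byrow = TRUE) - tau_prime
  se <- sqrt(b_hat^2 * se_a^2 + a_hat^2 * se_b^2)
  t_stat <- delta_tau / se
  zero_zero <- !is.na(se) & se == 0 & delta_tau == 0
  t_stat[zero_zero] <- 0
  pval <- 2 * stats::pnorm(-abs(t_stat))
  pval[zero_zero] <- 1
  list(tau = tau, tau_prime = tau_prime, delta_tau = delta_tau,
       a_hat = a_hat, b_hat = b_hat, se = se, t_stat = t_stat, p = pval,
       degenerate = degenerate)
}

#' Mediation weight of a triplet
#'
#' The fraction of the total alteration-to-trans effect explained by the cis
#' mediator, `w = delta_tau / tau`, clipped into \[0, 1\]. The ratio cancels
#' the sign of the total effect, so full mediation scores 1 whether the
#' alteration up- or down-regulates the trans gene (deletions have negative
#' tau and negative delta_tau under real mediation).
#'
#' @param delta_tau Mediated effect(s).
#' @param tau Total effect(s); zero values yield `NA` (triplet excluded).
#' @return Weight(s) in \[0, 1\] (or `NA` where `tau == 0`).
#' @export
mediation_weight <- function(delta_tau, tau) {
  w <- delta_tau / tau
  w <- pmin(pmax(w, 0), 1)
  w[tau == 0] <- NA_real_
  w
}

#' Assign each trans gene its single best cis mediator
#'
#' Per trans gene, the cis gene with the smallest mediation FDR wins; ties go
#' to the larger `|delta_tau|`, then to the lexicographically first cis gene.
#' Trans genes whose best FDR is at or above `assign_fdr_max` remain
#' unassigned (they still count in the WFTM denominator).
#'
#' @param triplets Tibble of one alteration's triplets with columns
#'   `cis_gene`, `trans_gene`, `delta_tau`, `fdr`, `weight`.
#' @param assign_fdr_max Significance cutoff for calling any mediation
#'   (default 0.25).
#' @return Tibble with one row per trans gene: `trans_gene`, `cis_gene`
#'   (`NA` if unassigned), `weight`, `fdr`, `assigned`.
#' @export
assign_mediators <- function(triplets, assign_fdr_max = 0.25) {
  triplets |>
    dplyr::filter(!is.na(.data$weight)) |>
    dplyr::group_by(.data$trans_gene) |>
    dplyr::arrange(.data$fdr, dplyr::desc(abs(.data$delta_tau)),
                   .data$cis_gene, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      trans_gene = .data$trans_gene,
      cis_gene = dplyr::if_else(.data$fdr < assign_fdr_max, .data$cis_gene,
                                NA_character_),
      weight = .data$weight, fdr = .data$fdr,
      assigned = .data$fdr < assign_fdr_max
    )
}

#' Weighted fraction of trans mediation per cis gene
#'
#' `WFTM_i = sum_j w_ij I_ij / m`, where the indicator selects the trans
#' genes assigned to cis gene i and `m` is the number of significant trans
#' genes of the alteration. Cis genes are ranked by descending WFTM (ties:
#' more mediated trans genes, then lexicographic); rank 1 is the candidate
#' driver.
#'
#' @param assignment Output of [assign_mediators()].
#' @param cis_genes All tested cis genes (zero-WFTM genes are kept).
#' @param m Number of significant trans genes (the denominator).
#' @return Tibble: `cis_gene`, `wftm`, `n_trans_mediated`, `rank`,
#'   `is_rank1`.
#' @export
compute_wftm <- function(assignment, cis_genes, m) {
  stopifnot(m >= 1L)
  hits <- assignment |>
    dplyr::filter(.data$assigned) |>
    dplyr::group_by(cis_gene = .data$cis_gene) |>
    dplyr::summarise(total_w = sum(.data$weight),
                     n_trans_mediated = dplyr::n(), .groups = "drop")
  out <- tibble::tibble(cis_gene = sort(unique(cis_genes))) |>
    dplyr::left_join(hits, by = "cis_gene") |>
    dplyr::mutate(
      wftm = dplyr::coalesce(.data$total_w, 0) / m,
      n_trans_mediated = dplyr::coalesce(.data$n_trans_mediated, 0L)
    ) |>
    dplyr::select(-"total_w") |>
    dplyr::arrange(dplyr::desc(.data$wftm),
                   dplyr::desc(.data$n_trans_mediated), .data$cis_gene)
  out$rank <- seq_len(nrow(out))
  out$is_rank1 <- out$rank == 1L
  out
}

#' Mediation analysis of one alteration
#'
#' Tests every (cis, trans) pair of significant genes with the Sobel test,
#' adjusts FDR over the alteration's triplets, assigns each trans gene its
#' best mediator, computes mediation weights and WFTM, and calls the Rank-1
#' cis driver.
#'
#' @param expr Genes x samples log2 expression matrix (harmonized).
#' @param alts An `alteration_set`.
#' @param alt_id Alteration to analyse.
#' @param cis_sig,trans_sig Significant cis / trans gene identifiers from
#'   [run_de()].
#' @param assign_fdr_max Mediation-call FDR cutoff (default 0.25).
#' @param trans_restrict Optional gene set; only trans genes inside it enter
#'   the mediation (numerator and denominator).
#' @return A `mediation_fit`: list with tibbles `triplets` (per-pair Sobel
#'   statistics), `assignment`, `ranking`, and scalars `alt_id`, `m`,
#'   `rank1_gene`.
#' @export
run_mediation <- function(expr, alts, alt_id, cis_sig, trans_sig,
                          assign_fdr_max = 0.25, trans_restrict = NULL) {
  if (!is.null(trans_restrict)) {
    trans_sig <- intersect(trans_sig, trans_restrict)
  }
  trans_sig <- setdiff(trans_sig, cis_sig)
  if (!length(cis_sig) || !length(trans_sig)) {
    warning("no significant cis or trans genes for '", alt_id,
            "'; skipping mediation", call. = FALSE)
    return(NULL)
  }
  status <- alts$status[alt_id, colnames(expr)]
  cis_mat <- t(expr[cis_sig, , drop = FALSE])
  trans_mat <- t(expr[trans_sig, , drop = FALSE])
  core <- sobel_core(status, cis_mat, trans_mat)
  if (any(core$degenerate)) {
    warning("cis gene(s) collinear with status excluded: ",
            paste(cis_sig[core$degenerate], collapse = ", "), call. = FALSE)
  }
  keep <- !core$degenerate
  p <- sum(keep)
  q <- length(trans_sig)
  triplets <- tibble::tibble(
    alt_id = alt_id,
    cis_gene = rep(cis_sig[keep], times = q),
    trans_gene = rep(trans_sig, each = p),
    tau = rep(core$tau, each = p),
    tau_prime = as.vector(core$tau_prime[keep, , drop = FALSE]),
    delta_tau = as.vector(core$delta_tau[keep, , drop = FALSE]),
    se = as.vector(core$se[keep, , drop = FALSE]),
    t_stat = as.vector(core$t_stat[keep, , drop = FALSE]),
    p = as.vector(core$p[keep, , drop = FALSE])
  )
  triplets$fdr <- bh_fdr(triplets$p)
  triplets$weight <- mediation_weight(triplets$delta_tau, triplets$tau)
  assignment <- assign_mediators(triplets, assign_fdr_max)
  m <- length(trans_sig)
  ranking <- compute_wftm(assignment, cis_sig[keep], m)
  ranking <- dplyr::mutate(ranking, alt_id = alt_id, .before = 1L)
  structure(
    list(alt_id = alt_id, triplets = triplets, assignment = assignment,
         ranking = ranking, m = m,
         rank1_gene = ranking$cis_gene[ranking$is_rank1]),
    class = "mediation_fit"
  )
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat("<mediation_fit> alteration ", x$alt_id, ": ",
      nrow(x$triplets), " triplet(s), m = ", x$m,
      ", Rank-1 cis gene = ", x$rank1_gene, "\n", sep = "")
  print(x$ranking, ...)
  invisible(x)
}
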