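#' Two-group pooled-variance test for a single gene
#'
#' Ordinary two-sample linear-model t-test of log2 expression against a
#' binary alteration status, equal-variance pooling. The log2 fold change is
#' the altered-minus-unaltered group-mean difference.
#'
#' @param values Numeric vector of log2 expression values.
#' @param status Binary 0/1 vector, same length.
#' @return Tibble with one row: `log2fc`, `t_stat`, `p_two`, `df`,
#'   `degenerate` (zero pooled variance).
#' @export
two_group_test <- function(values, status) {
  stopifnot(length(values) == length(status), all(status %in% c(0, 1)))
  n1 <- sum(status == 1)
  n0 <- sum(status == 0)
  if (n1 < 2L || n0 < 2L) {
    stop("each status group needs at least 2 samples (got ", n0, " and ", n1,
         ")", call. = FALSE)
  }
  m1 <- mean(values[status == 1])
  m0 <- mean(values[status == 0])
  log2fc <- m1 - m0
  df <- n0 + n1 - 2
  sp2 <- (sum((values[status == 1] - m1)^2) +
          sum((values[status == 0] - m0)^2)) / df
  se <- sqrt(sp2 * (1 / n0 + 1 / n1))
  degenerate <- se == 0
  if (degenerate) {
    t_stat <- if (log2fc == 0) 0 else sign(log2fc) * Inf
    p_two <- if (log2fc == 0) 1 else 0
  } else {
    t_stat <- log2fc / se
    p_two <- 2 * stats::pt(-abs(t_stat), df)
  }
  tibble::tibble(log2fc = log2fc, t_stat = t_stat, p_two = p_two, df = df,
                 degenerate = degenerate)
}

#' One-sided p-value in the expected direction
#'
#' Upper-tail Student-t probability when the expected direction is `"up"`
#' (amplification cis genes), lower tail when `"down"` (deletion cis genes).
#'
#' @param t_stat t statistic(s).
#' @param df Degrees of freedom (recycled).
#' @param expected_direction `"up"` or `"down"`.
#' @return One-sided p-value(s).
#' @export
one_sided_p <- function(t_stat, df, expected_direction = c("up", "down")) {
  expected_direction <- match.arg(expected_direction)
  if (expected_direction == "up") {
    stats::pt(t_stat, df, lower.tail = FALSE)
  } else {
    stats::pt(t_stat, df, lower.tail = TRUE)
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR adjustment preserving input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) && (anyNA(pvals) || any(pvals < 0 | pvals > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

de_thresholds <- function(role, fc_min = NULL, fdr_max = NULL) {
  defaults <- if (role == "cis") c(fc = 1.2, fdr = 0.25) else c(fc = 1.5,
                                                                fdr = 0.01)
  c(fc_min = fc_min %||% defaults[["fc"]],
    fdr_max = fdr_max %||% defaults[["fdr"]])
}

#' Differential expression of one role's genes against an alteration
#'
#' Tests every gene of the given role (cis or trans) for differential
#' expression between altered and unaltered samples. Cis genes use a
#' one-sided p-value in the alteration's expected direction (up for
#' amplifications, down for deletions); trans genes use the two-sided
#' p-value. FDR is adjusted within the (alteration, role) family before
#' filtering; the significant set requires `fold_change > fc_min` and
#' `fdr < fdr_max` (defaults 1.2/0.25 for cis, 1.5/0.01 for trans).
#'
#' With `moderation = TRUE` the gene variances are shrunk with
#' limma's empirical-Bayes moderated t over the whole gene batch; with
#' `FALSE` each gene gets the closed-form pooled t.
#'
#' @param expr Genes x samples log2 expression matrix.
#' @param alts An `alteration_set`, harmonized with `expr`.
#' @param alt_id Alteration to test against.
#' @param role `"cis"` or `"trans"`.
#' @param genes Gene identifiers to test (from [partition_cis_trans()]).
#' @param fc_min,fdr_max Threshold overrides; `NULL` keeps the role default.
#' @param moderation Use limma's moderated t (default `TRUE`).
#' @return A `de_table` tibble with columns `alt_id`, `role`, `gene_id`,
#'   `log2fc`, `fold_change`, `t_stat`, `p`, `fdr`, `significant` and
#'   attributes `fc_min`, `fdr_max`, `sided`.
#' @export
run_de <- function(expr, alts, alt_id, role = c("cis", "trans"), genes,
                   fc_min = NULL, fdr_max = NULL, moderation = TRUE) {
  role <- match.arg(role)
  thr <- de_thresholds(role, fc_min, fdr_max)
  info <- alts$info[alts$info$alt_id == alt_id, ]
  if (nrow(info) != 1L) stop("unknown alteration '", alt_id, "'",
                             call. = FALSE)
  status <- alts$status[alt_id, colnames(expr)]
  empty <- tibble::tibble(
    alt_id = character(), role = character(), gene_id = character(),
    log2fc = double(), fold_change = double(), t_stat = double(),
    p = double(), fdr = double(), significant = logical()
  )
  if (!length(genes)) {
    warning("no ", role, " genes to test for '", alt_id, "'", call. = FALSE)
    return(new_de_table(empty, alt_id, role, thr))
  }
  if (!info$usable) {
    stop("alteration '", alt_id, "' has constant status; two-group test ",
         "undefined", call. = FALSE)
  }
  if (sum(status == 1) < 2L || sum(status == 0) < 2L) {
    stop("each status group of '", alt_id, "' needs at least 2 samples",
         call. = FALSE)
  }
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    stop("gene(s) absent from expression matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  mat <- expr[genes, , drop = FALSE]
  if (moderation) {
    design <- cbind(Intercept = 1, status = status)
    fit <- limma::eBayes(limma::lmFit(mat, design))
    log2fc <- fit$coefficients[, "status"]
    t_stat <- fit$t[, "status"]
    p_two <- fit$p.value[, "status"]
    df <- fit$df.total
  } else {
    stats_tbl <- pooled_t_matrix(mat, status)
    log2fc <- stats_tbl$log2fc
    t_stat <- stats_tbl$t_stat
    p_two <- stats_tbl$p_two
    df <- stats_tbl$df
  }
  if (role == "cis") {
    dirn <- if (info$direction == "amplification") "up" else "down"
    p <- one_sided_p(t_stat, df, dirn)
    sided <- "one"
  } else {
    p <- p_two
    sided <- "two"
  }
  out <- tibble::tibble(
    alt_id = alt_id, role = role, gene_id = genes,
    log2fc = unname(log2fc), fold_change = 2^abs(unname(log2fc)),
    t_stat = unname(t_stat), p = unname(p), fdr = bh_fdr(unname(p))
  )
  out$significant <- out$fold_change > thr[["fc_min"]] &
    out$fdr < thr[["fdr_max"]]
  new_de_table(out, alt_id, role, thr, sided)
}

new_de_table <- function(tbl, alt_id, role, thr, sided = NA_character_) {
  structure(tbl, class = c("de_table", class(tbl)),
            alt_id = alt_id, role = role,
            fc_min = thr[["fc_min"]], fdr_max = thr[["fdr_max"]],
            sided = sided)
}

# closed-form pooled-variance t across all rows of a matrix
pooled_t_matrix <- function(mat, status) {
  i1 <- status == 1
  i0 <- !i1
  n1 <- sum(i1)
  n0 <- sum(i0)
  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m0 <- rowMeans(mat[, i0, drop = FALSE])
  ss1 <- rowSums((mat[, i1, drop = FALSE] - m1)^2)
  ss0 <- rowSums((mat[, i0, drop = FALSE] - m0)^2)
  df <- n0 + n1 - 2
  se <- sqrt((ss1 + ss0) / df * (1 / n0 + 1 / n1))
  log2fc <- m1 - m0
  t_stat <- ifelse(se == 0, ifelse(log2fc == 0, 0, sign(log2fc) * Inf),
                   log2fc / se)
  p_two <- ifelse(se == 0, ifelse(log2fc == 0, 1, 0),
                  2 * stats::pt(-abs(t_stat), df))
  list(log2fc = log2fc, t_stat = t_stat, p_two = p_two, df = df)
}

#' Significant genes of a DE table
#'
#' @param de A `de_table` from [run_de()].
#' @return Character vector of significant gene identifiers.
#' @export
significant_genes <- function(de) {
  de$gene_id[de$significant]
}
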