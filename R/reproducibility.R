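#' Shannon entropy of an alteration's WFTM profile
#'
#' Normalizes the WFTM values of an alteration's differentially expressed
#' cis genes to a probability vector and returns its Shannon entropy in
#' bits. A single dominant mediator gives 0; k equal mediators give log2(k).
#'
#' @param wftm Non-negative WFTM values; at least one must be positive.
#' @return Entropy in bits (`NA` with a warning for an all-zero vector).
#' @export
wftm_entropy <- function(wftm) {
  stopifnot(all(wftm >= 0))
  total <- sum(wftm)
  if (total == 0) {
    warning("all WFTM values are zero; entropy undefined", call. = FALSE)
    return(NA_real_)
  }
  p <- wftm / total
  p <- p[p > 0]
  h <- -sum(p * log2(p))
  if (h <= 0) 0 else h
}

#' Regress reproducibility scores on a covariate
#'
#' Simple linear regression of bootstrap inclusion fractions on either WFTM
#' or WFTM entropy, with a two-sided t-test on the slope.
#'
#' @param scores Inclusion fractions (response).
#' @param covariate WFTM or entropy values, same length, non-constant.
#' @return One-row tibble: `slope`, `se`, `t_stat`, `p`, `n`, `significant`
#'   (p < 0.05).
#' @export
regress_reproducibility <- function(scores, covariate) {
  n <- length(scores)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  stopifnot(length(covariate) == n)
  if (stats::var(covariate) == 0) {
    stop("covariate is constant; slope undefined", call. = FALSE)
  }
  fit <- stats::lm(scores ~ covariate)
  sm <- summary(fit)$coefficients
  tibble::tibble(slope = sm["covariate", "Estimate"],
                 se = sm["covariate", "Std. Error"],
                 t_stat = sm["covariate", "t value"],
                 p = sm["covariate", "Pr(>|t|)"], n = n,
                 significant = sm["covariate", "Pr(>|t|)"] < 0.05)
}

# Differential expression + mediation for every usable alteration.
# Returns a list of mediation_fit objects (NULL entries dropped) plus the
# per-alteration DE tables.
integrate_alterations <- function(expr, alts, config = list()) {
  cfg <- pipeline_config(config)
  universe <- rownames(expr)
  de_tables <- list()
  fits <- list()
  for (alt in alts$info$alt_id) {
    if (!alts$info$usable[alts$info$alt_id == alt]) next
    status <- alts$status[alt, colnames(expr)]
    if (sum(status == 1) < 2L || sum(status == 0) < 2L) next
    parts <- partition_cis_trans(alts, alt, universe)
    if (!length(parts$cis) || !length(parts$trans)) next
    de_cis <- run_de(expr, alts, alt, "cis", parts$cis,
                     fc_min = cfg$de$cis$fc_min, fdr_max = cfg$de$cis$fdr_max,
                     moderation = cfg$de$moderation)
    de_trans <- run_de(expr, alts, alt, "trans", parts$trans,
                       fc_min = cfg$de$trans$fc_min,
                       fdr_max = cfg$de$trans$fdr_max,
                       moderation = cfg$de$moderation)
    de_tables[[alt]] <- list(cis = de_cis, trans = de_trans)
    fit <- withCallingHandlers(
      run_mediation(expr, alts, alt,
                    significant_genes(de_cis), significant_genes(de_trans),
                    assign_fdr_max = cfg$mediation$assign_fdr_max,
                    trans_restrict = cfg$mediation$trans_restrict),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (!is.null(fit)) fits[[alt]] <- fit
  }
  list(de = de_tables, fits = fits)
}

#' Bootstrap reproducibility of Rank-1 driver calls
#'
#' Reruns differential expression and mediation on `B` resamples of the
#' samples (with replacement, original size) and scores each original
#' Rank-1 gene by its inclusion fraction: the proportion of usable resamples
#' in which it is again Rank-1 for the same alteration. Resamples where an
#' alteration's status becomes constant are skipped for that alteration and
#' its denominator reduced. WFTM entropy over each alteration's tested cis
#' genes and slope regressions of inclusion on WFTM and on entropy complete
#' the report.
#'
#' @param expr,alts Harmonized expression matrix and alteration set.
#' @param config Pipeline configuration list (see [pipeline_config()]).
#' @param B Number of bootstrap resamples (default 100).
#' @param seed Integer seed.
#' @return A `bootstrap_report`: list with tibble `scores` (per original
#'   Rank-1 gene: `alt_id`, `gene`, `wftm`, `entropy`,
#'   `inclusion_fraction`, `n_resamples_used`), tibble `novel` (genes
#'   Rank-1 only in resamples, listed, not scored), and one-row tibbles
#'   `fit_wftm`, `fit_entropy` (or `NULL` when fewer than 3 scores).
#' @export
bootstrap_rank1 <- function(expr, alts, config = list(), B = 100, seed = 1) {
  stopifnot(B >= 1)
  original <- integrate_alterations(expr, alts, config)
  if (!length(original$fits)) {
    stop("original run produced no Rank-1 genes", call. = FALSE)
  }
  scores <- purrr::map_dfr(original$fits, function(fit) {
    tibble::tibble(
      alt_id = fit$alt_id, gene = fit$rank1_gene,
      wftm = fit$ranking$wftm[fit$ranking$is_rank1],
      entropy = wftm_entropy(fit$ranking$wftm)
    )
  })
  hits <- stats::setNames(numeric(nrow(scores)),
                          paste(scores$alt_id, scores$gene))
  used <- stats::setNames(numeric(nrow(scores)), scores$alt_id)
  novel <- list()
  set.seed(seed)
  n <- ncol(expr)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    bexpr <- expr[, idx, drop = FALSE]
    colnames(bexpr) <- sprintf("bs%04d", seq_len(n))
    bstatus <- alts$status[, idx, drop = FALSE]
    colnames(bstatus) <- colnames(bexpr)
    balts <- alteration_set(alts$info[, c("alt_id", "direction")], bstatus,
                            alts$cis_genes)
    res <- integrate_alterations(bexpr, balts, config)
    for (alt in scores$alt_id) {
      fit <- res$fits[[alt]]
      if (is.null(fit)) next
      used[alt] <- used[alt] + 1
      key <- paste(alt, fit$rank1_gene)
      if (key %in% names(hits)) {
        hits[key] <- hits[key] + 1
      } else {
        novel[[length(novel) + 1L]] <- tibble::tibble(
          alt_id = alt, gene = fit$rank1_gene, resample = b)
      }
    }
  }
  scores$n_resamples_used <- as.integer(used[scores$alt_id])
  scores$inclusion_fraction <- ifelse(
    scores$n_resamples_used > 0,
    hits[paste(scores$alt_id, scores$gene)] / scores$n_resamples_used,
    NA_real_)
  fit_wftm <- fit_entropy <- NULL
  if (nrow(scores) >= 3L) {
    if (stats::var(scores$wftm) > 0) {
      fit_wftm <- regress_reproducibility(scores$inclusion_fraction,
                                          scores$wftm)
    }
    if (stats::var(scores$entropy) > 0) {
      fit_entropy <- regress_reproducibility(scores$inclusion_fraction,
                                             scores$entropy)
    }
  }
  structure(list(B = B, seed = seed, scores = scores,
                 novel = dplyr::bind_rows(novel), fit_wftm = fit_wftm,
                 fit_entropy = fit_entropy),
            class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat("<bootstrap_report> B = ", x$B, ", ", nrow(x$scores),
      " original Rank-1 gene(s)\n", sep = "")
  print(x$scores, ...)
  invisible(x)
}

#' Assemble a full pipeline configuration with defaults
#'
#' Missing entries fall back to the package defaults: cis DE thresholds
#' fold change > 1.2 / FDR < 0.25 (one-sided), trans fold change > 1.5 /
#' FDR < 0.01 (two-sided), limma moderation on, mediation-assignment
#' FDR < 0.25, enrichment reporting FDR < 0.25, subtype FDR < 0.05.
#'
#' @param config Possibly partial nested list of overrides.
#' @return Completed configuration list.
#' @export
pipeline_config <- function(config = list()) {
  defaults <- list(
    de = list(cis = list(fc_min = 1.2, fdr_max = 0.25),
              trans = list(fc_min = 1.5, fdr_max = 0.01),
              moderation = TRUE),
    mediation = list(assign_fdr_max = 0.25, trans_restrict = NULL),
    enrichment = list(enabled = TRUE, report_fdr_max = 0.25,
                      subtype_fdr_max = 0.05, mode = "union"),
    seed = 1
  )
  utils::modifyList(defaults, config, keep.null = TRUE)
}

#' Run the full integration pipeline and write its outputs
#'
#' Executes sample harmonization, per-alteration cis/trans differential
#' expression, Sobel mediation with WFTM ranking, and (optionally)
#' gene-set enrichment of the cis-union-trans signatures, writing every
#' table as TSV plus a run log and a summary table to `out_dir`.
#'
#' @param expr Genes x samples log2 expression matrix.
#' @param alts An `alteration_set` (harmonized internally).
#' @param out_dir Output directory (created if needed).
#' @param config Configuration overrides (see [pipeline_config()]).
#' @param gene_sets Optional named list of gene sets for enrichment.
#' @return Invisibly, a list with `summary` (per-alteration counts and
#'   Rank-1 calls), `ranking` (all alterations' WFTM tables), `de`,
#'   `fits`, and `enrichment` (or `NULL`).
#' @export
run_pipeline <- function(expr, alts, out_dir, config = list(),
                         gene_sets = NULL) {
  cfg <- pipeline_config(config)
  set.seed(cfg$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  h <- match_samples(expr, alts)
  log_lines <- c(
    "drivermed run",
    paste0("package version: ",
           as.character(utils::packageVersion("drivermed"))),
    paste0("samples: ", ncol(h$expr), ", genes: ", nrow(h$expr)),
    paste0("seed: ", cfg$seed),
    paste0("thresholds: cis fc>", cfg$de$cis$fc_min, " fdr<",
           cfg$de$cis$fdr_max, "; trans fc>", cfg$de$trans$fc_min, " fdr<",
           cfg$de$trans$fdr_max, "; moderation=", cfg$de$moderation,
           "; assign fdr<", cfg$mediation$assign_fdr_max),
    paste0("unusable alterations (constant status): ",
           paste(h$alts$info$alt_id[!h$alts$info$usable], collapse = ", "))
  )
  res <- integrate_alterations(h$expr, h$alts, cfg)

  de_all <- purrr::map_dfr(res$de, function(pair) {
    dplyr::bind_rows(tibble::as_tibble(pair$cis),
                     tibble::as_tibble(pair$trans))
  })
  readr::write_tsv(de_all, file.path(out_dir, "differential_expression.tsv"),
                   progress = FALSE)
  triplets <- purrr::map_dfr(res$fits, "triplets")
  readr::write_tsv(triplets, file.path(out_dir, "mediation_triplets.tsv"),
                   progress = FALSE)
  ranking <- purrr::map_dfr(res$fits, "ranking")
  readr::write_tsv(ranking, file.path(out_dir, "cis_ranking.tsv"),
                   progress = FALSE)

  enr <- NULL
  if (isTRUE(cfg$enrichment$enabled) && !is.null(gene_sets)) {
    signatures <- purrr::map(res$de, function(pair) {
      list(cis = significant_genes(pair$cis),
           trans = significant_genes(pair$trans))
    })
    enr <- enrich_signatures(signatures, gene_sets, rownames(h$expr),
                             mode = cfg$enrichment$mode,
                             report_fdr_max = cfg$enrichment$report_fdr_max)
    readr::write_tsv(enr, file.path(out_dir, "enrichment.tsv"),
                     progress = FALSE)
  }

  summary_tbl <- purrr::map_dfr(names(res$de), function(alt) {
    fit <- res$fits[[alt]]
    tibble::tibble(
      alt_id = alt,
      n_cis_significant = sum(res$de[[alt]]$cis$significant),
      n_trans_significant = sum(res$de[[alt]]$trans$significant),
      m = if (is.null(fit)) NA_integer_ else fit$m,
      rank1_gene = if (is.null(fit)) NA_character_ else fit$rank1_gene,
      rank1_wftm = if (is.null(fit)) NA_real_ else
        fit$ranking$wftm[fit$ranking$is_rank1]
    )
  })
  readr::write_tsv(summary_tbl, file.path(out_dir, "summary.tsv"),
                   progress = FALSE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(summary = summary_tbl, ranking = ranking, de = res$de,
                 fits = res$fits, enrichment = enr, config = cfg))
}
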