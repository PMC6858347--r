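#' Simulation configuration for evaluating the Sobel mediation test
#'
#' The forward simulator draws labeled mediation instances from two
#' generative systems. True positives follow the causal chain
#' `Y = alpha1 + beta1 X + N(0, sigma1^2)` then
#' `Z = alpha2 + beta2 Y + N(0, sigma2^2)` (total mediation). True negatives
#' share the common cause only: `Y = alpha1 + beta1 X + N(0, sigma1^2)` and
#' `Z = alpha2 + beta2 X + N(0, sigma2^2)`, so `Y` and `Z` are independent
#' given `X`.
#'
#' @param n Sample size (>= 4).
#' @param sigma1,sigma2 Gaussian noise standard deviations (> 0).
#' @param beta1,beta2 Regression coefficients (default 0.7, estimated from
#'   breast-tumor data in the source study design).
#' @param alpha1,alpha2 Intercepts (default 0).
#' @param reps_pos,reps_neg Replicate counts (default 1000 each).
#' @param p_cut Mediation-call threshold on the Sobel p-value (default 0.05).
#' @param altered_fraction Fraction of samples with `X = 1` (default 0.5,
#'   balanced).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n = 500, sigma1 = 0.5, sigma2 = 0.5,
                       beta1 = 0.7, beta2 = 0.7, alpha1 = 0, alpha2 = 0,
                       reps_pos = 1000, reps_neg = 1000, p_cut = 0.05,
                       altered_fraction = 0.5) {
  stopifnot(n >= 4, sigma1 > 0, sigma2 > 0, reps_pos >= 1, reps_neg >= 1,
            p_cut > 0, p_cut <= 1, altered_fraction > 0,
            altered_fraction < 1)
  structure(list(n = n, sigma1 = sigma1, sigma2 = sigma2, beta1 = beta1,
                 beta2 = beta2, alpha1 = alpha1, alpha2 = alpha2,
                 reps_pos = reps_pos, reps_neg = reps_neg, p_cut = p_cut,
                 altered_fraction = altered_fraction),
            class = "sim_config")
}

sim_x <- function(config) {
  n1 <- round(config$n * config$altered_fraction)
  c(rep(0L, config$n - n1), rep(1L, n1))
}

#' Draw one true-positive (mediated) instance
#'
#' @param config A [sim_config()].
#' @return List with binary `x`, mediator `y`, outcome `z`.
#' @export
simulate_positive <- function(config) {
  x <- sim_x(config)
  y <- config$alpha1 + config$beta1 * x + stats::rnorm(config$n, 0,
                                                       config$sigma1)
  z <- config$alpha2 + config$beta2 * y + stats::rnorm(config$n, 0,
                                                       config$sigma2)
  list(x = x, y = y, z = z)
}

#' Draw one true-negative (common-cause, unmediated) instance
#'
#' @param config A [sim_config()].
#' @return List with binary `x`, pseudo-mediator `y`, outcome `z`
#'   (independent of `y` given `x`).
#' @export
simulate_negative <- function(config) {
  x <- sim_x(config)
  y <- config$alpha1 + config$beta1 * x + stats::rnorm(config$n, 0,
                                                       config$sigma1)
  z <- config$alpha2 + config$beta2 * x + stats::rnorm(config$n, 0,
                                                       config$sigma2)
  list(x = x, y = y, z = z)
}

#' Operating characteristics of the Sobel test on simulated data
#'
#' Runs the Sobel test on `reps_pos` true-positive and `reps_neg`
#' true-negative replicates. Sensitivity is the fraction of positives called
#' at `p < p_cut`, specificity the fraction of negatives not called, and AUC
#' the Mann-Whitney probability that a positive's p-value is smaller than a
#' negative's (ties credited 1/2).
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return One-row tibble: `auc`, `sensitivity`, `specificity`,
#'   `corr_xy` (empirical mean correlation of X and Y over replicates),
#'   `n`, `sigma1`, `sigma2`, `n_degenerate`.
#' @export
evaluate_sobel <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  run_side <- function(reps, gen) {
    p <- numeric(reps)
    r <- numeric(reps)
    for (i in seq_len(reps)) {
      d <- gen(config)
      res <- sobel_triplet(d$x, d$y, d$z)
      p[i] <- res$p
      r[i] <- stats::cor(d$x, d$y)
    }
    list(p = p, r = r)
  }
  pos <- run_side(config$reps_pos, simulate_positive)
  neg <- run_side(config$reps_neg, simulate_negative)
  keep_pos <- !is.na(pos$p)
  keep_neg <- !is.na(neg$p)
  pp <- pos$p[keep_pos]
  pn <- neg$p[keep_neg]
  auc <- (sum(outer(pp, pn, "<")) + 0.5 * sum(outer(pp, pn, "=="))) /
    (length(pp) * length(pn))
  tibble::tibble(
    auc = auc,
    sensitivity = mean(pp < config$p_cut),
    specificity = mean(pn >= config$p_cut),
    corr_xy = mean(c(pos$r[keep_pos], neg$r[keep_neg])),
    n = config$n, sigma1 = config$sigma1, sigma2 = config$sigma2,
    n_degenerate = sum(!keep_pos) + sum(!keep_neg)
  )
}

#' Analytic noise-to-correlation conversion
#'
#' For binary X with altered fraction f, `corr(X, Y)` under
#' `Y = beta1 X + noise(sigma1)` is
#' `beta1 sd(X) / sqrt(beta1^2 var(X) + sigma1^2)` with `var(X) = f (1-f)`.
#' Used to label simulation-grid axes by correlation instead of noise sd.
#'
#' @param sigma1 Noise standard deviation (> 0 allowed to be a vector).
#' @param beta1 Regression coefficient (default 0.7).
#' @param altered_fraction Fraction of altered samples (default 0.5).
#' @return Pearson correlation value(s).
#' @export
sigma_to_correlation <- function(sigma1, beta1 = 0.7,
                                 altered_fraction = 0.5) {
  vx <- altered_fraction * (1 - altered_fraction)
  beta1 * sqrt(vx) / sqrt(beta1^2 * vx + sigma1^2)
}

#' Solve for the noise sd giving a target X-Y correlation
#'
#' Inverse of [sigma_to_correlation()].
#'
#' @param r Target correlation in (0, 1).
#' @param beta1,altered_fraction As in [sigma_to_correlation()].
#' @return Noise standard deviation.
#' @export
correlation_to_sigma <- function(r, beta1 = 0.7, altered_fraction = 0.5) {
  stopifnot(r > 0, r < 1)
  vx <- altered_fraction * (1 - altered_fraction)
  sqrt(beta1^2 * vx * (1 - r^2) / r^2)
}

#' Performance grid of the Sobel test over sample size and noise
#'
#' @param n_values Sample sizes.
#' @param sigma_values Noise standard deviations (applied to both stages).
#' @param reps Replicates per side per cell.
#' @param seed Root seed; each cell derives its own sub-seed so cells along
#'   the sigma axis share random draws (common random numbers).
#' @param ... Further arguments to [sim_config()].
#' @return `perf_grid` tibble: one row per (n, sigma) cell with `r`
#'   (analytic correlation), `auc`, `sensitivity`, `specificity`.
#' @export
simulate_grid <- function(n_values = c(50, 200, 1000),
                          sigma_values = c(0.25, 0.5, 1),
                          reps = 200, seed = 1, ...) {
  grid <- tidyr::expand_grid(n = n_values, sigma = sigma_values)
  out <- purrr::pmap_dfr(grid, function(n, sigma) {
    cfg <- sim_config(n = n, sigma1 = sigma, sigma2 = sigma,
                      reps_pos = reps, reps_neg = reps, ...)
    # same sub-seed across the sigma ladder of one n: common random numbers
    res <- evaluate_sobel(cfg, seed = seed + match(n, n_values))
    dplyr::mutate(res, sigma = sigma,
                  r = sigma_to_correlation(sigma, cfg$beta1,
                                           cfg$altered_fraction),
                  .before = 1L)
  })
  structure(out, class = c("perf_grid", class(out)))
}

#' Generate a synthetic integration study with planted mediation structure
#'
#' Emulates the data a copy-number/expression integration run consumes: a
#' log2 expression matrix, an alteration set with cis-gene membership, gene
#' sets, a driver reference, and the planted ground truth. Each alteration
#' carries one or more planted driver cis genes whose expression follows the
#' alteration status (`cis = beta_cis * status + noise`) and which drive a
#' fraction of the alteration's trans genes through the chain
#' (`trans = beta_trans * cis + noise`); the remaining trans genes respond
#' to the alteration directly (no mediation); decoy cis genes track status
#' but are conditionally independent of every trans gene.
#'
#' @param n_samples Samples (default 300).
#' @param n_alterations Alterations (default 2), alternating direction.
#' @param cis_per_alt Cis genes per alteration (default 5: 1 driver + 4
#'   decoys under the default `driver_split`).
#' @param trans_per_alt Trans genes per alteration (default 30).
#' @param mediated_fraction Fraction of trans genes driven through the
#'   planted driver(s) (default 0.8).
#' @param driver_split Numeric vector of per-driver shares of the mediated
#'   trans genes (default `1`: a single dominant driver; `c(0.5, 0.5)`
#'   plants two near-tied mediators).
#' @param beta_cis Status-to-cis effect in log2 units (default 1).
#' @param beta_trans Cis-to-trans effect (default 0.8).
#' @param noise_sd Gaussian noise sd (default 0.5).
#' @param n_background Unrelated noise genes padding the universe
#'   (default 100).
#' @param altered_fraction Fraction of altered samples (default 0.5).
#' @param seed Integer seed.
#' @return A `synthetic_study`: list with `expr`, `alts`, `gene_sets`,
#'   `driver_reference`, and `truth` (tibble of planted drivers and
#'   mediated trans genes per alteration).
#' @export
generate_synthetic_study <- function(n_samples = 300, n_alterations = 2,
                                     cis_per_alt = 5, trans_per_alt = 30,
                                     mediated_fraction = 0.8,
                                     driver_split = 1,
                                     beta_cis = 1, beta_trans = 0.8,
                                     noise_sd = 0.5, n_background = 100,
                                     altered_fraction = 0.5, seed = 1) {
  stopifnot(n_alterations >= 1, cis_per_alt >= 2, trans_per_alt >= 5,
            mediated_fraction >= 0, mediated_fraction <= 1,
            all(driver_split > 0), abs(sum(driver_split) - 1) < 1e-8)
  n_drivers <- length(driver_split)
  if (n_drivers >= cis_per_alt) {
    stop("driver_split plants ", n_drivers, " driver(s) but only ",
         cis_per_alt, " cis genes are available", call. = FALSE)
  }
  set.seed(seed)
  samples <- sprintf("S%03d", seq_len(n_samples))
  n1 <- round(n_samples * altered_fraction)

  rows <- list()
  status <- matrix(0L, n_alterations, n_samples,
                   dimnames = list(sprintf("alt%02d", seq_len(n_alterations)),
                                   samples))
  cis_genes <- list()
  truth <- list()
  directions <- rep(c("amplification", "deletion"),
                    length.out = n_alterations)
  for (k in seq_len(n_alterations)) {
    alt <- rownames(status)[k]
    st <- sample(c(rep(1L, n1), rep(0L, n_samples - n1)))
    status[k, ] <- st
    sgn <- if (directions[k] == "amplification") 1 else -1
    cis_ids <- sprintf("%s_cis%02d", alt, seq_len(cis_per_alt))
    driver_ids <- cis_ids[seq_len(n_drivers)]
    cis_expr <- matrix(NA_real_, cis_per_alt, n_samples,
                       dimnames = list(cis_ids, samples))
    for (i in seq_len(cis_per_alt)) {
      cis_expr[i, ] <- sgn * beta_cis * st +
        stats::rnorm(n_samples, 0, noise_sd)
    }
    trans_ids <- sprintf("%s_trans%02d", alt, seq_len(trans_per_alt))
    n_med <- round(trans_per_alt * mediated_fraction)
    # split mediated trans genes over the planted drivers
    shares <- diff(round(cumsum(c(0, driver_split)) * n_med))
    mediator_of <- rep(NA_character_, trans_per_alt)
    if (n_med > 0) {
      mediator_of[seq_len(n_med)] <- rep(driver_ids, times = shares)
    }
    trans_expr <- matrix(NA_real_, trans_per_alt, n_samples,
                         dimnames = list(trans_ids, samples))
    for (j in seq_len(trans_per_alt)) {
      if (!is.na(mediator_of[j])) {
        trans_expr[j, ] <- beta_trans * cis_expr[mediator_of[j], ] +
          stats::rnorm(n_samples, 0, noise_sd)
      } else {
        trans_expr[j, ] <- sgn * beta_cis * beta_trans * st +
          stats::rnorm(n_samples, 0, noise_sd)
      }
    }
    rows[[alt]] <- rbind(cis_expr, trans_expr)
    cis_genes[[alt]] <- cis_ids
    truth[[alt]] <- tibble::tibble(
      alt_id = alt, direction = directions[k],
      driver = list(driver_ids), driver_split = list(driver_split),
      mediated_trans = list(trans_ids[!is.na(mediator_of)]),
      mediator_of = list(stats::setNames(mediator_of, trans_ids))
    )
  }
  bg <- matrix(stats::rnorm(n_background * n_samples, 0, noise_sd),
               n_background, n_samples,
               dimnames = list(sprintf("bg%03d", seq_len(n_background)),
                               samples))
  expr <- rbind(do.call(rbind, rows), bg)
  alts <- alteration_set(
    tibble::tibble(alt_id = rownames(status), direction = directions),
    status, cis_genes
  )
  truth <- dplyr::bind_rows(truth)
  gene_sets <- list()
  for (k in seq_len(n_alterations)) {
    alt <- truth$alt_id[k]
    gene_sets[[paste0(alt, "_mediated")]] <- truth$mediated_trans[[k]]
    gene_sets[[paste0(alt, "_cis_peak")]] <- cis_genes[[alt]]
  }
  gene_sets[["background"]] <- rownames(bg)
  attr(gene_sets, "source_name") <- "synthetic"
  driver_reference <- tibble::tibble(
    gene = unlist(truth$driver),
    class = ifelse(rep(truth$direction, lengths(truth$driver)) ==
                     "amplification", "oncogene", "tumor_suppressor"),
    source = "planted"
  )
  structure(
    list(expr = expr, alts = alts, gene_sets = gene_sets,
         driver_reference = driver_reference, truth = truth, seed = seed),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> ", nrow(x$expr), " genes x ", ncol(x$expr),
      " samples, ", nrow(x$alts$info), " alteration(s), seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Write a synthetic study's file set
#'
#' Emits the study in the package's TSV/GMT input schemas so the file-based
#' pipeline entry points can consume it.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(study$expr, file.path(dir, "expression.tsv"))
  write_alterations(study$alts, file.path(dir, "lesions.tsv"),
                    file.path(dir, "cis_map.tsv"))
  write_gmt(study$gene_sets, file.path(dir, "gene_sets.gmt"))
  readr::write_tsv(study$driver_reference, file.path(dir, "drivers.tsv"),
                   progress = FALSE)
  truth_flat <- study$truth |>
    dplyr::transmute(.data$alt_id, .data$direction,
                     driver = purrr::map_chr(.data$driver, paste,
                                             collapse = ";"),
                     mediated_trans = purrr::map_chr(.data$mediated_trans,
                                                     paste, collapse = ";"))
  readr::write_tsv(truth_flat, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
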