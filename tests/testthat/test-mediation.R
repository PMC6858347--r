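test_that("an exact additive fit has zero mediated effect", {
  res <- sobel_triplet(c(0, 0, 1, 1), c(0, 1, 0, 1), c(1, 2, 3, 4))
  expect_equal(res$tau, 2)
  expect_equal(res$tau_prime, 2)
  expect_equal(res$delta_tau, 0)
  expect_equal(res$a_hat, 0)
  expect_equal(res$p, 1)
})

test_that("the nested-OLS identity delta_tau = a * b holds on random data", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(6:60, 1)
    status <- rbinom(n, 1, 0.5)
    if (var(status) == 0) next
    cis <- rnorm(n) + status * runif(1, -2, 2)
    trans <- rnorm(n) + cis * runif(1, -2, 2) + status * runif(1, -1, 1)
    res <- sobel_triplet(status, cis, trans)
    expect_equal(res$delta_tau, res$a_hat * res$b_hat, tolerance = 1e-9)
    expect_equal(res$delta_tau, res$tau - res$tau_prime, tolerance = 1e-12)
    # and the regressions themselves agree with lm()
    lm1 <- lm(trans ~ status)
    lm2 <- lm(trans ~ status + cis)
    expect_equal(res$tau, unname(coef(lm1)["status"]), tolerance = 1e-10)
    expect_equal(res$tau_prime, unname(coef(lm2)["status"]),
                 tolerance = 1e-10)
  }
})

test_that("Sobel SE and p match the first-order formula via lm", {
  set.seed(12)
  n <- 80
  status <- rep(c(0, 1), each = 40)
  cis <- 0.9 * status + rnorm(n, sd = 0.6)
  trans <- 0.8 * cis + rnorm(n, sd = 0.6)
  res <- sobel_triplet(status, cis, trans)
  sm_a <- summary(lm(cis ~ status))$coefficients
  sm_b <- summary(lm(trans ~ status + cis))$coefficients
  a <- sm_a["status", "Estimate"]
  se_a <- sm_a["status", "Std. Error"]
  b <- sm_b["cis", "Estimate"]
  se_b <- sm_b["cis", "Std. Error"]
  se <- sqrt(b^2 * se_a^2 + a^2 * se_b^2)
  expect_equal(res$se, se, tolerance = 1e-10)
  expect_equal(res$p, 2 * pnorm(-abs(a * b / se)), tolerance = 1e-10)
})

test_that("Sobel decision agrees with a permutation test of the indirect
           effect on a planted chain", {
  set.seed(30)
  n <- 200
  status <- rep(c(0, 1), each = n / 2)
  cis <- 0.7 * status + rnorm(n, sd = 0.5)
  trans <- 0.7 * cis + rnorm(n, sd = 0.5)
  res <- sobel_triplet(status, cis, trans)
  expect_lt(res$p, 0.01)
  p_perm <- indirect_permutation_oracle(status, cis, trans, n_perm = 2000)
  expect_equal(res$p < 0.05, p_perm < 0.05)

  # and a common-cause (no mediation) instance is accepted as null
  cis0 <- 0.7 * status + rnorm(n, sd = 0.5)
  trans0 <- 0.7 * status + rnorm(n, sd = 0.5)
  res0 <- sobel_triplet(status, cis0, trans0)
  expect_gte(res0$p, 0.05)
})

test_that("Sobel p is invariant to affine rescaling of cis and trans", {
  set.seed(14)
  n <- 60
  status <- rep(c(0, 1), each = 30)
  cis <- status + rnorm(n)
  trans <- cis + rnorm(n)
  base <- sobel_triplet(status, cis, trans)
  scaled <- sobel_triplet(status, 3 * cis - 7, -0.5 * trans + 2)
  expect_equal(scaled$p, base$p, tolerance = 1e-9)
})

test_that("collinear cis genes are flagged degenerate", {
  status <- rep(c(0, 1), each = 5)
  expect_error(sobel_triplet(rep(1, 10), status, rnorm(10)), "constant")
  study_status <- status
  res <- drivermed:::sobel_core(study_status, cbind(study_status),
                                cbind(rnorm(10)))
  expect_true(res$degenerate[1])
})

test_that("mediation weights are the clipped mediated fraction", {
  expect_equal(mediation_weight(0.5, 1.0), 0.5)
  expect_equal(mediation_weight(1.2, 1.0), 1.0)
  expect_equal(mediation_weight(-0.2, 1.0), 0.0)
  # sign cancels: full mediation of a down-regulated trans gene scores 1
  expect_equal(mediation_weight(-0.8, -0.8), 1.0)
  expect_true(is.na(mediation_weight(0.1, 0)))
})

test_that("mediator assignment picks the smallest FDR with stated
           tie-breaks", {
  triplets <- tibble::tibble(
    cis_gene = c("A", "B", "A", "B", "A", "B"),
    trans_gene = c("T1", "T1", "T2", "T2", "T3", "T3"),
    delta_tau = c(0.4, 0.3, 0.5, 0.3, 0.1, 0.2),
    fdr = c(0.01, 0.20, 0.05, 0.05, 0.6, 0.9),
    weight = c(0.4, 0.3, 0.5, 0.3, 0.1, 0.2)
  )
  asg <- assign_mediators(triplets)
  expect_equal(asg$cis_gene[asg$trans_gene == "T1"], "A")
  # exact FDR tie -> larger |delta_tau| wins
  expect_equal(asg$cis_gene[asg$trans_gene == "T2"], "A")
  # best FDR above the cutoff -> unassigned but retained
  expect_true(is.na(asg$cis_gene[asg$trans_gene == "T3"]))
  expect_false(asg$assigned[asg$trans_gene == "T3"])

  # full tie falls back to lexicographic cis gene
  tie <- tibble::tibble(
    cis_gene = c("B", "A"), trans_gene = "T", delta_tau = c(0.3, 0.3),
    fdr = c(0.02, 0.02), weight = c(0.3, 0.3)
  )
  expect_equal(assign_mediators(tie)$cis_gene, "A")
})

test_that("WFTM sums assigned weights over the trans denominator", {
  asg <- tibble::tibble(
    trans_gene = c("T1", "T2", "T3", "T4"),
    cis_gene = c("A", "A", NA, NA),
    weight = c(0.5, 1.0, 0.2, 0.3),
    fdr = c(0.01, 0.01, 0.5, 0.6),
    assigned = c(TRUE, TRUE, FALSE, FALSE)
  )
  rk <- compute_wftm(asg, c("A", "B"), m = 4)
  expect_equal(rk$wftm[rk$cis_gene == "A"], 0.375)
  expect_equal(rk$wftm[rk$cis_gene == "B"], 0)
  expect_equal(rk$cis_gene[rk$is_rank1], "A")

  # single cis gene mediating everything with weight 1 reaches the bound
  asg2 <- tibble::tibble(
    trans_gene = paste0("T", 1:3), cis_gene = "A", weight = 1,
    fdr = 0.01, assigned = TRUE
  )
  rk2 <- compute_wftm(asg2, "A", m = 3)
  expect_equal(rk2$wftm, 1)

  # brute-force recount on random instances; sum of WFTM bounded by 1
  set.seed(9)
  for (i in 1:20) {
    m <- sample(3:10, 1)
    cis <- LETTERS[1:sample(2:4, 1)]
    asg_r <- tibble::tibble(
      trans_gene = paste0("T", 1:m),
      cis_gene = sample(c(cis, NA), m, replace = TRUE),
      weight = runif(m),
      fdr = 0.01
    )
    asg_r$assigned <- !is.na(asg_r$cis_gene)
    rk_r <- compute_wftm(asg_r, cis, m)
    expect_equal(sum(rk_r$wftm),
                 sum(asg_r$weight[asg_r$assigned]) / m,
                 tolerance = 1e-12)
    expect_lte(sum(rk_r$wftm), 1 + 1e-12)
    for (g in cis) {
      expect_equal(rk_r$wftm[rk_r$cis_gene == g],
                   sum(asg_r$weight[asg_r$assigned &
                                      asg_r$cis_gene == g]) / m)
    }
  }
})

test_that("run_mediation recovers a planted driver and honors
           trans_restrict", {
  study <- small_study(seed = 17)
  h <- match_samples(study$expr, study$alts)
  alt <- study$alts$info$alt_id[1]
  parts <- partition_cis_trans(h$alts, alt, rownames(h$expr))
  de_cis <- run_de(h$expr, h$alts, alt, "cis", parts$cis)
  de_trans <- run_de(h$expr, h$alts, alt, "trans", parts$trans)
  fit <- run_mediation(h$expr, h$alts, alt, significant_genes(de_cis),
                       significant_genes(de_trans))
  expect_equal(fit$rank1_gene, study$truth$driver[[1]])
  expect_true(all(fit$ranking$wftm >= 0 & fit$ranking$wftm <= 1))
  expect_lte(sum(fit$ranking$wftm), 1 + 1e-12)
  expect_equal(fit$m, length(significant_genes(de_trans)))

  # restricting trans genes to a pathway shrinks the denominator to the
  # significant trans genes inside it
  restrict <- study$gene_sets[[paste0(alt, "_mediated")]][1:5]
  fit_r <- run_mediation(h$expr, h$alts, alt, significant_genes(de_cis),
                         significant_genes(de_trans),
                         trans_restrict = restrict)
  expect_equal(fit_r$m,
               length(intersect(significant_genes(de_trans), restrict)))

  # a single significant cis gene is Rank-1 by construction
  fit_1 <- run_mediation(h$expr, h$alts, alt,
                         significant_genes(de_cis)[1],
                         significant_genes(de_trans))
  expect_equal(fit_1$rank1_gene, significant_genes(de_cis)[1])

  # empty inputs warn and return NULL
  expect_warning(expect_null(
    run_mediation(h$expr, h$alts, alt, character(0), "x")
  ), "skipping")
})

test_that("tidy and glance expose the mediation fit tables", {
  study <- small_study(seed = 17)
  h <- match_samples(study$expr, study$alts)
  res <- drivermed:::integrate_alterations(h$expr, h$alts)
  fit <- res$fits[[1]]
  expect_s3_class(tidy(fit), "tbl_df")
  g <- glance(fit)
  expect_equal(g$rank1_gene, fit$rank1_gene)
  expect_equal(g$m, fit$m)
})
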