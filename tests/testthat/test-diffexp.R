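test_that("unmoderated two-group test equals the closed-form pooled t", {
  res <- two_group_test(c(1, 1, 2, 2), c(0, 0, 1, 1))
  expect_equal(res$log2fc, 1)
  oracle <- pooled_t_oracle(c(1, 1, 2, 2), c(0, 0, 1, 1))
  expect_equal(res$t_stat, oracle$t)
  expect_equal(res$p_two, oracle$p)

  set.seed(11)
  for (i in 1:25) {
    n <- sample(6:40, 1)
    status <- c(rep(0, ceiling(n / 2)), rep(1, floor(n / 2)))
    values <- rnorm(n, sd = runif(1, 0.2, 3))
    res <- two_group_test(values, status)
    tt <- t.test(values[status == 1], values[status == 0],
                 var.equal = TRUE)
    expect_equal(res$t_stat, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_two, tt$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate groupings are rejected or flagged", {
  expect_error(two_group_test(1:4, c(0, 0, 0, 0)), "at least 2")
  expect_error(two_group_test(1:4, c(0, 0, 0, 1)), "at least 2")
  same <- two_group_test(c(2, 2, 2, 2), c(0, 0, 1, 1))
  expect_equal(same$log2fc, 0)
  expect_equal(same$p_two, 1)
  expect_true(same$degenerate)
})

test_that("one-sided p-values take the expected tail", {
  expect_equal(one_sided_p(0, 10, "up"), 0.5)
  expect_equal(one_sided_p(2.5, 7, "up"), one_sided_p(-2.5, 7, "down"))
  expect_equal(one_sided_p(1, 10, "up"), pt(1, 10, lower.tail = FALSE))
  expect_equal(one_sided_p(1, 10, "down"), pt(1, 10))
})

test_that("BH adjustment matches the brute-force step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, bh_stepup_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
  }
})

test_that("run_de applies role-specific sides, families and thresholds", {
  study <- small_study(seed = 2)
  h <- match_samples(study$expr, study$alts)
  alt <- study$alts$info$alt_id[1]
  parts <- partition_cis_trans(h$alts, alt, rownames(h$expr))
  de_cis <- run_de(h$expr, h$alts, alt, "cis", parts$cis,
                   moderation = FALSE)
  de_trans <- run_de(h$expr, h$alts, alt, "trans", parts$trans,
                     moderation = FALSE)
  # planted cis genes all follow status: all significant one-sided
  expect_true(all(study$truth$driver[[1]] %in% significant_genes(de_cis)))
  # mediated trans genes respond to status; background does not
  expect_true(all(grepl("trans", significant_genes(de_trans))))
  # FDR is computed within the (alteration, role) family
  expect_equal(de_trans$fdr, bh_stepup_oracle(de_trans$p))
  # fold change is on the natural scale
  expect_equal(de_cis$fold_change, 2^abs(de_cis$log2fc))

  # threshold filtering: relaxing thresholds never removes a gene
  strict <- run_de(h$expr, h$alts, alt, "trans", parts$trans,
                   fc_min = 1.5, fdr_max = 0.01, moderation = FALSE)
  loose <- run_de(h$expr, h$alts, alt, "trans", parts$trans,
                  fc_min = 1.1, fdr_max = 0.2, moderation = FALSE)
  expect_true(all(significant_genes(strict) %in% significant_genes(loose)))
})

test_that("cis one-sided direction follows the alteration direction", {
  set.seed(3)
  expr <- matrix(rnorm(40), 2, 20,
                 dimnames = list(c("up_g", "dn_g"), paste0("s", 1:20)))
  status <- matrix(rep(c(0L, 1L), each = 10), 2, 20, byrow = TRUE,
                   dimnames = list(c("amp", "del"), colnames(expr)))
  expr["up_g", status["amp", ] == 1] <- expr["up_g", status["amp", ] == 1] + 2
  expr["dn_g", status["del", ] == 1] <- expr["dn_g", status["del", ] == 1] - 2
  alts <- alteration_set(
    tibble::tibble(alt_id = c("amp", "del"),
                   direction = c("amplification", "deletion")),
    status, list(amp = "up_g", del = "dn_g")
  )
  de_amp <- run_de(expr, alts, "amp", "cis", "up_g", moderation = FALSE)
  de_del <- run_de(expr, alts, "del", "cis", "dn_g", moderation = FALSE)
  expect_lt(de_amp$p, 0.001)
  expect_lt(de_del$p, 0.001)
  # a gene moving against the expected direction gets p near 1
  de_wrong <- run_de(expr, alts, "del", "cis", "up_g", moderation = FALSE)
  expect_gt(de_wrong$p, 0.5)
})

test_that("flipping status labels negates the effect but keeps p_two", {
  set.seed(21)
  values <- rnorm(30)
  status <- rep(c(0, 1), 15)
  a <- two_group_test(values, status)
  b <- two_group_test(values, 1 - status)
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$t_stat, -b$t_stat)
  expect_equal(a$p_two, b$p_two)
})

test_that("moderated statistics track limma's moderated t", {
  study <- small_study(seed = 4)
  h <- match_samples(study$expr, study$alts)
  alt <- study$alts$info$alt_id[1]
  parts <- partition_cis_trans(h$alts, alt, rownames(h$expr))
  de <- run_de(h$expr, h$alts, alt, "trans", parts$trans, moderation = TRUE)
  status <- h$alts$status[alt, colnames(h$expr)]
  fit <- limma::eBayes(limma::lmFit(h$expr[parts$trans, ],
                                    cbind(1, status = status)))
  expect_equal(de$t_stat, unname(fit$t[, "status"]))
  expect_equal(de$log2fc, unname(fit$coefficients[, "status"]))
})

test_that("permuted status labels yield near-null significant trans counts", {
  study <- small_study(seed = 6)
  h <- match_samples(study$expr, study$alts)
  alt <- study$alts$info$alt_id[1]
  parts <- partition_cis_trans(h$alts, alt, rownames(h$expr))
  set.seed(41)
  counts <- replicate(30, {
    perm <- sample(h$alts$status[alt, ])
    st <- matrix(perm, 1, dimnames = list(alt, colnames(h$expr)))
    palts <- alteration_set(h$alts$info[1, c("alt_id", "direction")], st,
                            h$alts$cis_genes[alt])
    de <- run_de(h$expr, palts, alt, "trans", parts$trans,
                 moderation = FALSE)
    sum(de$significant)
  })
  # trans family: fdr < 0.01 and fold > 1.5 under the null
  expect_lt(mean(counts), 0.01 * length(parts$trans) + 0.5)
})

test_that("empty gene lists give an empty table with a warning", {
  study <- small_study(seed = 2)
  h <- match_samples(study$expr, study$alts)
  alt <- study$alts$info$alt_id[1]
  expect_warning(de <- run_de(h$expr, h$alts, alt, "cis", character(0)),
                 "no cis genes")
  expect_equal(nrow(de), 0)
})

test_that("tidy and glance summarize DE tables", {
  study <- small_study(seed = 2)
  h <- match_samples(study$expr, study$alts)
  alt <- study$alts$info$alt_id[1]
  parts <- partition_cis_trans(h$alts, alt, rownames(h$expr))
  de <- run_de(h$expr, h$alts, alt, "cis", parts$cis, moderation = FALSE)
  g <- glance(de)
  expect_equal(g$n_tested, nrow(de))
  expect_equal(g$n_significant, sum(de$significant))
  expect_equal(g$sided, "one")
  expect_s3_class(tidy(de), "tbl_df")
})
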