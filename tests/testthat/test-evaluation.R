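test_that("CCC matches the closed-form example and its edge cases", {
  expect_equal(lins_ccc(c(1, 2, 3), c(2, 4, 6)), 8 / 22, tolerance = 1e-12)
  x <- rnorm(20, 3)
  expect_equal(lins_ccc(x, x), 1, tolerance = 1e-12)
  expect_equal(lins_ccc(x, rep(2, 20)), 0)
  expect_equal(lins_ccc(rep(2, 5), rep(2, 5)), 1)  # identical constants
  expect_error(lins_ccc(1:3, 1:4), "length mismatch")
})

test_that("CCC is symmetric, shift-invariant, and attenuates Pearson", {
  set.seed(51)
  for (rep in 1:30) {
    x <- rnorm(15, 2, 1.5)
    y <- 0.6 * x + rnorm(15, 1, 0.8)
    expect_equal(lins_ccc(x, y), lins_ccc(y, x), tolerance = 1e-12)
    expect_equal(lins_ccc(x + 3, y + 3), lins_ccc(x, y), tolerance = 1e-10)
    expect_lte(abs(lins_ccc(x, y)), abs(cor(x, y)) + 1e-12)
    expect_equal(lins_ccc(x, y), oracle_ccc(x, y), tolerance = 1e-12)
  }
})

test_that("RMSE matches forced arithmetic and the loop oracle", {
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5), tolerance = 1e-12)
  expect_equal(rmse(1:5, 1:5), 0)
  set.seed(52)
  for (rep in 1:20) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(rmse(x, y), oracle_rmse(x, y), tolerance = 1e-12)
  }
  expect_error(rmse(1:3, 1:2), "length mismatch")
})

test_that("paired evaluation equals per-unit CCC recomputation and bins correctly", {
  pc <- affine_cohort(n_genes = 12, n_samples = 10, slope = 0.9,
                      intercept = 0.5, noise = 0.4, seed = 53)
  ev <- paired_ccc(pc, "within_gene")
  pm <- procrustes:::paired_matrices(pc)
  for (i in seq_len(nrow(pm$source))) {
    expect_equal(ev$table$ccc[i], oracle_ccc(pm$source[i, ], pm$target[i, ]),
                 tolerance = 1e-12)
  }
  evs <- paired_ccc(pc, "within_sample")
  for (j in seq_len(ncol(pm$source))) {
    expect_equal(evs$table$ccc[j], oracle_ccc(pm$source[, j], pm$target[, j]),
                 tolerance = 1e-12)
  }
  expect_equal(sum(ev$bin_fractions), 1, tolerance = 1e-9)

  # identical platforms: everything in the high bin
  id <- affine_cohort(n_genes = 5, n_samples = 8, slope = 1, intercept = 0)
  evi <- paired_ccc(id, "within_gene")
  expect_equal(unname(evi$bin_fractions["high"]), 1)
})

test_that("CCC bin edges put 0.5 and 0.8 in the medium bin", {
  ccc_vals <- c(0.49, 0.5, 0.65, 0.8, 0.81)
  bins <- c(0.5, 0.8)
  low <- mean(ccc_vals < bins[1])
  med <- mean(ccc_vals >= bins[1] & ccc_vals <= bins[2])
  high <- mean(ccc_vals > bins[2])
  expect_equal(c(low, med, high), c(0.2, 0.6, 0.2))
  # and the implementation agrees on an engineered cohort
  pc <- affine_cohort(n_genes = 3, n_samples = 50, slope = 1, intercept = 0)
  ev <- paired_ccc(pc, "within_gene", bins = bins)
  expect_equal(unname(ev$bin_fractions), c(0, 0, 1))
})

test_that("gene_set restriction works and validates membership", {
  pc <- affine_cohort(n_genes = 6, n_samples = 10)
  ev <- paired_ccc(pc, "within_gene", gene_set = c("g1", "g3"))
  expect_setequal(ev$table$unit, c("g1", "g3"))
  expect_error(paired_ccc(pc, "within_gene", gene_set = "nope"), "absent")
})

test_that("power solver reproduces the reference result and its contracts", {
  n <- anova_power_sample_size(0.56, 1e-4, 0.95, 2)
  expect_identical(n, 108L)
  expect_gte(anova_power(n, 0.56, 1e-4, 2), 0.95)
  expect_lt(anova_power(n - 1, 0.56, 1e-4, 2), 0.95)

  # equals a brute-force linear scan on an easy configuration
  expect_identical(anova_power_sample_size(2.0, 0.05, 0.8, 2),
                   as.integer(oracle_power_n(2.0, 0.05, 0.8, 2)))
  expect_identical(anova_power_sample_size(0.8, 0.01, 0.9, 3),
                   as.integer(oracle_power_n(0.8, 0.01, 0.9, 3)))
})

test_that("required sample size is monotone in effect size, alpha, and power", {
  n_base <- anova_power_sample_size(0.5, 0.01, 0.9, 2)
  expect_lte(anova_power_sample_size(0.8, 0.01, 0.9, 2), n_base)
  expect_lte(anova_power_sample_size(0.5, 0.05, 0.9, 2), n_base)
  expect_gte(anova_power_sample_size(0.5, 0.01, 0.99, 2), n_base)
  expect_error(anova_power_sample_size(-1, 0.05, 0.8), "effect_size")
  expect_error(anova_power_sample_size(0.5, 1.5, 0.8), "alpha")
})

test_that("signed-rank test matches exact tails and hand-computed statistics", {
  b <- rnorm(20)
  res_same <- suppressWarnings(paired_difference_test(b, b))
  expect_equal(res_same$p.value, 1)

  # uniform +1 shift, n = 20: most extreme rank sum, exact two-sided tail
  res <- paired_difference_test(b, b + 1)
  expect_equal(res$statistic, 20 * 21 / 2)
  expect_equal(res$p.value, 2 / 2^20, tolerance = 1e-12)

  # hand-computed mixed-sign toy: d = (1, -2, 3, -4, 5, 6)
  before <- rep(0, 6)
  after <- c(1, -2, 3, -4, 5, 6)
  res2 <- paired_difference_test(before, after)
  expect_equal(res2$statistic, 1 + 3 + 5 + 6)  # ranks of positives
  expect_equal(res2$p.value, oracle_signed_rank_p(after), tolerance = 1e-12)
})

test_that("signed-rank p-values agree with exhaustive enumeration", {
  set.seed(54)
  for (rep in 1:30) {
    n <- sample(6:11, 1)
    d <- rnorm(n)
    res <- paired_difference_test(rep(0, n), d)
    expect_equal(res$p.value, oracle_signed_rank_p(d), tolerance = 1e-10,
                 info = paste("rep", rep))
  }
})

test_that("per-gene variance matching is CCC-optimal among per-gene linear maps", {
  # For any joint distribution, CCC(c*x + d, y) is maximized over (c, d)
  # at c = sd(y)/sd(x), d matching the means — i.e. the z-score transform.
  # A fitted per-gene regression can therefore approach but never beat a
  # well-estimated z-score on within-gene CCC; its deficit is bounded by
  # r(1-r)^2/(1+r^2). Multi-gene models are not subject to this bound.
  set.seed(56)
  for (rep in 1:20) {
    x <- rnorm(200, 6, 1.5)
    y <- 0.8 * x + 1 + rnorm(200, 0, 0.6)
    c_z <- sd(y) / sd(x)
    ccc_z <- lins_ccc(c_z * (x - mean(x)) + mean(y), y)
    b <- cov(x, y) / var(x)
    ccc_reg <- lins_ccc(b * (x - mean(x)) + mean(y), y)
    expect_gte(ccc_z, ccc_reg - 1e-12)
    r <- cor(x, y)
    expect_lte(ccc_z - ccc_reg, r * (1 - r)^2 / (1 + r^2) + 0.01)
  }
})

test_that("evaluation report joins before/after and tests the difference", {
  pc <- affine_cohort(n_genes = 30, n_samples = 40, slope = 0.6,
                      intercept = 2, noise = 0.3, seed = 55)
  ms <- fit_sprocrustes(pc, mode = "ols")
  before <- paired_ccc(pc, "within_gene")
  after <- paired_ccc(transform_paired(pc, ms), "within_gene")
  rep <- evaluation_report(before, after)
  expect_gt(rep$summary$median_ccc_after, rep$summary$median_ccc_before)
  expect_lt(rep$test$p.value, 0.01)
})
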