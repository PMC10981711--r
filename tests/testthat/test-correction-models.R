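test_that("elastic net at alpha = 0 recovers a noiseless line exactly", {
  x <- seq(0, 5, length.out = 20)
  y <- 2 * x + 1
  f <- elastic_net_fit(matrix(x, ncol = 1), y, alpha = 0, l1_ratio = 0.5)
  expect_equal(f$w0, 1, tolerance = 1e-10)
  expect_equal(unname(f$w), 2, tolerance = 1e-10)
})

test_that("overwhelming l1 penalty shrinks to the intercept-only model", {
  set.seed(21)
  X <- matrix(rnorm(40), 20, 2)
  y <- rnorm(20, 3)
  f <- elastic_net_fit(X, y, alpha = 1e6, l1_ratio = 1)
  expect_equal(unname(f$w), c(0, 0))
  expect_equal(f$w0, mean(y), tolerance = 1e-10)
  # p = 0 degenerates to the response mean
  f0 <- elastic_net_fit(matrix(numeric(0), 20, 0), y, 0.1, 0.5)
  expect_equal(f0$w0, mean(y))
})

test_that("solutions match an independent coordinate-descent oracle", {
  set.seed(22)
  for (rep in 1:10) {
    n <- 20; p <- 3
    X <- matrix(rnorm(n * p), n, p)
    beta <- rnorm(p)
    y <- as.numeric(X %*% beta + rnorm(n, 0, 0.5))
    alpha <- stats::runif(1, 0.01, 0.5)
    rho <- sample(c(0, 0.25, 0.5, 0.9, 1), 1)
    f <- elastic_net_fit(X, y, alpha, rho)
    o <- oracle_elastic_net(X, y, alpha, rho)
    obj_f <- elastic_net_objective(X, y, f$w0, f$w, alpha, rho)
    obj_o <- elastic_net_objective(X, y, o$w0, o$w, alpha, rho)
    expect_lt(obj_f, obj_o + 1e-6)
  }
})

test_that("sProcrustes on an identity platform yields identity models and CCC = 1", {
  pc <- affine_cohort(n_genes = 15, n_samples = 25, slope = 1, intercept = 0)
  ms <- fit_sprocrustes(pc, mode = "ols")
  w1 <- sapply(ms$models, function(m) m$w)
  w0 <- sapply(ms$models, function(m) m$w0)
  expect_equal(unname(w1), rep(1, 15), tolerance = 1e-9)
  expect_equal(unname(w0), rep(0, 15), tolerance = 1e-8)
  ev <- paired_ccc(transform_paired(pc, ms), "within_gene")
  expect_equal(unname(ev$bin_fractions["high"]), 1)
  expect_equal(ev$median_ccc, 1, tolerance = 1e-12)
})

test_that("sProcrustes OLS recovers an exact affine distortion", {
  pc <- affine_cohort(slope = 0.5, intercept = 2)
  ms <- fit_sprocrustes(pc, mode = "ols")
  for (m in ms$models) {
    expect_equal(m$w0, 2, tolerance = 1e-9)
    expect_equal(unname(m$w), 0.5, tolerance = 1e-9)
  }
  # noiseless transform reproduces the target to machine precision
  tr <- transform_expression(ms, pc$source)
  expect_equal(rmse(as.numeric(tr$values), as.numeric(pc$target$values)), 0,
               tolerance = 1e-9)
})

test_that("zero-variance source genes fall back to flagged intercept models", {
  pc <- affine_cohort(n_genes = 5, n_samples = 10)
  pc$source$values[3, ] <- 4
  ms <- fit_sprocrustes(pc, mode = "ols")
  m <- ms$models[["g3"]]
  expect_identical(m$flag, "zero_variance")
  expect_equal(unname(m$w), 0)
  expect_equal(m$w0, mean(pc$target$values[3, ]))
})

test_that("cross-validated sProcrustes recovers slopes under noise", {
  sim <- simulate_paired_cohort(simulation_config(n_genes = 300, seed = 5))
  ms <- fit_sprocrustes(sim$cohort, mode = "elasticnet_cv", seed = 2)
  rec <- truth_recovery_report(sim$truth, ms)
  expect_lt(median(rec$slope_error, na.rm = TRUE), 0.05)
})

test_that("mProcrustes with an empty map matches the single-gene structure", {
  pc <- affine_cohort(n_genes = 6, n_samples = 30, slope = 0.8,
                      intercept = 1, noise = 0.1)
  empty_map <- structure(list(partners = list(), provenance = NULL,
                              params = list()), class = "CoexpressionMap")
  mm <- fit_mprocrustes(pc, empty_map, seed = 3)
  ms <- fit_sprocrustes(pc, mode = "elasticnet_cv", seed = 3)
  expect_identical(names(mm$models), names(ms$models))
  for (g in names(mm$models)) {
    expect_identical(mm$models[[g]]$predictors, g)
    expect_equal(mm$models[[g]]$w, ms$models[[g]]$w, tolerance = 1e-12)
  }
})

test_that("mProcrustes beats sProcrustes when distortion mixes co-expressed genes", {
  # heavy source-platform noise: partner genes carry independent reads of
  # the shared factor, so averaging across them pays on held-out RMSE
  sim <- simulate_paired_cohort(simulation_config(
    n_genes = 120, n_samples = 120, n_factors = 5,
    distortion_mixing = 0.4, noise_sd_source = 0.4, seed = 17))
  labels <- sim$truth$labels[sim$cohort$pairs$source]
  sp <- stratified_split(labels, 0.4, seed = 1)
  pairs <- sim$cohort$pairs
  tr_pairs <- pairs[pairs$source %in% sp$train, ]
  ho_pairs <- pairs[pairs$source %in% sp$holdout, ]
  train <- align_paired(sim$cohort$source, sim$cohort$target, tr_pairs)
  holdout <- align_paired(sim$cohort$source, sim$cohort$target, ho_pairs)
  map <- build_coexpression_map(list(), reference = train$target,
                                k_reference = 10, r_min = 0.7)
  ms <- fit_sprocrustes(train, seed = 4)
  mm <- fit_mprocrustes(train, map, rho_grid = c(0.5, 1), seed = 4)
  rmse_s <- paired_ccc(transform_paired(holdout, ms), "within_gene")$median_rmse
  rmse_m <- paired_ccc(transform_paired(holdout, mm), "within_gene")$median_rmse
  expect_lt(rmse_m, rmse_s)
})

test_that("p >> n fits stay finite with long partner lists", {
  sim <- simulate_paired_cohort(simulation_config(
    n_genes = 70, n_samples = 12, n_factors = 1,
    loading_range = c(1, 1.2), seed = 23))
  g <- "gene_0001"
  partners <- setdiff(sim$truth$genes$gene, g)[1:56]
  map <- structure(list(partners = stats::setNames(list(partners), g),
                        provenance = NULL, params = list()),
                   class = "CoexpressionMap")
  mm <- fit_mprocrustes(sim$cohort, map, rho_grid = c(0.5),
                        max_predictors = 60, seed = 5)
  m <- mm$models[[g]]
  expect_length(m$w, 57)
  expect_true(all(is.finite(m$w)) && is.finite(m$w0))
})

test_that("partner lists beyond the predictor cap are truncated with a warning", {
  sim <- simulate_paired_cohort(simulation_config(
    n_genes = 30, n_samples = 20, n_factors = 1, seed = 31))
  g <- "gene_0001"
  map <- structure(list(partners = stats::setNames(
    list(setdiff(sim$truth$genes$gene, g)), g),
    provenance = NULL, params = list()), class = "CoexpressionMap")
  expect_warning(
    mm <- fit_mprocrustes(sim$cohort, map, rho_grid = 0.5,
                          max_predictors = 10, seed = 5),
    "truncated")
  expect_length(mm$models[[g]]$predictors, 10)
})

test_that("ridge and lasso variants behave at their penalty limits", {
  pc <- affine_cohort(n_genes = 4, n_samples = 25, slope = 1.5,
                      intercept = 0.5)
  # vanishing ridge penalty -> OLS solution
  mr <- fit_penalized_variant(pc, "ridge", grid = 1e-10)
  for (m in mr$models) {
    expect_equal(unname(m$w), 1.5, tolerance = 1e-6)
    expect_equal(m$w0, 0.5, tolerance = 1e-5)
  }
  # huge lasso penalty -> zero weights, intercept = mean
  ml <- fit_penalized_variant(pc, "lasso", grid = 1e6)
  for (g in names(ml$models)) {
    expect_equal(unname(ml$models[[g]]$w), 0)
    expect_equal(ml$models[[g]]$w0, mean(pc$target$values[g, ]),
                 tolerance = 1e-10)
  }
  expect_error(fit_penalized_variant(pc, "ridge", grid = numeric(0)),
               "empty")
})

test_that("ridge solution coincides with elastic_net_fit at l1_ratio = 0", {
  set.seed(24)
  x <- rnorm(30, 5)
  y <- 0.7 * x + 1 + rnorm(30, 0, 0.3)
  for (a in c(0.01, 0.1, 1)) {
    f <- elastic_net_fit(matrix(x, ncol = 1), y, a, 0)
    o <- oracle_elastic_net(matrix(x, ncol = 1), y, a, 0)
    expect_equal(unname(f$w), o$w, tolerance = 1e-8)
    expect_equal(f$w0, o$w0, tolerance = 1e-8)
  }
})

test_that("transform is column-independent, clips at zero, and reports skips", {
  pc <- affine_cohort(n_genes = 8, n_samples = 12, slope = 1, intercept = 0)
  ms <- fit_sprocrustes(pc, mode = "ols")
  # identity model set -> output equals input
  tr <- transform_expression(ms, pc$source)
  expect_equal(tr$values, pc$source$values, tolerance = 1e-9)

  # single-column input equals the corresponding batch column
  one <- new_expression_matrix(pc$source$values[, 3, drop = FALSE],
                               "LOG2_TPM_PLUS1")
  tr1 <- transform_expression(ms, one)
  expect_equal(tr1$values[, 1], tr$values[, 3])

  # clip rule: force a negative prediction
  ms$models[["g1"]]$w0 <- -100
  tr2 <- transform_expression(ms, pc$source)
  expect_true(all(tr2$values["g1", ] == 0))

  # missing predictor -> model skipped and reported
  sub <- new_expression_matrix(pc$source$values[-1, , drop = FALSE],
                               "LOG2_TPM_PLUS1")
  tr3 <- transform_expression(ms, sub)
  expect_identical(attr(tr3, "skipped_genes"), "g1")
  expect_false("g1" %in% rownames(tr3$values))

  raw <- toy_matrix(matrix(c(2e5, 8e5), 2, 1), unit = "TPM")
  expect_error(transform_expression(ms, raw), "LOG2")
})

test_that("z-score transform matches its formula and moment identities", {
  em <- toy_matrix(matrix(5, 1, 1), genes = "g", samples = "s")
  src <- structure(list(batch = "src", mean = c(g = 3), sd = c(g = 2)),
                   class = "BatchMoments")
  tgt <- structure(list(batch = "tgt", mean = c(g = 10), sd = c(g = 4)),
                   class = "BatchMoments")
  out <- zscore_transform(em, src, tgt)
  expect_equal(unname(out$values[1, 1]), 14)  # ((5-3)/2)*4 + 10

  # equal moments -> identity
  m <- random_log_matrix(10, 8)
  bm <- batch_moments(m)
  expect_equal(zscore_transform(m, bm, bm)$values, m$values,
               tolerance = 1e-12)

  # transformed source moments converge to the target moments
  sim <- simulate_paired_cohort(simulation_config(n_genes = 50,
                                                  n_samples = 400, seed = 6))
  pm <- procrustes:::paired_matrices(sim$cohort)
  src_m <- batch_moments(sim$cohort$source)
  tgt_m <- batch_moments(sim$cohort$target)
  ztr <- zscore_transform(sim$cohort$source, src_m, tgt_m)
  expect_equal(unname(rowMeans(ztr$values)), unname(tgt_m$mean),
               tolerance = 1e-8)
  expect_equal(unname(procrustes:::row_pop_sd(ztr$values)),
               unname(tgt_m$sd), tolerance = 1e-8)

  # zero source SD passes through as the target mean
  src0 <- structure(list(batch = "s", mean = c(g = 3), sd = c(g = 0)),
                    class = "BatchMoments")
  expect_warning(out0 <- zscore_transform(em, src0, tgt), "zero source SD")
  expect_equal(unname(out0$values[1, 1]), 10)
})

test_that("BMC transform matches its formula and mean identity exactly", {
  em <- toy_matrix(matrix(7, 1, 1), genes = "g")
  out <- bmc_transform(em, c(g = 5), c(g = 2))
  expect_equal(unname(out$values[1, 1]), 4)

  m <- random_log_matrix(12, 9, seed = 31)
  bm <- batch_moments(m)
  expect_equal(bmc_transform(m, bm, bm)$values, m$values)

  # per-gene mean of transformed training source equals the target mean
  pc <- affine_cohort(n_genes = 10, n_samples = 20, slope = 1.3,
                      intercept = 1, noise = 0.3, seed = 8)
  src_m <- batch_moments(pc$source)
  tgt_m <- batch_moments(pc$target)
  tr <- bmc_transform(pc$source, src_m, tgt_m)
  expect_equal(unname(rowMeans(tr$values)), unname(tgt_m$mean),
               tolerance = 1e-12)
})

test_that("coefficient-scaling transform applies m/d and the clip rules", {
  em <- toy_matrix(matrix(2, 1, 1), genes = "g")
  # 2 * 3 / 2 = 3 (single value: mean + 3 sd = value, no clipping effect)
  out <- dasc_transform(em, data.frame(gene = "g", m = 3, d = 2))
  expect_equal(unname(out$values[1, 1]), 3)

  # m = d and values within 3 sd -> identity
  m <- random_log_matrix(6, 30, seed = 41)
  cf <- data.frame(gene = gene_ids(m), m = 2, d = 2)
  expect_equal(dasc_transform(m, cf)$values, m$values, tolerance = 1e-12)

  # constructed outlier is clipped to mean + 3 sd of the scaled vector
  x <- c(rep(2, 30), 60)
  emo <- toy_matrix(matrix(x, 1), genes = "g",
                    samples = paste0("s", seq_along(x)))
  cfo <- data.frame(gene = "g", m = 2, d = 1)
  sc <- 2 * x
  lim <- mean(sc) + 3 * sqrt(mean((sc - mean(sc))^2))
  outo <- dasc_transform(emo, cfo)
  expect_equal(unname(outo$values[1, 31]), lim)
  expect_equal(unname(outo$values[1, 1]), 4)

  # d = 0 genes are skipped with a warning
  expect_warning(
    res <- dasc_transform(m, data.frame(gene = gene_ids(m), m = 1,
                                        d = c(0, rep(1, 5)))),
    "d = 0")
  expect_false(gene_ids(m)[1] %in% rownames(res$values))
})

test_that("model sets serialize to text and reload with bit-identical predictions", {
  sim <- simulate_paired_cohort(simulation_config(n_genes = 25,
                                                  n_samples = 30, seed = 9))
  ms <- fit_sprocrustes(sim$cohort, mode = "elasticnet_cv", seed = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model_set(ms, path)
  back <- read_model_set(path)
  tr1 <- transform_expression(ms, sim$cohort$source)
  tr2 <- transform_expression(back, sim$cohort$source)
  expect_identical(tr1$values, tr2$values)
})
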