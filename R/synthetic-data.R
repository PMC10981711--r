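#' Simulation configuration for paired two-platform cohorts
#'
#' Describes the generative model of the built-in simulator: a
#' latent-factor poly-A (target) cohort with cancer-type clusters, and an
#' exome-capture (source) replicate obtained by gene-wise affine platform
#' distortion plus platform noise, with optional probe-dropout
#' ("problematic") genes, zero inflation, and multi-gene distortion
#' mixing. All expression lives in a log2(TPM+1)-like space (non-negative,
#' baselines in log2 units).
#'
#' Defaults are the package's reference study conditions: 2,000 genes x
#' 100 pairs over 3 cohorts at 5-sigma separation, 10 co-expression
#' factors with loadings in `[0.8, 1.2]`, distortion slopes
#' `LogNormal(0, 0.3)` and intercepts `N(0, 0.5^2)`, biological noise SD
#' 0.5 and source-platform noise SD 0.2.
#'
#' @param n_genes,n_samples,n_cohorts problem dimensions (`n_samples` =
#'   number of sample pairs).
#' @param cohort_separation minimum pairwise distance between cohort
#'   centers in latent-factor space, in units of the within-cohort factor
#'   SD (1).
#' @param n_factors number of latent co-expression factors (<= n_genes).
#' @param loading_range per-gene factor loading range (uniform).
#' @param baseline_range per-gene baseline expression range, log2 units.
#' @param slope_meanlog,slope_sdlog LogNormal prior of the per-gene
#'   distortion slope.
#' @param intercept_mean,intercept_sd Normal prior of the distortion
#'   intercept.
#' @param noise_sd_target gene-specific biological noise SD in the target
#'   matrix.
#' @param noise_sd_source platform noise SD added on the source side.
#' @param frac_problematic fraction of genes with source-side signal loss
#'   (probe coverage gap analog).
#' @param zero_inflation per-entry dropout probability on the source side.
#' @param distortion_mixing fraction of the distorted signal taken from
#'   the average of the gene's factor mates instead of the gene itself
#'   (0 = pure per-gene affine distortion).
#' @param seed master seed; independent sub-streams are derived from it
#'   for structure, cohorts, target noise, distortion, and source noise.
#' @return a validated `SimulationConfig` list.
#' @export
simulation_config <- function(n_genes = 2000L, n_samples = 100L,
                              n_cohorts = 3L, cohort_separation = 5,
                              n_factors = 10L, loading_range = c(0.8, 1.2),
                              baseline_range = c(3, 9),
                              slope_meanlog = 0, slope_sdlog = 0.3,
                              intercept_mean = 0, intercept_sd = 0.5,
                              noise_sd_target = 0.5, noise_sd_source = 0.2,
                              frac_problematic = 0, zero_inflation = 0,
                              distortion_mixing = 0, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              n_cohorts = as.integer(n_cohorts),
              cohort_separation = cohort_separation,
              n_factors = as.integer(n_factors),
              loading_range = loading_range, baseline_range = baseline_range,
              slope_meanlog = slope_meanlog, slope_sdlog = slope_sdlog,
              intercept_mean = intercept_mean, intercept_sd = intercept_sd,
              noise_sd_target = noise_sd_target,
              noise_sd_source = noise_sd_source,
              frac_problematic = frac_problematic,
              zero_inflation = zero_inflation,
              distortion_mixing = distortion_mixing,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_genes < 1L || cfg$n_samples < 2L || cfg$n_cohorts < 1L) {
    stop("need n_genes >= 1, n_samples >= 2, n_cohorts >= 1", call. = FALSE)
  }
  if (cfg$n_factors < 1L || cfg$n_factors > cfg$n_genes) {
    stop("n_factors must lie in [1, n_genes]", call. = FALSE)
  }
  for (f in c("frac_problematic", "zero_inflation", "distortion_mixing")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(f, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$cohort_separation < 0) stop("cohort_separation must be >= 0", call. = FALSE)
  if (cfg$noise_sd_target < 0 || cfg$noise_sd_source < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  if (diff(cfg$loading_range) < 0 || diff(cfg$baseline_range) < 0) {
    stop("ranges must be non-decreasing", call. = FALSE)
  }
  invisible(cfg)
}

#' Simulate a paired two-platform cohort with known ground truth
#'
#' Target (poly-A-like) matrix: per gene `b_g + lambda_g * F_{f(g),j} +
#' eps`, rectified at 0, where factor scores `F` carry cohort shifts
#' (cohort centers are random directions rescaled so the minimum pairwise
#' distance equals `cohort_separation`). Source (EC-like) matrix: per-gene
#' affine distortion `a_g + s_g * signal + eta`, rectified at 0, where
#' `signal` is the gene's own target value, optionally mixed with its
#' factor-mate average (`distortion_mixing`). Problematic genes lose the
#' source-side signal entirely (replaced by rectified low-level noise).
#' Deterministic given `config$seed`; independent sub-streams drive
#' structure, cohorts, target noise, distortion, and source noise.
#'
#' @param config a `SimulationConfig`.
#' @return list with `cohort` (a `PairedCohort` in `LOG2_TPM_PLUS1`
#'   space) and `truth` (a `SyntheticTruth`).
#' @export
simulate_paired_cohort <- function(config = simulation_config()) {
  validate_simulation_config(config)
  ng <- config$n_genes; n <- config$n_samples
  nf <- config$n_factors; nc <- config$n_cohorts
  seed <- config$seed

  # structure stream: gene -> factor, loadings, baselines, problematic set
  st <- with_preserved_seed(derive_seed(seed, 11L), {
    list(factor_of = sample(rep_len(seq_len(nf), ng)),
         loading = stats::runif(ng, config$loading_range[1L],
                                config$loading_range[2L]),
         baseline = stats::runif(ng, config$baseline_range[1L],
                                 config$baseline_range[2L]),
         problematic = sort(sample.int(ng, round(config$frac_problematic * ng))))
  })

  # cohort stream: labels and factor-space centers at fixed separation
  co <- with_preserved_seed(derive_seed(seed, 12L), {
    lab_idx <- sample(rep_len(seq_len(nc), n))
    centers <- matrix(0, nf, nc)
    if (nc > 1L && config$cohort_separation > 0) {
      centers <- matrix(stats::rnorm(nf * nc), nf, nc)
      dmin <- min(stats::dist(t(centers)))
      if (dmin == 0) dmin <- 1e-8
      centers <- centers * (config$cohort_separation / dmin)
    }
    scores <- centers[, lab_idx, drop = FALSE] +
      matrix(stats::rnorm(nf * n), nf, n)
    list(lab_idx = lab_idx, centers = centers, scores = scores)
  })

  # target matrix with biological noise
  eps <- with_preserved_seed(derive_seed(seed, 13L),
                             matrix(stats::rnorm(ng * n, 0, config$noise_sd_target),
                                    ng, n))
  target <- pmax(st$baseline + st$loading * co$scores[st$factor_of, , drop = FALSE] + eps, 0)

  # distortion stream
  dis <- with_preserved_seed(derive_seed(seed, 14L), {
    list(slope = stats::rlnorm(ng, config$slope_meanlog, config$slope_sdlog),
         intercept = stats::rnorm(ng, config$intercept_mean,
                                  config$intercept_sd))
  })

  signal <- target
  if (config$distortion_mixing > 0) {
    fac_sum <- rowsum(target, st$factor_of)
    fac_n <- as.numeric(table(factor(st$factor_of, levels = seq_len(nf))))
    mates <- (fac_sum[st$factor_of, , drop = FALSE] - target) /
      pmax(fac_n[st$factor_of] - 1L, 1L)
    solo <- fac_n[st$factor_of] == 1L
    mates[solo, ] <- target[solo, ]
    signal <- (1 - config$distortion_mixing) * target +
      config$distortion_mixing * mates
  }

  src <- with_preserved_seed(derive_seed(seed, 15L), {
    s0 <- dis$intercept + dis$slope * signal +
      matrix(stats::rnorm(ng * n, 0, config$noise_sd_source), ng, n)
    if (length(st$problematic) > 0L) {
      # probe coverage gap: source-side signal loss, not added noise
      s0[st$problematic, ] <- matrix(stats::rnorm(length(st$problematic) * n, 0, 0.1),
                                     length(st$problematic), n)
    }
    if (config$zero_inflation > 0) {
      s0[matrix(stats::runif(ng * n) < config$zero_inflation, ng, n)] <- 0
    }
    s0
  })
  source <- pmax(src, 0)

  genes <- sprintf("gene_%04d", seq_len(ng))
  src_ids <- sprintf("EC_%03d", seq_len(n))
  tgt_ids <- sprintf("PA_%03d", seq_len(n))
  cohort_names <- sprintf("C%d", co$lab_idx)
  dimnames(target) <- list(genes, tgt_ids)
  dimnames(source) <- list(genes, src_ids)
  labels <- stats::setNames(c(cohort_names, cohort_names),
                            c(src_ids, tgt_ids))
  paired <- align_paired(new_expression_matrix(source, "LOG2_TPM_PLUS1"),
                         new_expression_matrix(target, "LOG2_TPM_PLUS1"),
                         data.frame(source = src_ids, target = tgt_ids,
                                    stringsAsFactors = FALSE),
                         cohort_labels = labels)
  truth <- structure(
    list(genes = data.frame(gene = genes,
                            slope = dis$slope,
                            intercept = dis$intercept,
                            factor = st$factor_of,
                            loading = st$loading,
                            baseline = st$baseline,
                            problematic = seq_len(ng) %in% st$problematic,
                            stringsAsFactors = FALSE),
         problematic = genes[st$problematic],
         labels = labels,
         centers = co$centers,
         config = config,
         seed = seed),
    class = "SyntheticTruth")
  list(cohort = paired, truth = truth)
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf("SyntheticTruth: %d genes (%d problematic), %d cohorts, seed=%d\n",
              nrow(x$genes), length(x$problematic),
              x$config$n_cohorts, x$seed))
  invisible(x)
}

#' Parameter-recovery report against simulator ground truth
#'
#' For single-gene identifiable genes, compares a fitted model's
#' coefficients with the true inverse-distortion parameters: the target
#' satisfies `target = (source - a_g)/s_g` up to noise, so the truth for
#' the fitted slope is `1/s_g` and for the intercept `-a_g/s_g`.
#' Problematic genes are flagged unrecoverable rather than scored;
#' multi-predictor models are marked `multigene`; genes without a model
#' are marked `unrecovered`.
#'
#' @param truth a `SyntheticTruth`.
#' @param models a `ModelSet` fit on a cohort generated from `truth`.
#' @return data.frame with per-gene true and estimated inverse-distortion
#'   parameters, absolute errors, and a `status` column (`ok`,
#'   `problematic`, `multigene`, `unrecovered`).
#' @export
truth_recovery_report <- function(truth, models) {
  g <- truth$genes
  true_slope <- 1 / g$slope
  true_int <- -g$intercept / g$slope
  est_slope <- rep(NA_real_, nrow(g))
  est_int <- rep(NA_real_, nrow(g))
  status <- rep("unrecovered", nrow(g))
  for (i in seq_len(nrow(g))) {
    gm <- models$models[[g$gene[i]]]
    if (is.null(gm)) next
    if (g$problematic[i]) {
      status[i] <- "problematic"
      next
    }
    if (length(gm$predictors) > 1L) {
      status[i] <- "multigene"
      next
    }
    est_slope[i] <- gm$w[1L]
    est_int[i] <- gm$w0
    status[i] <- "ok"
  }
  data.frame(gene = g$gene,
             true_slope = true_slope, est_slope = est_slope,
             slope_error = abs(est_slope - true_slope),
             true_intercept = true_int, est_intercept = est_int,
             intercept_error = abs(est_int - true_int),
             status = status, stringsAsFactors = FALSE)
}

#' Write simulated cohort and truth to a directory
#'
#' Writes `source.tsv`, `target.tsv`, `pairs.tsv`, `labels.tsv`, and
#' `truth.json` (slope/intercept/factor/loading per gene plus the
#' configuration).
#'
#' @param sim result of [simulate_paired_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(sim$cohort$source, file.path(dir, "source.tsv"))
  write_expression_matrix(sim$cohort$target, file.path(dir, "target.tsv"))
  utils::write.table(sim$cohort$pairs, file.path(dir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- data.frame(sample = names(sim$truth$labels),
                    cohort = unname(sim$truth$labels),
                    stringsAsFactors = FALSE)
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(genes = sim$truth$genes,
                            config = unclass(sim$truth$config),
                            seed = sim$truth$seed),
                       file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
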