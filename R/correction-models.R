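#' Elastic net fit at fixed penalties
#'
#' Minimizes
#' `(1/2n) ||X w - y||^2 + alpha * rho * ||w||_1 + alpha * (1 - rho)/2 * ||w||_2^2`
#' with an unpenalized intercept. For two or more predictors the solver is
#' `glmnet` (whose gaussian objective is exactly this, with
#' `lambda = alpha` and mixing `alpha = rho`); for a single predictor the
#' exact closed-form soft-threshold solution is used; `alpha = 0` is plain
#' least squares.
#'
#' @param X numeric predictor matrix, samples x p (p may be 0).
#' @param y numeric response vector.
#' @param alpha penalty strength (>= 0).
#' @param l1_ratio mixing parameter rho in `[0, 1]`; 1 = lasso, 0 = ridge.
#' @return list with `w0` (intercept) and `w` (weights, named when `X` has
#'   column names).
#' @export
elastic_net_fit <- function(X, y, alpha, l1_ratio) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y) && ncol(X) > 0L) {
    stop("nrow(X) must equal length(y)", call. = FALSE)
  }
  if (length(y) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("NA in inputs", call. = FALSE)
  stop_if_not_scalar_number(alpha, "alpha")
  stop_if_not_scalar_number(l1_ratio, "l1_ratio")
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (l1_ratio < 0 || l1_ratio > 1) stop("l1_ratio must lie in [0, 1]", call. = FALSE)
  p <- ncol(X)
  if (p == 0L) return(list(w0 = mean(y), w = numeric(0)))
  if (alpha == 0) {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    return(list(w0 = unname(cf[1L]),
                w = stats::setNames(unname(cf[-1L]), colnames(X))))
  }
  if (p == 1L) {
    f <- en_fit_1d(X[, 1L], y, alpha, l1_ratio)
    return(list(w0 = f$w0, w = stats::setNames(f$w1, colnames(X))))
  }
  # glmnet standardizes y internally, which rescales the l1 part of the
  # penalty by sd(y) but not the l2 part; standardize y explicitly and
  # remap (alpha, rho) so the stated objective is solved exactly
  sy <- sqrt(mean((y - mean(y))^2))
  if (sy == 0) return(list(w0 = mean(y),
                           w = stats::setNames(rep(0, p), colnames(X))))
  l1 <- alpha * l1_ratio / sy
  l2 <- alpha * (1 - l1_ratio)
  lam <- l1 + l2
  mix <- l1 / lam
  # approach the target lambda along a short decreasing path for stability
  fit <- glmnet::glmnet(X, y / sy, family = "gaussian", alpha = mix,
                        lambda = lam * c(64, 16, 4, 1), standardize = FALSE,
                        thresh = 1e-14, maxit = 1e7)
  cf <- as.numeric(stats::coef(fit, s = lam)) * sy
  list(w0 = cf[1L], w = stats::setNames(cf[-1L], colnames(X)))
}

#' Elastic net objective value
#'
#' @inheritParams elastic_net_fit
#' @param w0 intercept.
#' @param w weight vector.
#' @return objective value (see [elastic_net_fit()]).
#' @export
elastic_net_objective <- function(X, y, w0, w, alpha, l1_ratio) {
  X <- as.matrix(X)
  resid <- y - w0 - if (ncol(X) > 0L) as.numeric(X %*% w) else 0
  mean(resid^2) / 2 + alpha * l1_ratio * sum(abs(w)) +
    alpha * (1 - l1_ratio) / 2 * sum(w^2)
}

# exact single-predictor elastic net
en_fit_1d <- function(x, y, alpha, rho) {
  mx <- mean(x); my <- mean(y)
  sxx <- mean((x - mx)^2)
  sxy <- mean((x - mx) * (y - my))
  den <- sxx + alpha * (1 - rho)
  w1 <- if (den <= 0) 0 else soft_threshold(sxy, alpha * rho) / den
  list(w0 = my - w1 * mx, w1 = w1)
}

#' Default l1-ratio grid for cross-validated elastic net
#' @return numeric vector of mixing values.
#' @export
default_rho_grid <- function() c(0.1, 0.5, 0.7, 0.9, 0.95, 0.99, 1.0)

# log-spaced penalty grid from the data-driven maximum down 4 decades
default_alpha_grid_1d <- function(x, y, rho_grid, n_alpha = 20L) {
  sxy <- abs(mean((x - mean(x)) * (y - mean(y))))
  rho_min <- max(min(rho_grid[rho_grid > 0], 1), 1e-3)
  amax <- max(sxy / rho_min, 1e-8)
  exp(seq(log(amax), log(amax * 1e-4), length.out = n_alpha))
}

# cross-validated single-predictor elastic net over an (alpha, rho) grid;
# fold assignment comes in as foldid so all genes share folds
en_cv_1d <- function(x, y, alpha_grid = NULL, rho_grid = default_rho_grid(),
                     foldid = NULL, cv_folds = 3L) {
  n <- length(x)
  if (is.null(foldid)) foldid <- rep_len(seq_len(cv_folds), n)
  if (is.null(alpha_grid)) alpha_grid <- default_alpha_grid_1d(x, y, rho_grid)
  grid <- expand.grid(alpha = sort(alpha_grid, decreasing = TRUE),
                      rho = rho_grid)
  A <- grid$alpha; R <- grid$rho
  folds <- sort(unique(foldid))
  err <- matrix(NA_real_, nrow = nrow(grid), ncol = length(folds))
  for (i in seq_along(folds)) {
    tr <- foldid != folds[i]
    xt <- x[tr]; yt <- y[tr]
    mx <- mean(xt); my <- mean(yt)
    sxx <- mean((xt - mx)^2)
    sxy <- mean((xt - mx) * (yt - my))
    den <- sxx + A * (1 - R)
    w1 <- ifelse(den <= 0, 0, soft_threshold(sxy, A * R) / den)
    w0 <- my - w1 * mx
    xv <- x[!tr]; yv <- y[!tr]
    # validation MSE, expanded so the whole grid is vectorized
    err[, i] <- mean(yv^2) - 2 * w0 * mean(yv) - 2 * w1 * mean(xv * yv) +
      w0^2 + 2 * w0 * w1 * mean(xv) + w1^2 * mean(xv^2)
  }
  cvm <- rowMeans(err)
  best <- which.min(cvm)  # grid ordered most-regularized first; ties keep it
  f <- en_fit_1d(x, y, A[best], R[best])
  list(w0 = f$w0, w1 = f$w1, alpha = A[best], rho = R[best])
}

# --- ModelSet -----------------------------------------------------------

gene_model <- function(gene_id, predictors, w0, w, alpha = NA_real_,
                       rho = NA_real_, n_train = NA_integer_, flag = "") {
  list(gene_id = gene_id, predictors = predictors, w0 = unname(w0),
       w = unname(as.numeric(w)), alpha = unname(alpha), rho = unname(rho),
       n_train = n_train, flag = flag)
}

new_model_set <- function(models, source_platform, target_platform,
                          gene_universe, meta) {
  names(models) <- vapply(models, `[[`, "", "gene_id")
  structure(list(models = models, source_platform = source_platform,
                 target_platform = target_platform,
                 gene_universe = gene_universe, meta = meta),
            class = "ModelSet")
}

#' @export
print.ModelSet <- function(x, ...) {
  np <- vapply(x$models, function(m) length(m$predictors), integer(1L))
  cat(sprintf("ModelSet: %d gene models (%s -> %s), predictors per model %d..%d\n",
              length(x$models), x$source_platform, x$target_platform,
              if (length(np)) min(np) else 0, if (length(np)) max(np) else 0))
  cat(sprintf("  method=%s cv_folds=%s seed=%s\n",
              x$meta$method %||% "?", x$meta$cv_folds %||% "-",
              x$meta$seed %||% "-"))
  invisible(x)
}

check_fit_inputs <- function(paired) {
  if (paired$source$unit != "LOG2_TPM_PLUS1") {
    stop("model fitting requires LOG2_TPM_PLUS1 matrices; got ",
         paired$source$unit, " (apply log_transform first)", call. = FALSE)
  }
  if (n_pairs(paired) < 3L) stop("need at least 3 paired samples", call. = FALSE)
}

#' Fit single-gene transfer models (sProcrustes)
#'
#' One model per gene with the gene's own source-platform expression as
#' the only predictor: `y = w0 + w1 * x`. `mode = "elasticnet_cv"`
#' (default) tunes the penalty by internal k-fold cross-validation over an
#' (alpha, rho) grid; `mode = "ols"` is plain least squares. Genes with
#' zero source variance get an intercept-only model predicting the target
#' mean, flagged `"zero_variance"`.
#'
#' @param paired a `PairedCohort` in `LOG2_TPM_PLUS1` space with >= 3
#'   pairs.
#' @param mode `"elasticnet_cv"` or `"ols"`.
#' @param cv_folds folds for internal cross-validation (default 3).
#' @param alpha_grid optional penalty grid; default is a data-driven
#'   log-spaced path per gene.
#' @param rho_grid l1-ratio grid (default [default_rho_grid()]).
#' @param seed seed for the fold assignment, recorded in the metadata.
#' @return a `ModelSet`.
#' @export
fit_sprocrustes <- function(paired, mode = c("elasticnet_cv", "ols"),
                            cv_folds = 3L, alpha_grid = NULL,
                            rho_grid = default_rho_grid(), seed = 1L) {
  mode <- match.arg(mode)
  check_fit_inputs(paired)
  pm <- paired_matrices(paired)
  S <- pm$source; Tg <- pm$target
  n <- ncol(S)
  genes <- rownames(S)
  sm <- rowMeans(S); tm <- rowMeans(Tg)
  sxx <- rowMeans((S - sm)^2)
  sxy <- rowMeans((S - sm) * (Tg - tm))
  zero <- sxx < 1e-12
  foldid <- with_preserved_seed(derive_seed(seed, 1L),
                                sample(rep_len(seq_len(cv_folds), n)))
  models <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    if (zero[i]) {
      models[[i]] <- gene_model(g, g, tm[i], 0, n_train = n,
                                flag = "zero_variance")
    } else if (mode == "ols") {
      w1 <- sxy[i] / sxx[i]
      models[[i]] <- gene_model(g, g, tm[i] - w1 * sm[i], w1, alpha = 0,
                                rho = NA_real_, n_train = n)
    } else {
      f <- en_cv_1d(S[i, ], Tg[i, ], alpha_grid = alpha_grid,
                    rho_grid = rho_grid, foldid = foldid)
      models[[i]] <- gene_model(g, g, f$w0, f$w1, alpha = f$alpha,
                                rho = f$rho, n_train = n)
    }
  }
  new_model_set(models, "EC", "polyA", genes,
                meta = list(method = paste0("sprocrustes_", mode),
                            cv_folds = if (mode == "ols") NA_integer_ else cv_folds,
                            seed = seed, n_train = n,
                            created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
}

#' Fit multi-gene transfer models (mProcrustes)
#'
#' Per gene, an elastic net with cross-validated penalties on predictors =
#' the gene itself plus its co-expression partners (restricted to the
#' paired gene universe). Genes absent from the map fall back to the
#' single-gene cross-validated model. Partner lists longer than
#' `max_predictors - 1` are truncated with a warning.
#'
#' @inheritParams fit_sprocrustes
#' @param coexp a `CoexpressionMap`.
#' @param max_predictors cap on predictors per model (default 60).
#' @param nlambda length of the glmnet penalty path per rho.
#' @return a `ModelSet`.
#' @export
fit_mprocrustes <- function(paired, coexp, cv_folds = 3L,
                            rho_grid = default_rho_grid(),
                            alpha_grid = NULL, max_predictors = 60L,
                            nlambda = 50L, seed = 1L) {
  check_fit_inputs(paired)
  pm <- paired_matrices(paired)
  S <- pm$source; Tg <- pm$target
  n <- ncol(S)
  genes <- rownames(S)
  foldid <- with_preserved_seed(derive_seed(seed, 1L),
                                sample(rep_len(seq_len(cv_folds), n)))
  n_truncated <- 0L
  models <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    partners <- setdiff(intersect(coexp$partners[[g]] %||% character(), genes), g)
    if (length(partners) > max_predictors - 1L) {
      partners <- partners[seq_len(max_predictors - 1L)]
      n_truncated <- n_truncated + 1L
    }
    y <- Tg[i, ]
    if (stats::sd(S[i, ]) == 0 && length(partners) == 0L) {
      models[[i]] <- gene_model(g, g, mean(y), 0, n_train = n,
                                flag = "zero_variance")
      next
    }
    if (length(partners) == 0L) {
      f <- en_cv_1d(S[i, ], y, alpha_grid = alpha_grid, rho_grid = rho_grid,
                    foldid = foldid)
      models[[i]] <- gene_model(g, g, f$w0, f$w1, alpha = f$alpha,
                                rho = f$rho, n_train = n, flag = "single_gene")
      next
    }
    preds <- c(g, partners)
    X <- t(S[preds, , drop = FALSE])
    best <- NULL
    for (rho in rho_grid) {
      cf <- glmnet::cv.glmnet(X, y, alpha = rho, foldid = foldid,
                              nlambda = nlambda, standardize = FALSE,
                              family = "gaussian")
      j <- which.min(cf$cvm)
      if (is.null(best) || cf$cvm[j] < best$cvm) {
        best <- list(cvm = cf$cvm[j], fit = cf, rho = rho,
                     lambda = cf$lambda[j])
      }
    }
    cfv <- as.numeric(stats::coef(best$fit, s = "lambda.min"))
    models[[i]] <- gene_model(g, preds, cfv[1L], cfv[-1L],
                              alpha = best$lambda, rho = best$rho,
                              n_train = n)
  }
  if (n_truncated > 0L) {
    warning(n_truncated, " partner list(s) truncated to max_predictors = ",
            max_predictors, call. = FALSE)
  }
  new_model_set(models, "EC", "polyA", genes,
                meta = list(method = "mprocrustes", cv_folds = cv_folds,
                            seed = seed, n_train = n,
                            rho_grid = rho_grid,
                            created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
}

#' Fit l1-only or l2-only single-gene models (Lasso / Ridge variants)
#'
#' Same single-predictor layout as [fit_sprocrustes()], but the penalty is
#' pure ridge (l2) or pure lasso (l1) with strength selected by grid-search
#' cross-validation.
#'
#' @inheritParams fit_sprocrustes
#' @param penalty `"ridge"` or `"lasso"`.
#' @param grid penalty-strength grid (must be non-empty); default 13
#'   log-spaced values in `[1e-3, 1e3]`.
#' @return a `ModelSet`.
#' @export
fit_penalized_variant <- function(paired, penalty = c("ridge", "lasso"),
                                  grid = 10^seq(-3, 3, length.out = 13),
                                  cv_folds = 3L, seed = 1L) {
  penalty <- match.arg(penalty)
  if (length(grid) == 0L) stop("empty penalty grid", call. = FALSE)
  rho <- if (penalty == "ridge") 0 else 1
  check_fit_inputs(paired)
  pm <- paired_matrices(paired)
  S <- pm$source; Tg <- pm$target
  n <- ncol(S)
  genes <- rownames(S)
  foldid <- with_preserved_seed(derive_seed(seed, 1L),
                                sample(rep_len(seq_len(cv_folds), n)))
  models <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    if (stats::sd(S[i, ]) == 0) {
      models[[i]] <- gene_model(g, g, mean(Tg[i, ]), 0, n_train = n,
                                flag = "zero_variance")
      next
    }
    f <- en_cv_1d(S[i, ], Tg[i, ], alpha_grid = grid, rho_grid = rho,
                  foldid = foldid)
    models[[i]] <- gene_model(g, g, f$w0, f$w1, alpha = f$alpha, rho = rho,
                              n_train = n)
  }
  new_model_set(models, "EC", "polyA", genes,
                meta = list(method = penalty, cv_folds = cv_folds, seed = seed,
                            n_train = n,
                            created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
}

#' Apply a ModelSet to an expression matrix
#'
#' Predicts target-platform log expression gene by gene. Models whose
#' predictors are missing from the input are skipped and reported via the
#' `"skipped_genes"` attribute (never imputed). Predictions are
#' column-wise independent, so a one-column (single-sample) matrix works
#' without any cohort context. Predictions are clipped below at 0 (log2
#' TPM+1 cannot be negative) unless `clip = FALSE`.
#'
#' @param models a `ModelSet`.
#' @param em an `ExpressionMatrix` in `LOG2_TPM_PLUS1` space.
#' @param clip clip predictions below at 0 (default `TRUE`).
#' @return an `ExpressionMatrix` (`LOG2_TPM_PLUS1`) over the transformed
#'   genes, with attribute `skipped_genes`.
#' @export
transform_expression <- function(models, em, clip = TRUE) {
  if (em$unit != "LOG2_TPM_PLUS1") {
    stop("transform requires LOG2_TPM_PLUS1 input, got ", em$unit,
         call. = FALSE)
  }
  v <- em$values
  avail <- rownames(v)
  out <- matrix(NA_real_, nrow = length(models$models), ncol = ncol(v),
                dimnames = list(names(models$models), colnames(v)))
  skipped <- character()
  keep <- logical(length(models$models))
  for (i in seq_along(models$models)) {
    gm <- models$models[[i]]
    if (!all(gm$predictors %in% avail)) {
      skipped <- c(skipped, gm$gene_id)
      next
    }
    keep[i] <- TRUE
    pred <- gm$w0
    if (length(gm$predictors) > 0L && any(gm$w != 0)) {
      pred <- pred + colSums(v[gm$predictors, , drop = FALSE] * gm$w)
    } else {
      pred <- rep(pred, ncol(v))
    }
    out[i, ] <- pred
  }
  out <- out[keep, , drop = FALSE]
  if (clip) out <- pmax(out, 0)
  res <- new_expression_matrix(out, "LOG2_TPM_PLUS1")
  attr(res, "skipped_genes") <- skipped
  res
}

# --- baseline correctors ------------------------------------------------

#' Per-gene batch moments
#'
#' Mean and population (1/n) standard deviation per gene for one batch.
#'
#' @param em an `ExpressionMatrix`.
#' @param batch batch name.
#' @return a `BatchMoments`: list with `batch`, `mean`, `sd`.
#' @export
batch_moments <- function(em, batch = "batch") {
  v <- em$values
  structure(list(batch = batch,
                 mean = rowMeans(v),
                 sd = row_pop_sd(v)),
            class = "BatchMoments")
}

#' @export
print.BatchMoments <- function(x, ...) {
  cat(sprintf("BatchMoments '%s': %d genes\n", x$batch, length(x$mean)))
  invisible(x)
}

moment_vector <- function(x, field) {
  if (inherits(x, "BatchMoments")) return(x[[field]])
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("expected a BatchMoments object or a named numeric vector",
       call. = FALSE)
}

#' Z-score baseline transform
#'
#' Standardizes each gene by the source-batch moments and rescales to the
#' target-batch moments:
#' `out = ((x - mu_src) / sd_src) * sd_tgt + mu_tgt`. Genes with zero
#' source standard deviation are passed through as `mu_tgt` with a
#' warning.
#'
#' @param em `ExpressionMatrix` to transform.
#' @param source `BatchMoments` of the source batch (training data).
#' @param target `BatchMoments` of the target batch (training data).
#' @return an `ExpressionMatrix` in the same unit.
#' @export
zscore_transform <- function(em, source, target) {
  mu_s <- moment_vector(source, "mean"); sd_s <- moment_vector(source, "sd")
  mu_t <- moment_vector(target, "mean"); sd_t <- moment_vector(target, "sd")
  genes <- rownames(em$values)
  genes <- genes[genes %in% names(mu_s) & genes %in% names(mu_t)]
  if (length(genes) < nrow(em$values)) {
    warning(nrow(em$values) - length(genes),
            " gene(s) without batch moments dropped", call. = FALSE)
  }
  v <- em$values[genes, , drop = FALSE]
  s <- sd_s[genes]
  degenerate <- s == 0
  if (any(degenerate)) {
    warning(sum(degenerate),
            " gene(s) with zero source SD passed through as target mean",
            call. = FALSE)
  }
  z <- (v - mu_s[genes]) / ifelse(degenerate, 1, s)
  z[degenerate, ] <- 0
  out <- z * sd_t[genes] + mu_t[genes]
  # no clipping: the transform is the plain moment-matching formula
  new_expression_matrix(out, em$unit)
}

#' Batch mean centering (BMC) baseline transform
#'
#' `out = x - mu_src + mu_tgt` per gene.
#'
#' @param em `ExpressionMatrix` to transform.
#' @param source_means `BatchMoments` or named numeric vector of
#'   source-batch per-gene means.
#' @param target_means likewise for the target batch.
#' @return an `ExpressionMatrix` in the same unit.
#' @export
bmc_transform <- function(em, source_means, target_means) {
  mu_s <- moment_vector(source_means, "mean")
  mu_t <- moment_vector(target_means, "mean")
  genes <- rownames(em$values)
  genes <- genes[genes %in% names(mu_s) & genes %in% names(mu_t)]
  if (length(genes) < nrow(em$values)) {
    warning(nrow(em$values) - length(genes),
            " gene(s) without batch means dropped", call. = FALSE)
  }
  v <- em$values[genes, , drop = FALSE]
  out <- v - mu_s[genes] + mu_t[genes]
  new_expression_matrix(out, em$unit)
}

#' Per-gene coefficient-scaling baseline transform (DASC-style)
#'
#' Scales each gene by `m/d` from an externally supplied (n x 2)
#' coefficient table, then applies the clipping rule: values below zero
#' are set to zero, and values higher than mean + 3 sd are clipped to
#' mean + 3 sd, where mean and sd (population) are computed per gene over
#' the scaled values of the matrix at hand. Genes with `d = 0` are skipped
#' with a warning; genes without coefficients are dropped.
#'
#' @param em `ExpressionMatrix` to transform.
#' @param coeffs data.frame with columns `gene`, `m`, `d`.
#' @return an `ExpressionMatrix` in the same unit.
#' @export
dasc_transform <- function(em, coeffs) {
  if (!all(c("gene", "m", "d") %in% names(coeffs))) {
    stop("coeffs must have columns gene, m, d", call. = FALSE)
  }
  cf <- coeffs[!duplicated(coeffs$gene), ]
  rownames(cf) <- cf$gene
  genes <- rownames(em$values)
  genes <- genes[genes %in% cf$gene]
  bad <- genes[cf[genes, "d"] == 0]
  if (length(bad) > 0L) {
    warning(length(bad), " gene(s) skipped: d = 0", call. = FALSE)
    genes <- setdiff(genes, bad)
  }
  v <- em$values[genes, , drop = FALSE]
  scaled <- v * (cf[genes, "m"] / cf[genes, "d"])
  mu <- rowMeans(scaled)
  sd3 <- mu + 3 * row_pop_sd(scaled)
  scaled[scaled < 0] <- 0
  over <- scaled > sd3
  scaled[over] <- (matrix(sd3, nrow = nrow(scaled), ncol = ncol(scaled)))[over]
  new_expression_matrix(scaled, em$unit)
}

# --- serialization ------------------------------------------------------

#' Save / load a ModelSet
#'
#' TSV with one row per gene (`gene`, `intercept`, `alpha`, `rho`,
#' `n_train`, `flag`, and `terms` as `predictor:weight` pairs joined by
#' `;`), plus a JSON metadata sidecar `<path>.meta.json`. Numbers are
#' written with 17 significant digits so a reloaded model produces
#' bit-identical predictions.
#'
#' @param models a `ModelSet`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_model_set <- function(models, path) {
  rows <- lapply(models$models, function(m) {
    data.frame(gene = m$gene_id,
               intercept = format_full(m$w0),
               alpha = format_full(m$alpha),
               rho = format_full(m$rho),
               n_train = m$n_train,
               flag = m$flag,
               terms = paste(sprintf("%s:%s", m$predictors,
                                     vapply(m$w, format_full, "")),
                             collapse = ";"),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(models$meta,
            list(source_platform = models$source_platform,
                 target_platform = models$target_platform,
                 gene_universe = models$gene_universe))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_model_set
#' @export
read_model_set <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  models <- lapply(seq_len(nrow(df)), function(i) {
    terms <- strsplit(df$terms[i], ";", fixed = TRUE)[[1L]]
    parts <- strsplit(terms, ":", fixed = TRUE)
    preds <- vapply(parts, `[[`, "", 1L)
    w <- as.numeric(vapply(parts, `[[`, "", 2L))
    gene_model(df$gene[i], preds, as.numeric(df$intercept[i]), w,
               alpha = as.numeric(df$alpha[i]), rho = as.numeric(df$rho[i]),
               n_train = as.integer(df$n_train[i]), flag = df$flag[i])
  })
  meta_path <- paste0(path, ".meta.json")
  meta <- list(); source_platform <- "EC"; target_platform <- "polyA"
  universe <- df$gene
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    source_platform <- meta$source_platform %||% source_platform
    target_platform <- meta$target_platform %||% target_platform
    universe <- meta$gene_universe %||% universe
    meta$source_platform <- meta$target_platform <- meta$gene_universe <- NULL
  }
  new_model_set(models, source_platform, target_platform, universe, meta)
}
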