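#' Per-gene unit scaling and cohort medians
#'
#' Min-max scales every gene to `[0, 1]` across all samples within each
#' source group (e.g. scaling tumor and normal compendia separately),
#' then summarizes each cohort by its per-gene median of scaled values.
#' Genes constant within a group scale to 0 with a warning.
#'
#' @param cohorts named list of `ExpressionMatrix` objects
#'   (`LOG2_TPM_PLUS1`), all over the same gene set.
#' @param source_group optional named character vector mapping cohort name
#'   to its source group; default puts every cohort in one group.
#' @return a `ScaledCohortSet`: list with `cohorts` (per cohort: `name`,
#'   `group`, `n_samples`, `medians`) and `genes`.
#' @export
scale_unit_per_gene <- function(cohorts, source_group = NULL) {
  if (length(cohorts) == 0L) stop("no cohorts", call. = FALSE)
  if (is.null(names(cohorts))) {
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  }
  for (em in cohorts) {
    if (em$unit != "LOG2_TPM_PLUS1") {
      stop("scaling expects LOG2_TPM_PLUS1 cohorts", call. = FALSE)
    }
  }
  genes <- rownames(cohorts[[1L]]$values)
  for (nm in names(cohorts)) {
    if (!identical(rownames(cohorts[[nm]]$values), genes)) {
      stop("cohort '", nm, "' has a different gene set/order", call. = FALSE)
    }
  }
  if (is.null(source_group)) {
    source_group <- stats::setNames(rep("all", length(cohorts)), names(cohorts))
  }
  missing <- setdiff(names(cohorts), names(source_group))
  if (length(missing) > 0L) {
    stop("source_group missing for cohort(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- list()
  n_constant <- 0L
  for (grp in unique(source_group[names(cohorts)])) {
    members <- names(cohorts)[source_group[names(cohorts)] == grp]
    combined <- do.call(cbind, lapply(cohorts[members], function(e) e$values))
    lo <- apply(combined, 1L, min)
    hi <- apply(combined, 1L, max)
    rng <- hi - lo
    constant <- rng == 0
    n_constant <- n_constant + sum(constant)
    rng[constant] <- 1
    for (nm in members) {
      scaled <- (cohorts[[nm]]$values - lo) / rng
      scaled[constant, ] <- 0
      out[[nm]] <- list(name = nm, group = grp,
                        n_samples = ncol(scaled),
                        medians = apply(scaled, 1L, stats::median))
    }
  }
  if (n_constant > 0L) {
    warning(n_constant, " constant gene/group combination(s) scaled to 0",
            call. = FALSE)
  }
  structure(list(cohorts = out[names(cohorts)], genes = genes),
            class = "ScaledCohortSet")
}

#' @export
print.ScaledCohortSet <- function(x, ...) {
  cat(sprintf("ScaledCohortSet: %d cohorts, %d genes\n",
              length(x$cohorts), length(x$genes)))
  invisible(x)
}

#' Tissue-specific gene calling
#'
#' A gene is tissue specific for the selected cohorts when its median
#' scaled expression is at least `hi` (inclusive) in every selected
#' cohort and strictly below `lo` in every remaining cohort.
#'
#' @param scaled a `ScaledCohortSet`.
#' @param selected non-empty character vector of selected cohort names.
#' @param hi inclusive lower bound for selected cohorts (default 0.5).
#' @param lo exclusive upper bound for the remaining cohorts (default
#'   0.2).
#' @param min_samples optionally drop cohorts with fewer samples from
#'   consideration before applying the rule (canonically, undersized
#'   cohorts are excluded upstream when the set is built).
#' @return character vector of tissue-specific gene ids.
#' @export
tissue_specific_genes <- function(scaled, selected, hi = 0.5, lo = 0.2,
                                  min_samples = NULL) {
  if (length(selected) == 0L) stop("empty selected cohort set", call. = FALSE)
  cohorts <- scaled$cohorts
  if (!is.null(min_samples)) {
    sizes <- vapply(cohorts, `[[`, 0, "n_samples")
    dropped <- names(cohorts)[sizes < min_samples]
    if (length(dropped) > 0L) {
      warning("cohort(s) below min_samples dropped: ",
              paste(dropped, collapse = ", "), call. = FALSE)
    }
    cohorts <- cohorts[sizes >= min_samples]
  }
  unknown <- setdiff(selected, names(cohorts))
  if (length(unknown) > 0L) {
    stop("unknown selected cohort(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  med <- do.call(cbind, lapply(cohorts, function(co)
    co$medians[scaled$genes]))
  rownames(med) <- scaled$genes
  sel <- med[, selected, drop = FALSE]
  rest <- med[, setdiff(colnames(med), selected), drop = FALSE]
  ok_sel <- apply(sel >= hi, 1L, all)
  ok_rest <- if (ncol(rest) == 0L) rep(TRUE, nrow(med)) else
    apply(rest < lo, 1L, all)
  scaled$genes[ok_sel & ok_rest]
}

#' Stratified train/holdout split
#'
#' Splits samples into train and holdout with cohort proportions
#' preserved: per-cohort holdout counts follow the largest-remainder
#' method so the global holdout fraction is respected. Cohorts of size 1
#' go to train with a warning; cohorts of size >= 2 always keep at least
#' one training sample. Deterministic given `seed`.
#'
#' @param labels named character vector mapping sample id to cohort.
#' @param holdout_fraction fraction in (0, 1).
#' @param seed RNG seed for within-cohort sampling.
#' @return list with `train` and `holdout` character vectors of sample
#'   ids.
#' @export
stratified_split <- function(labels, holdout_fraction, seed = 1L) {
  if (is.null(names(labels))) stop("'labels' must be named", call. = FALSE)
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("holdout_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- length(labels)
  counts <- table(labels)
  cohorts <- sort(names(counts))
  quota <- holdout_fraction * as.numeric(counts[cohorts])
  base <- floor(quota)
  target <- round(holdout_fraction * n)
  leftover <- target - sum(base)
  if (leftover > 0) {
    frac <- quota - base
    ord <- order(-frac, cohorts)  # largest remainder, ties by name
    take <- ord[seq_len(min(leftover, length(ord)))]
    base[take] <- base[take] + 1
  }
  # never hold out a full cohort; singletons stay in train
  sizes <- as.numeric(counts[cohorts])
  singles <- cohorts[sizes == 1L & base > 0]
  if (length(singles) > 0L) {
    warning("cohort(s) of size 1 assigned to train: ",
            paste(singles, collapse = ", "), call. = FALSE)
  }
  base <- pmin(base, pmax(sizes - 1L, 0L))
  holdout <- character(0)
  with_preserved_seed(derive_seed(seed, 2L), {
    for (i in seq_along(cohorts)) {
      ids <- names(labels)[labels == cohorts[i]]
      if (base[i] > 0) {
        holdout <- c(holdout, sort(ids)[sample.int(length(ids), base[i])])
      }
    }
  })
  list(train = setdiff(names(labels), holdout), holdout = holdout)
}
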