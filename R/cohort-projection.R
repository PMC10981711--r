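#' Fit a reference projection space
#'
#' Centers the reference cohort per gene, computes a truncated SVD basis
#' (exact or randomized with subspace iteration), projects the reference
#' samples, and stores per-cohort class-mean centroids for
#' nearest-centroid assignment. Only the per-gene mean is removed; no
#' variance scaling (available via `scale_genes = TRUE`).
#'
#' @param reference an `ExpressionMatrix` in `LOG2_TPM_PLUS1` space.
#' @param labels named character vector mapping every reference sample id
#'   to its cohort.
#' @param n_components number of components (<= min(genes, samples)).
#' @param method `"exact"` or `"randomized"`.
#' @param scale_genes also divide each centered gene by its SD.
#' @param seed seed for the randomized range finder, recorded.
#' @param n_oversample,n_iter randomized-SVD oversampling and subspace
#'   iterations.
#' @return a `ProjectionSpace`: list with `basis` (genes x k, orthonormal
#'   columns), `center`, `scale`, `centroids` (cohorts x k), `labels`,
#'   `n_components`, `singular_values`, `method`, `seed`.
#' @export
fit_reference_space <- function(reference, labels, n_components,
                                method = c("exact", "randomized"),
                                scale_genes = FALSE, seed = 1L,
                                n_oversample = 10L, n_iter = 2L) {
  method <- match.arg(method)
  if (reference$unit != "LOG2_TPM_PLUS1") {
    stop("projection requires LOG2_TPM_PLUS1 input, got ", reference$unit,
         call. = FALSE)
  }
  v <- reference$values
  if (n_components > min(dim(v))) {
    stop("n_components exceeds min(genes, samples)", call. = FALSE)
  }
  samples <- colnames(v)
  if (!all(samples %in% names(labels))) {
    stop("labels missing for samples: ",
         paste(utils::head(setdiff(samples, names(labels)), 5L),
               collapse = ", "), call. = FALSE)
  }
  lab <- labels[samples]
  small <- names(which(table(lab) < 2L))
  if (length(small) > 0L) {
    warning("cohort(s) with < 2 samples: ", paste(small, collapse = ", "),
            call. = FALSE)
  }
  center <- rowMeans(v)
  X <- v - center
  scl <- rep(1, nrow(v))
  names(scl) <- rownames(v)
  if (scale_genes) {
    scl <- row_pop_sd(v)
    scl[scl == 0] <- 1
    X <- X / scl
  }
  if (method == "exact") {
    sv <- svd(X, nu = n_components, nv = 0L)
    basis <- sv$u
    d <- sv$d[seq_len(n_components)]
  } else {
    rs <- randomized_svd_basis(X, n_components, n_oversample, n_iter, seed)
    basis <- rs$u
    d <- rs$d
  }
  dimnames(basis) <- list(rownames(v), paste0("PC", seq_len(n_components)))
  coords <- crossprod(X, basis)
  rownames(coords) <- samples
  centroids <- rowsum(coords, lab) / as.numeric(table(lab)[sort(unique(lab))])
  structure(list(basis = basis, center = center, scale = scl,
                 scale_genes = scale_genes,
                 centroids = centroids, labels = lab,
                 n_components = n_components, singular_values = d,
                 method = method, seed = seed),
            class = "ProjectionSpace")
}

# randomized range finder with subspace (power) iterations and
# re-orthogonalization at every step
randomized_svd_basis <- function(X, k, n_oversample, n_iter, seed) {
  l <- min(k + n_oversample, min(dim(X)))
  Omega <- with_preserved_seed(seed,
                               matrix(stats::rnorm(ncol(X) * l), ncol(X), l))
  Q <- qr.Q(qr(X %*% Omega))
  for (i in seq_len(n_iter)) {
    Q <- qr.Q(qr(crossprod(X, Q)))
    Q <- qr.Q(qr(X %*% Q))
  }
  B <- crossprod(Q, X)
  sb <- svd(B, nu = k, nv = 0L)
  list(u = Q %*% sb$u, d = sb$d[seq_len(k)])
}

#' @export
print.ProjectionSpace <- function(x, ...) {
  cat(sprintf("ProjectionSpace: %d genes, %d components (%s SVD), %d cohorts\n",
              nrow(x$basis), x$n_components, x$method, nrow(x$centroids)))
  invisible(x)
}

#' Project samples into a frozen reference space
#'
#' Centers by the stored per-gene offsets and multiplies by the basis. The
#' input must contain every reference gene (missing genes are an error,
#' never imputed); extra genes are ignored and row order is matched by id.
#' A one-column matrix (single sample) projects the same way.
#'
#' @param space a `ProjectionSpace`.
#' @param em an `ExpressionMatrix` in `LOG2_TPM_PLUS1` space.
#' @return numeric coordinate matrix, samples x n_components.
#' @export
project_samples <- function(space, em) {
  if (em$unit != "LOG2_TPM_PLUS1") {
    stop("projection requires LOG2_TPM_PLUS1 input, got ", em$unit,
         call. = FALSE)
  }
  need <- rownames(space$basis)
  missing <- setdiff(need, rownames(em$values))
  if (length(missing) > 0L) {
    stop("input lacks ", length(missing), " reference gene(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ..." else "", call. = FALSE)
  }
  v <- em$values[need, , drop = FALSE]
  X <- (v - space$center)
  if (isTRUE(space$scale_genes)) X <- X / space$scale
  crossprod(X, space$basis)
}

#' Distances from projected samples to every cohort centroid
#'
#' @param space a `ProjectionSpace`.
#' @param coords coordinate matrix from [project_samples()].
#' @return matrix samples x cohorts of Euclidean distances.
#' @export
centroid_distances <- function(space, coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != space$n_components) {
    stop("coordinate dimension != n_components", call. = FALSE)
  }
  cent <- space$centroids
  d2 <- outer(rowSums(coords^2), rowSums(cent^2), "+") -
    2 * coords %*% t(cent)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  dimnames(d) <- list(rownames(coords), rownames(cent))
  d
}

#' Nearest-centroid cohort assignment
#'
#' Assigns every projected sample to the cohort whose class-mean centroid
#' is closest in Euclidean distance. Exact ties are broken by
#' lexicographically first cohort name, with a warning.
#'
#' @param space a `ProjectionSpace`.
#' @param coords coordinate matrix from [project_samples()].
#' @return data.frame with columns `sample`, `cohort`, `distance`.
#' @export
assign_nearest <- function(space, coords) {
  d <- centroid_distances(space, coords)
  cohorts <- colnames(d)[order(colnames(d))]
  d <- d[, cohorts, drop = FALSE]  # lexicographic order so ties pick first
  idx <- apply(d, 1L, which.min)
  mins <- d[cbind(seq_len(nrow(d)), idx)]
  n_tied <- sum(apply(d, 1L, function(r) sum(r == min(r)) > 1L))
  if (n_tied > 0L) {
    warning(n_tied, " sample(s) equidistant from multiple centroids; ",
            "lexicographically first cohort chosen", call. = FALSE)
  }
  data.frame(sample = rownames(d) %||% as.character(seq_len(nrow(d))),
             cohort = cohorts[idx], distance = mins,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Percentage overlap between predicted and expected cohort labels
#'
#' @param predicted,expected character vectors of equal, non-zero length.
#' @return percentage of matching positions (0-100).
#' @export
mapping_overlap <- function(predicted, expected) {
  if (length(predicted) == 0L) stop("empty input", call. = FALSE)
  if (length(predicted) != length(expected)) {
    stop("length mismatch", call. = FALSE)
  }
  100 * mean(predicted == expected)
}

#' Persist / load a projection space
#'
#' Writes a directory of plain-text files: `basis.tsv`, `offsets.tsv`
#' (per-gene center and scale), `centroids.tsv`, and `meta.json`. Numbers
#' carry 17 significant digits.
#'
#' @param space a `ProjectionSpace`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_projection_space <- function(space, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt_mat <- function(m) {
    apply(m, 2L, format_full)
  }
  bdf <- data.frame(gene = rownames(space$basis), fmt_mat(space$basis),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(bdf, file.path(dir, "basis.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  odf <- data.frame(gene = names(space$center),
                    center = vapply(space$center, format_full, ""),
                    scale = vapply(space$scale, format_full, ""),
                    stringsAsFactors = FALSE)
  utils::write.table(odf, file.path(dir, "offsets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cdf <- data.frame(cohort = rownames(space$centroids),
                    fmt_mat(space$centroids),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cdf, file.path(dir, "centroids.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_components = space$n_components, method = space$method,
         seed = space$seed, scale_genes = space$scale_genes,
         singular_values = space$singular_values,
         labels = as.list(space$labels)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_projection_space
#' @export
read_projection_space <- function(dir) {
  bdf <- utils::read.delim(file.path(dir, "basis.tsv"), check.names = FALSE)
  basis <- as.matrix(bdf[, -1L, drop = FALSE])
  rownames(basis) <- bdf$gene
  odf <- utils::read.delim(file.path(dir, "offsets.tsv"))
  center <- stats::setNames(odf$center, odf$gene)
  scl <- stats::setNames(odf$scale, odf$gene)
  cdf <- utils::read.delim(file.path(dir, "centroids.tsv"),
                           check.names = FALSE)
  centroids <- as.matrix(cdf[, -1L, drop = FALSE])
  rownames(centroids) <- cdf$cohort
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  structure(list(basis = basis, center = center, scale = scl,
                 scale_genes = isTRUE(meta$scale_genes),
                 centroids = centroids,
                 labels = unlist(meta$labels),
                 n_components = meta$n_components,
                 singular_values = meta$singular_values,
                 method = meta$method, seed = meta$seed),
            class = "ProjectionSpace")
}
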