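#' Expression matrix container
#'
#' Genes-as-rows, samples-as-columns numeric matrix with a declared unit.
#' All per-gene statistics in this package are row statistics; all model
#' fitting and evaluation happen in `LOG2_TPM_PLUS1` space.
#'
#' Units:
#' * `TPM` — transcripts per million; every sample column sums to 1e6
#'   (checked at construction with relative tolerance 1e-6).
#' * `LOG2_TPM_PLUS1` — `log2(TPM + 1)`; all values are non-negative.
#' * `RAW_ABUNDANCE` — arbitrary non-negative abundance, e.g. estimated
#'   counts before within-sample normalization.
#'
#' @param values numeric matrix with unique rownames (gene ids) and unique
#'   colnames (sample ids); no negative values, no `NA`.
#' @param unit one of `"TPM"`, `"LOG2_TPM_PLUS1"`, `"RAW_ABUNDANCE"`.
#' @return an `ExpressionMatrix`: a list with elements `values` and `unit`.
#' @examples
#' m <- matrix(c(2e5, 8e5, 3e5, 7e5), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' em <- expression_matrix(m, "TPM")
#' @export
expression_matrix <- function(values, unit = c("TPM", "LOG2_TPM_PLUS1", "RAW_ABUNDANCE")) {
  unit <- match.arg(unit)
  em <- new_expression_matrix(values, unit)
  validate_expression_matrix(em)
  em
}

# internal constructor without the unit-sum invariant, used where derived
# objects (e.g. gene subsets of a TPM matrix) legitimately break it
new_expression_matrix <- function(values, unit) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have gene rownames and sample colnames", call. = FALSE)
  }
  structure(list(values = values, unit = unit), class = "ExpressionMatrix")
}

#' Validate an ExpressionMatrix against its invariants
#'
#' Checks identifier uniqueness, non-negativity, and (for `TPM`) that each
#' sample column sums to 1e6 within relative tolerance 1e-6.
#'
#' @param em an `ExpressionMatrix`.
#' @return `em`, invisibly; errors on violation.
#' @export
validate_expression_matrix <- function(em) {
  v <- em$values
  if (anyDuplicated(rownames(v))) {
    stop("duplicate gene ids: ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(v))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(v)) stop("expression values contain NA", call. = FALSE)
  if (any(v < 0)) stop("expression values must be non-negative", call. = FALSE)
  if (em$unit == "TPM" && nrow(v) > 0L) {
    cs <- colSums(v)
    bad <- abs(cs - 1e6) > 1e-6 * 1e6
    if (any(bad)) {
      stop("TPM columns must sum to 1e6; offending samples: ",
           paste(colnames(v)[bad], collapse = ", "), call. = FALSE)
    }
  }
  invisible(em)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an ExpressionMatrix
#' @param em an `ExpressionMatrix`.
#' @return character vector of ids.
#' @export
gene_ids <- function(em) rownames(em$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(em) colnames(em$values)

#' Read an expression matrix from TSV
#'
#' Expects a UTF-8 tab-delimited file whose header row holds sample ids,
#' whose first column holds gene ids (conventionally headed `gene`), and
#' whose body is numeric.
#'
#' @param path path to a TSV file.
#' @param unit declared unit of the stored values (see
#'   [expression_matrix()]).
#' @return an `ExpressionMatrix`.
#' @export
read_expression_matrix <- function(path, unit = c("TPM", "LOG2_TPM_PLUS1", "RAW_ABUNDANCE")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("no sample columns in ", path, call. = FALSE)
  if (nrow(df) == 0L) stop("no genes in ", path, call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s' in %s",
                 body[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]],
                 colnames(body)[bad[1L, 2L]], path), call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(body))
  expression_matrix(num, unit)
}

#' Write an expression matrix to TSV
#'
#' @param em an `ExpressionMatrix`.
#' @param path output path; the gene-id column is headed `gene`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path) {
  df <- data.frame(gene = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Renormalize to TPM over a gene universe
#'
#' Restricts the matrix to `gene_universe` and rescales each sample column
#' to sum to 1e6. Accepts `TPM` or `RAW_ABUNDANCE` input.
#'
#' @param em an `ExpressionMatrix` with unit `TPM` or `RAW_ABUNDANCE`.
#' @param gene_universe character vector of gene ids, a subset of the
#'   matrix genes; `NULL` keeps all genes.
#' @return an `ExpressionMatrix` with unit `TPM`.
#' @export
tpm_renormalize <- function(em, gene_universe = NULL) {
  if (!em$unit %in% c("TPM", "RAW_ABUNDANCE")) {
    stop("tpm_renormalize requires unit TPM or RAW_ABUNDANCE, got ", em$unit,
         call. = FALSE)
  }
  genes <- rownames(em$values)
  if (is.null(gene_universe)) gene_universe <- genes
  gene_universe <- unique(as.character(gene_universe))
  missing <- setdiff(gene_universe, genes)
  if (length(missing) == length(gene_universe)) {
    stop("gene_universe is disjoint from the matrix genes", call. = FALSE)
  }
  if (length(missing) > 0L) {
    stop("gene_universe contains ids absent from the matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ..." else "", call. = FALSE)
  }
  keep <- genes[genes %in% gene_universe]
  v <- em$values[keep, , drop = FALSE]
  cs <- colSums(v)
  if (any(cs == 0)) {
    stop("all-zero sample column(s) after restriction: ",
         paste(colnames(v)[cs == 0], collapse = ", "), call. = FALSE)
  }
  v <- sweep(v, 2L, cs / 1e6, "/")
  expression_matrix(v, "TPM")
}

#' Log2(x + 1) transform and its inverse
#'
#' The forward transform maps `TPM` values to `log2(TPM + 1)`
#' (`LOG2_TPM_PLUS1`). The inverse maps back with `2^v - 1`, clipped below
#' at 0, and returns unit `RAW_ABUNDANCE` (back-transformed model output
#' need not sum to 1e6 per column; use [tpm_renormalize()] to restore TPM).
#'
#' @param em an `ExpressionMatrix`.
#' @param inverse apply the inverse transform.
#' @return an `ExpressionMatrix`.
#' @export
log_transform <- function(em, inverse = FALSE) {
  if (inverse) {
    if (em$unit != "LOG2_TPM_PLUS1") {
      stop("inverse log_transform requires unit LOG2_TPM_PLUS1, got ", em$unit,
           call. = FALSE)
    }
    v <- pmax(2^em$values - 1, 0)
    return(new_expression_matrix(v, "RAW_ABUNDANCE"))
  }
  if (em$unit != "TPM") {
    stop("log_transform requires unit TPM, got ", em$unit, call. = FALSE)
  }
  new_expression_matrix(log2(em$values + 1), "LOG2_TPM_PLUS1")
}

#' Align two platforms into a paired cohort
#'
#' Restricts both matrices to their common gene universe (source row order)
#' and records the sample pairing. Unpaired samples are retained in the
#' matrices but only paired columns are used by fitting and evaluation.
#' When genes are dropped from a `TPM` matrix the declared unit is kept;
#' re-run [tpm_renormalize()] if strict TPM column sums matter downstream.
#'
#' @param source `ExpressionMatrix` for the source platform (e.g. exome
#'   capture).
#' @param target `ExpressionMatrix` for the target platform (e.g. poly-A).
#' @param pairing data.frame with character columns `source` and `target`
#'   giving paired sample ids; must be a bijection between the declared
#'   paired subsets.
#' @param cohort_labels optional named character vector mapping sample ids
#'   (either platform) to cohort / cancer-type labels.
#' @return a `PairedCohort`: list with `source`, `target`, `pairs`,
#'   `cohort_labels`.
#' @export
align_paired <- function(source, target, pairing, cohort_labels = NULL) {
  if (source$unit != target$unit) {
    stop("source and target units differ: ", source$unit, " vs ", target$unit,
         call. = FALSE)
  }
  if (!is.data.frame(pairing) || !all(c("source", "target") %in% names(pairing))) {
    stop("'pairing' must be a data.frame with columns 'source' and 'target'",
         call. = FALSE)
  }
  pairing <- data.frame(source = as.character(pairing$source),
                        target = as.character(pairing$target),
                        stringsAsFactors = FALSE)
  unknown_s <- setdiff(pairing$source, sample_ids(source))
  unknown_t <- setdiff(pairing$target, sample_ids(target))
  if (length(unknown_s) || length(unknown_t)) {
    stop("pairing references unknown samples: ",
         paste(c(unknown_s, unknown_t), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(pairing$source) || anyDuplicated(pairing$target)) {
    stop("pairing must be a bijection: duplicated sample reference",
         call. = FALSE)
  }
  common <- intersect(gene_ids(source), gene_ids(target))
  if (length(common) == 0L) stop("empty gene intersection", call. = FALSE)
  keep <- gene_ids(source)[gene_ids(source) %in% common]
  src <- new_expression_matrix(source$values[keep, , drop = FALSE], source$unit)
  tgt <- new_expression_matrix(target$values[keep, , drop = FALSE], target$unit)
  structure(list(source = src, target = tgt, pairs = pairing,
                 cohort_labels = cohort_labels),
            class = "PairedCohort")
}

#' @export
print.PairedCohort <- function(x, ...) {
  cat(sprintf("PairedCohort: %d genes, %d pairs (%d/%d samples) [%s]\n",
              nrow(x$source$values), nrow(x$pairs),
              ncol(x$source$values), ncol(x$target$values), x$source$unit))
  invisible(x)
}

#' Number of sample pairs in a paired cohort
#' @param paired a `PairedCohort`.
#' @return integer.
#' @export
n_pairs <- function(paired) nrow(paired$pairs)

# paired columns as plain matrices, aligned pair-by-pair
paired_matrices <- function(paired) {
  list(source = paired$source$values[, paired$pairs$source, drop = FALSE],
       target = paired$target$values[, paired$pairs$target, drop = FALSE])
}

#' Replace the source side of a paired cohort by its model transform
#'
#' Convenience for before/after evaluation: applies a [ModelSet] to the
#' source matrix and returns a `PairedCohort` of (transformed source,
#' target), restricted to the transformed genes.
#'
#' @param paired a `PairedCohort` in log space.
#' @param models a `ModelSet`.
#' @return a `PairedCohort`.
#' @export
transform_paired <- function(paired, models) {
  tr <- transform_expression(models, paired$source)
  align_paired(tr, paired$target, paired$pairs, paired$cohort_labels)
}
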