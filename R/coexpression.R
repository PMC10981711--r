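#' Most correlated partner genes for one gene
#'
#' Ranks all other genes by correlation with `gene` across samples and
#' returns up to `k` partners whose correlation is at least `r_min`.
#' Zero-variance genes are skipped (their correlation is undefined and
#' treated as -Inf in the ranking). Ties are broken by descending r, then
#' lexicographic gene id.
#'
#' @param em an `ExpressionMatrix` with at least 3 samples; co-expression
#'   is conventionally computed in `LOG2_TPM_PLUS1` space.
#' @param gene target gene id.
#' @param k maximum number of partners.
#' @param r_min minimum correlation (default 0.7).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame with columns `partner`, `r`, ordered by rank; empty
#'   (with a warning) when the target gene has zero variance.
#' @export
top_correlated <- function(em, gene, k = 5L, r_min = 0.7,
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  v <- em$values
  if (ncol(v) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (!gene %in% rownames(v)) stop("gene not in matrix: ", gene, call. = FALSE)
  x <- v[gene, ]
  if (stats::sd(x) == 0) {
    warning("target gene has zero variance: ", gene, call. = FALSE)
    return(data.frame(partner = character(), r = numeric(),
                      stringsAsFactors = FALSE))
  }
  r <- suppressWarnings(as.numeric(stats::cor(x, t(v), method = method)))
  names(r) <- rownames(v)
  r <- r[names(r) != gene]
  r[!is.finite(r)] <- -Inf
  rank_partners(r, k, r_min)
}

# shared ranking rule: r >= r_min, descending r then lexicographic id, top k
rank_partners <- function(r, k, r_min) {
  keep <- is.finite(r) & r >= r_min
  r <- r[keep]
  if (length(r) == 0L) {
    return(data.frame(partner = character(), r = numeric(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(-r, names(r))
  r <- r[ord]
  n <- min(k, length(r))
  data.frame(partner = names(r)[seq_len(n)], r = as.numeric(r)[seq_len(n)],
             stringsAsFactors = FALSE)
}

#' Build a co-expression map from cohorts and a reference
#'
#' For every gene, nominates the top `k_cohort` correlated genes (r >=
#' `r_min`) from each eligible cohort and the top `k_reference` from the
#' reference matrix, then merges the nominations into one deduplicated
#' partner list per gene. Cohorts with fewer than `min_samples` samples
#' are skipped with a warning. Genes with no partner anywhere are absent
#' from the map (downstream model fitting falls back to the single-gene
#' model). Partner lists are sorted lexicographically so the map is
#' invariant to cohort input order.
#'
#' @param cohorts list of `ExpressionMatrix` objects (named list names are
#'   used as provenance labels).
#' @param reference optional reference `ExpressionMatrix`.
#' @param k_cohort partners nominated per cohort (default 5).
#' @param k_reference partners nominated by the reference (default 10).
#' @param r_min minimum correlation (default 0.7).
#' @param min_samples minimum cohort size (default 50).
#' @param method correlation method.
#' @return a `CoexpressionMap`: list with `partners` (named list of
#'   character vectors), `provenance` (data.frame `gene`, `partner`,
#'   `source`, `r`) and `params`.
#' @export
build_coexpression_map <- function(cohorts = list(), reference = NULL,
                                   k_cohort = 5L, k_reference = 10L,
                                   r_min = 0.7, min_samples = 50L,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(cohorts) > 0L && is.null(names(cohorts))) {
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  }
  eligible <- list()
  for (nm in names(cohorts)) {
    if (ncol(cohorts[[nm]]$values) < min_samples) {
      warning("cohort '", nm, "' skipped: fewer than ", min_samples,
              " samples", call. = FALSE)
    } else {
      eligible[[nm]] <- cohorts[[nm]]
    }
  }
  sources <- eligible
  if (!is.null(reference)) sources[["reference"]] <- reference
  if (length(sources) == 0L) {
    stop("no eligible cohort and no reference matrix", call. = FALSE)
  }
  prov <- list()
  for (nm in names(sources)) {
    k <- if (nm == "reference") k_reference else k_cohort
    nom <- nominate_all(sources[[nm]], k = k, r_min = r_min, method = method)
    if (nrow(nom) > 0L) {
      nom$source <- nm
      prov[[nm]] <- nom
    }
  }
  prov <- if (length(prov)) do.call(rbind, prov) else
    data.frame(gene = character(), partner = character(), r = numeric(),
               source = character(), stringsAsFactors = FALSE)
  rownames(prov) <- NULL
  partners <- lapply(split(prov$partner, prov$gene),
                     function(p) sort(unique(p)))
  structure(list(partners = partners,
                 provenance = prov[, c("gene", "partner", "source", "r")],
                 params = list(k_cohort = k_cohort, k_reference = k_reference,
                               r_min = r_min, min_samples = min_samples,
                               method = method)),
            class = "CoexpressionMap")
}

# top-k nominations for every gene of one matrix at once
nominate_all <- function(em, k, r_min, method) {
  v <- em$values
  if (ncol(v) < 3L) stop("need at least 3 samples", call. = FALSE)
  cm <- suppressWarnings(stats::cor(t(v), method = method))
  diag(cm) <- -Inf
  cm[!is.finite(cm)] <- -Inf
  out <- vector("list", nrow(cm))
  for (i in seq_len(nrow(cm))) {
    top <- rank_partners(cm[i, ], k, r_min)
    if (nrow(top) > 0L) {
      top$gene <- rownames(cm)[i]
      out[[i]] <- top
    }
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out) == 0L) {
    return(data.frame(gene = character(), partner = character(),
                      r = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[, c("gene", "partner", "r")]
}

#' @export
print.CoexpressionMap <- function(x, ...) {
  n <- lengths(x$partners)
  cat(sprintf("CoexpressionMap: %d genes with partners (list sizes %s..%s)\n",
              length(x$partners),
              if (length(n)) min(n) else 0, if (length(n)) max(n) else 0))
  invisible(x)
}

#' Serialize / read a co-expression map
#'
#' TSV with columns `gene` and comma-separated `partners`; provenance is
#' written to a JSON sidecar `<path>.provenance.json`.
#'
#' @param map a `CoexpressionMap`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_coexpression_map <- function(map, path) {
  df <- data.frame(gene = names(map$partners),
                   partners = vapply(map$partners, paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- paste0(path, ".provenance.json")
  jsonlite::write_json(list(params = map$params, provenance = map$provenance),
                       side, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_coexpression_map
#' @export
read_coexpression_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  partners <- lapply(strsplit(df$partners, ",", fixed = TRUE),
                     function(p) p[nzchar(p)])
  names(partners) <- df$gene
  side <- paste0(path, ".provenance.json")
  params <- NULL
  prov <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    params <- meta$params
    prov <- meta$provenance
  }
  structure(list(partners = partners, provenance = prov, params = params),
            class = "CoexpressionMap")
}
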