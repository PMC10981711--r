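#' Gene annotation container
#'
#' Exon-level annotation used to compute probe effective-length fractions.
#' Coordinates follow GTF convention on input (1-based, closed) and are
#' held internally as `GRanges`, so all interval arithmetic is exact.
#' Strand is ignored throughout: probe capture coverage is positional.
#'
#' @param exons data.frame with columns `chrom`, `start`, `end` (1-based
#'   closed, as in GTF), `gene_id`, `transcript_id`, and optionally
#'   `gene_biotype` and `gene_name`.
#' @return a `GeneAnnotation`: list with `exons` (a `GRanges`) and `genes`
#'   (a data.frame of per-gene metadata).
#' @export
gene_annotation <- function(exons) {
  required <- c("chrom", "start", "end", "gene_id", "transcript_id")
  if (!all(required %in% names(exons))) {
    stop("exons must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (any(exons$end < exons$start)) {
    stop("exon end < start", call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start, end = exons$end),
    gene_id = as.character(exons$gene_id),
    transcript_id = as.character(exons$transcript_id)
  )
  biotype <- if ("gene_biotype" %in% names(exons)) as.character(exons$gene_biotype) else NA_character_
  name <- if ("gene_name" %in% names(exons)) as.character(exons$gene_name) else as.character(exons$gene_id)
  per_gene <- !duplicated(exons$gene_id)
  genes <- data.frame(
    gene_id = as.character(exons$gene_id)[per_gene],
    gene_biotype = rep_len(biotype, nrow(exons))[per_gene],
    gene_name = rep_len(name, nrow(exons))[per_gene],
    stringsAsFactors = FALSE
  )
  chroms <- tapply(as.character(exons$chrom), exons$gene_id, function(x) unique(x))
  genes$chroms <- I(unname(chroms[genes$gene_id]))
  structure(list(exons = gr, genes = genes), class = "GeneAnnotation")
}

#' @export
print.GeneAnnotation <- function(x, ...) {
  cat(sprintf("GeneAnnotation: %d genes, %d transcripts, %d exons\n",
              nrow(x$genes), length(unique(x$exons$transcript_id)),
              length(x$exons)))
  invisible(x)
}

#' Read gene annotation from a GTF file (GENCODE attribute dialect)
#'
#' Keeps `exon` records; the biotype is taken from `gene_type` or
#' `gene_biotype`, whichever is present.
#'
#' @param path path to a GTF file.
#' @return a `GeneAnnotation`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon records in ", path, call. = FALSE)
  mc <- S4Vectors::mcols(gr)
  biotype <- if ("gene_type" %in% names(mc)) mc$gene_type else mc$gene_biotype
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    gene_id = mc$gene_id,
    transcript_id = mc$transcript_id,
    stringsAsFactors = FALSE
  )
  if (!is.null(biotype)) df$gene_biotype <- biotype
  if ("gene_name" %in% names(mc)) df$gene_name <- mc$gene_name
  gene_annotation(df)
}

#' Read capture-probe intervals from BED
#'
#' BED input is 0-based half-open by convention; `rtracklayer` converts it
#' to 1-based `GRanges`. Intervals are merged so that no two overlap or
#' touch.
#'
#' @param path path to a BED3+ file.
#' @return a merged, strand-free `GRanges` of probe intervals.
#' @export
read_probe_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "bed")
  merge_probes(gr)
}

#' Merge probe intervals
#'
#' @param gr a `GRanges` of probe intervals.
#' @return a sorted `GRanges` with overlapping/touching intervals merged
#'   and strand dropped.
#' @export
merge_probes <- function(gr) {
  GenomicRanges::strand(gr) <- "*"
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

# biotypes excluded by default: the non-coding classes dropped before
# TPM normalization
default_excluded_biotypes <- function() {
  c("lincRNA", "lncRNA", "miRNA", "snoRNA", "snRNA", "rRNA",
    "rRNA_pseudogene", "misc_RNA", "scaRNA", "scRNA", "sRNA", "ribozyme",
    "vault_RNA", "vaultRNA", "Mt_tRNA", "Mt_rRNA", "antisense",
    "sense_intronic", "sense_overlapping", "3prime_overlapping_ncRNA",
    "processed_transcript", "non_coding", "TEC", "pseudogene",
    "processed_pseudogene", "unprocessed_pseudogene",
    "transcribed_processed_pseudogene", "transcribed_unprocessed_pseudogene",
    "transcribed_unitary_pseudogene", "unitary_pseudogene",
    "polymorphic_pseudogene", "translated_processed_pseudogene",
    "IG_pseudogene", "IG_C_pseudogene", "IG_J_pseudogene",
    "IG_V_pseudogene", "TR_V_pseudogene", "TR_J_pseudogene")
}

known_biotypes <- function() {
  c(default_excluded_biotypes(),
    "protein_coding", "IG_C_gene", "IG_D_gene", "IG_J_gene", "IG_V_gene",
    "TR_C_gene", "TR_D_gene", "TR_J_gene", "TR_V_gene")
}

default_histone_patterns <- function() {
  c("^HIST", "^H1-", "^H2A", "^H2B", "^H3-", "^H4-")
}

#' Filter genes by biotype, histone class, and mitochondrial contig
#'
#' Retains genes that keep at least one transcript after excluding
#' non-coding biotypes, histone-coding genes, and genes on the
#' mitochondrial contig. Biotype values outside the known catalog pass
#' through with a warning (not an error).
#'
#' @param annotation a `GeneAnnotation`.
#' @param exclude_biotypes biotypes to drop; defaults to the standard
#'   non-coding classes (see `default_excluded_biotypes`).
#' @param histone_genes optional explicit list of histone gene names; in
#'   addition, gene names matching `histone_patterns` are dropped.
#' @param histone_patterns regexes identifying histone symbols.
#' @param mito_chroms mitochondrial contig names.
#' @return character vector of retained gene ids.
#' @export
filter_by_biotype <- function(annotation,
                              exclude_biotypes = default_excluded_biotypes(),
                              histone_genes = NULL,
                              histone_patterns = default_histone_patterns(),
                              mito_chroms = c("chrM", "MT")) {
  g <- annotation$genes
  unknown <- setdiff(unique(g$gene_biotype[!is.na(g$gene_biotype)]),
                     unique(c(known_biotypes(), exclude_biotypes)))
  if (length(unknown) > 0L) {
    warning("unknown biotype value(s) pass through: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  drop <- !is.na(g$gene_biotype) & g$gene_biotype %in% exclude_biotypes
  if (length(histone_patterns) > 0L) {
    pat <- paste(histone_patterns, collapse = "|")
    drop <- drop | grepl(pat, g$gene_name)
  }
  if (!is.null(histone_genes)) {
    drop <- drop | g$gene_name %in% histone_genes | g$gene_id %in% histone_genes
  }
  on_mito <- vapply(g$chroms, function(ch) any(ch %in% mito_chroms), logical(1L))
  drop <- drop | on_mito
  g$gene_id[!drop]
}

#' Probe effective-length fraction per gene
#'
#' For every transcript, the effective length is the length of its
#' (within-transcript merged) exons intersected with the probe intervals;
#' effective and actual transcript lengths are summed within each gene and
#' the per-gene ratio is returned. Exons within one transcript are merged
#' so no base is double counted; transcripts are summed without
#' cross-transcript merging. Strand is ignored. Chromosomes absent from
#' the probe set contribute zero covered length (not an error).
#'
#' @param annotation a `GeneAnnotation`.
#' @param probes a merged `GRanges` of probe intervals (see
#'   [read_probe_bed()]).
#' @return named numeric vector of fractions in `[0, 1]`, one per gene.
#' @export
effective_length_fraction <- function(annotation, probes) {
  ex <- annotation$exons
  GenomicRanges::strand(ex) <- "*"
  probes <- merge_probes(probes)
  grl <- GenomicRanges::reduce(S4Vectors::split(ex, ex$transcript_id))
  tx_len <- sum(IRanges::width(grl))
  flat <- unlist(grl, use.names = FALSE)
  tx_of <- rep(names(grl), S4Vectors::elementNROWS(grl))
  hits <- GenomicRanges::findOverlaps(flat, probes, ignore.strand = TRUE)
  ov <- IRanges::width(GenomicRanges::pintersect(
    flat[S4Vectors::queryHits(hits)], probes[S4Vectors::subjectHits(hits)],
    ignore.strand = TRUE))
  tx_cov <- stats::setNames(numeric(length(grl)), names(grl))
  if (length(hits) > 0L) {
    add <- tapply(ov, tx_of[S4Vectors::queryHits(hits)], sum)
    tx_cov[names(add)] <- as.numeric(add)
  }
  tx2gene <- tapply(ex$gene_id, ex$transcript_id, function(x) x[1L])
  gene_of_tx <- as.character(tx2gene[names(grl)])
  gene_len <- tapply(tx_len, gene_of_tx, sum)
  gene_cov <- tapply(tx_cov, gene_of_tx, sum)
  if (any(gene_len == 0)) {
    stop("gene(s) with zero total transcript length: ",
         paste(names(gene_len)[gene_len == 0], collapse = ", "), call. = FALSE)
  }
  frac <- as.numeric(gene_cov) / as.numeric(gene_len)
  stats::setNames(frac, names(gene_len))
}

#' Flag problematic genes by effective-length fraction
#'
#' A gene is problematic when its probe-covered fraction of transcript
#' length is strictly below the threshold; a fraction of exactly 0.5 is
#' not problematic.
#'
#' @param fractions named numeric vector in `[0, 1]` (see
#'   [effective_length_fraction()]).
#' @param threshold fraction threshold, default 0.5.
#' @return character vector of problematic gene ids.
#' @export
flag_problematic <- function(fractions, threshold = 0.5) {
  if (is.null(names(fractions))) stop("'fractions' must be named", call. = FALSE)
  if (any(fractions < 0 | fractions > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  names(fractions)[fractions < threshold]
}

#' Low-expression exclusion set
#'
#' Excludes genes whose expression exceeds `min_expr` in fewer than
#' `min_fraction_samples` of samples. Thresholds are interpreted in the
#' matrix's own unit. Defaults: TPM > 1 in < 10% of samples.
#'
#' @param em an `ExpressionMatrix` (`TPM` or `LOG2_TPM_PLUS1`).
#' @param min_expr expression threshold.
#' @param min_fraction_samples required fraction of samples in `[0, 1]`.
#' @return character vector of gene ids to exclude.
#' @export
low_expression_filter <- function(em, min_expr = 1, min_fraction_samples = 0.1) {
  if (!em$unit %in% c("TPM", "LOG2_TPM_PLUS1")) {
    stop("low_expression_filter requires TPM or LOG2_TPM_PLUS1, got ",
         em$unit, call. = FALSE)
  }
  if (min_fraction_samples < 0 || min_fraction_samples > 1) {
    stop("min_fraction_samples must lie in [0, 1]", call. = FALSE)
  }
  frac <- rowMeans(em$values > min_expr)
  rownames(em$values)[frac < min_fraction_samples]
}

#' Build the four named gene groups
#'
#' `AG` = all genes; `AGEP` = all genes excluding problematic genes;
#' `BMG` = biologically meaningful genes (restricted to `AG`); `BMGEP` =
#' `BMG` excluding problematic genes. Ids in `bmg_list` outside `AG` are
#' dropped with a warning.
#'
#' @param all_genes character vector (the gene universe, `AG`).
#' @param problematic character vector of problematic gene ids.
#' @param bmg_list character vector of biologically meaningful gene ids.
#' @return a `GeneGroups` list with elements `AG`, `AGEP`, `BMG`, `BMGEP`.
#' @export
build_gene_groups <- function(all_genes, problematic = character(),
                              bmg_list = character()) {
  all_genes <- unique(as.character(all_genes))
  problematic <- unique(as.character(problematic))
  bmg_list <- unique(as.character(bmg_list))
  outside <- setdiff(bmg_list, all_genes)
  if (length(outside) > 0L) {
    warning("bmg_list ids outside the gene universe dropped: ",
            paste(utils::head(outside, 5L), collapse = ", "),
            if (length(outside) > 5L) ", ..." else "", call. = FALSE)
  }
  bmg <- intersect(bmg_list, all_genes)
  structure(list(AG = all_genes,
                 AGEP = setdiff(all_genes, problematic),
                 BMG = bmg,
                 BMGEP = setdiff(bmg, problematic)),
            class = "GeneGroups")
}

#' @export
print.GeneGroups <- function(x, ...) {
  cat(sprintf("GeneGroups: AG=%d AGEP=%d BMG=%d BMGEP=%d\n",
              length(x$AG), length(x$AGEP), length(x$BMG), length(x$BMGEP)))
  invisible(x)
}

#' Per-gene filtering report
#'
#' @param fractions named effective-length fractions.
#' @param groups a `GeneGroups` object covering the same genes.
#' @param threshold problematic threshold used.
#' @return data.frame with columns `gene`, `fraction`, `problematic`, and
#'   group membership flags.
#' @export
gene_filter_report <- function(fractions, groups, threshold = 0.5) {
  genes <- names(fractions)
  data.frame(
    gene = genes,
    fraction = as.numeric(fractions),
    problematic = fractions < threshold,
    AG = genes %in% groups$AG,
    AGEP = genes %in% groups$AGEP,
    BMG = genes %in% groups$BMG,
    BMGEP = genes %in% groups$BMGEP,
    stringsAsFactors = FALSE
  )
}
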