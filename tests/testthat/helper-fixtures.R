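# Fixture builders; everything is generated in code at test time.

toy_matrix <- function(values, genes = NULL, samples = NULL,
                       unit = "LOG2_TPM_PLUS1") {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, unit)
}

random_log_matrix <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  v <- matrix(abs(rnorm(n_genes * n_samples, 5, 2)), n_genes, n_samples)
  toy_matrix(v)
}

identity_pairing <- function(em) {
  data.frame(source = colnames(em$values), target = colnames(em$values),
             stringsAsFactors = FALSE)
}

# paired cohort where target = slope * source + intercept (+ noise)
affine_cohort <- function(n_genes = 20, n_samples = 30, slope = 1,
                          intercept = 0, noise = 0, seed = 1) {
  set.seed(seed)
  src <- matrix(abs(rnorm(n_genes * n_samples, 6, 2)), n_genes, n_samples,
                dimnames = list(paste0("g", seq_len(n_genes)),
                                paste0("ec", seq_len(n_samples))))
  tgt <- slope * src + intercept +
    matrix(rnorm(n_genes * n_samples, 0, noise), n_genes, n_samples)
  tgt <- pmax(tgt, 0)
  colnames(tgt) <- paste0("pa", seq_len(n_samples))
  align_paired(
    expression_matrix(src, "LOG2_TPM_PLUS1"),
    expression_matrix(tgt, "LOG2_TPM_PLUS1"),
    data.frame(source = colnames(src), target = colnames(tgt),
               stringsAsFactors = FALSE))
}

# random exon/probe instance on one small chromosome, 1-based closed
random_interval_instance <- function(seed, max_pos = 1500) {
  set.seed(seed)
  n_genes <- sample(1:3, 1)
  rows <- list()
  for (g in seq_len(n_genes)) {
    for (tx in seq_len(sample(1:3, 1))) {
      for (e in seq_len(sample(1:4, 1))) {
        start <- sample.int(max_pos - 60, 1)
        rows[[length(rows) + 1]] <- data.frame(
          chrom = "chr1", start = start,
          end = start + sample(5:60, 1),
          gene_id = paste0("G", g),
          transcript_id = paste0("G", g, "T", tx),
          stringsAsFactors = FALSE)
      }
    }
  }
  exons <- do.call(rbind, rows)
  n_probes <- sample(2:8, 1)
  pstart <- sample.int(max_pos - 80, n_probes)
  probes <- data.frame(chrom = "chr1", start = pstart,
                       end = pstart + sample(10:80, n_probes, replace = TRUE),
                       stringsAsFactors = FALSE)
  list(exons = exons, probes = probes)
}

probes_granges <- function(probes) {
  GenomicRanges::GRanges(probes$chrom,
                         IRanges::IRanges(probes$start, probes$end))
}

write_toy_gtf <- function(exons, path) {
  lines <- vapply(seq_len(nrow(exons)), function(i) {
    bt <- if ("gene_biotype" %in% names(exons)) exons$gene_biotype[i] else "protein_coding"
    nm <- if ("gene_name" %in% names(exons)) exons$gene_name[i] else exons$gene_id[i]
    sprintf(paste0("%s\ttest\texon\t%d\t%d\t.\t+\t.\t",
                   "gene_id \"%s\"; transcript_id \"%s\"; gene_type \"%s\"; gene_name \"%s\";"),
            exons$chrom[i], exons$start[i], exons$end[i],
            exons$gene_id[i], exons$transcript_id[i], bt, nm)
  }, "")
  writeLines(lines, path)
  path
}

write_toy_bed <- function(probes, path) {
  # BED is 0-based half-open: start-1, end
  writeLines(sprintf("%s\t%d\t%d", probes$chrom, probes$start - 1L,
                     probes$end), path)
  path
}
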