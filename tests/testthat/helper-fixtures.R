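# Shared fixtures, built in code.

toy_genome <- function(n_chrom = 2, len = 5e7) {
  setNames(rep(len, n_chrom), paste0("chr", seq_len(n_chrom)))
}

# StrandCountMatrix with a constant per-copy depth and hand-set strand
# states; `states` is a list cell -> chrom -> c(W copies, C copies) per bin.
manual_strand_matrix <- function(bins, cells, copies_w, copies_c,
                                 depth_per_copy = 10) {
  W <- round(copies_w * depth_per_copy)
  C <- round(copies_c * depth_per_copy)
  rownames(W) <- rownames(C) <- cells
  structure(list(bins = bins, cells = cells, W = W, C = C),
            class = "StrandCountMatrix")
}

toy_bins <- function(chrom = "chr1", n = 50, width = 1e6) {
  data.frame(chrom = chrom, start = width * (seq_len(n) - 1),
             end = width * seq_len(n))
}

# gene table on one chromosome plus background on another
toy_gene_table <- function(n_region = 24, n_background = 1976) {
  n <- n_region + n_background
  data.frame(gene = sprintf("g%04d", seq_len(n)),
             chrom = c(rep("chr17", n_region), rep("chr2", n_background)),
             start = 1e5 * seq_len(n), end = 1e5 * seq_len(n) + 5e4,
             stringsAsFactors = FALSE)
}

toy_cres <- function(n = 300, spacing = 2e4, chrom = "chrX") {
  d <- data.frame(chrom = chrom, start = spacing * (seq_len(n) - 1))
  d$end <- d$start + 1e3
  d
}
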