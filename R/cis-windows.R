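## Haplotype-specific nucleosome occupancy at CREs in sliding windows:
## cis-regulatory effect testing for balanced mSVs.

#' Sliding windows over a region
#'
#' Windows of \code{size} bp placed every \code{step} bp, fully inside the
#' region (half-open placement). A region shorter than \code{size} yields a
#' single truncated window; a step larger than the size leaves gaps (a
#' message is emitted).
#'
#' @param region data.frame or list with chrom, start, end (0-based
#'   half-open).
#' @param size window size in bp (default 300 kb).
#' @param step window step in bp (default 10 kb).
#' @return data.frame(chrom, start, end).
#' @export
make_windows <- function(region, size = 3e5, step = 1e4) {
  stopifnot(size > 0, step > 0)
  len <- region$end - region$start
  if (step > size) message("step exceeds window size; windows leave gaps")
  if (len < size) {
    return(data.frame(chrom = region$chrom, start = region$start,
                      end = region$end, stringsAsFactors = FALSE))
  }
  starts <- seq(region$start, region$end - size, by = step)
  data.frame(chrom = region$chrom, start = starts, end = starts + size,
             stringsAsFactors = FALSE)
}

## per-cell log2 haplotype occupancy ratio over the CREs of one window;
## counts are RPM-normalized per haplotype matrix, pseudocount stabilizes
## zero denominators
.window_log2_ratio <- function(h1, h2, cre_idx, pseudo = 0.5) {
  a <- rowSums(h1[, cre_idx, drop = FALSE]) + pseudo
  b <- rowSums(h2[, cre_idx, drop = FALSE]) + pseudo
  log2(a / b)
}

## Gaussian LRT of equal vs separate group means (shared variance, 1 df)
.gaussian_lrt <- function(y, grp) {
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  m <- tapply(y, grp, mean)
  rss1 <- sum((y - m[grp])^2)
  if (rss1 <= 0) rss1 <- .Machine$double.eps
  stat <- n * log(rss0 / rss1)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Haplotype-ratio likelihood ratio test in one window
#'
#' Per cell, the haplotype-specific NO ratio (haplotype 1 / haplotype 2,
#' RPM-normalized, pseudocount 0.5) is summed over the window's CREs and
#' log2-transformed; mutant and WT cells are compared by a Gaussian
#' likelihood ratio test of equal versus separate means (1 df, chi-squared
#' reference). log2FC is mean(mutant) - mean(WT) of the log2 ratios: on the
#' NO scale, a negative log2FC over H1 means lower H1 occupancy, i.e.
#' inferred increased accessibility on haplotype 1.
#'
#' @param counts list with H1, H2 cells-by-CRE count matrices and
#'   \code{cres} coordinates (as from
#'   \code{\link{simulate_cre_haplotype_counts}}).
#' @param genotype per-cell labels, "mutant" or "WT".
#' @param window data.frame/list with chrom, start, end.
#' @param min_cres minimum covered CREs for the window to be tested
#'   (default 3).
#' @return list(log2fc, p, n_cres); p = NA if untestable.
#' @export
window_lrt <- function(counts, genotype, window, min_cres = 3) {
  ratios <- .cis_ratio_matrix(counts)
  cre_idx <- .window_cre_idx(counts$cres, window)
  if (length(cre_idx) < min_cres) {
    return(list(log2fc = NA_real_, p = NA_real_, n_cres = length(cre_idx)))
  }
  grp <- factor(genotype, levels = c("WT", "mutant"))
  if (min(table(grp)) < 2) stop("insufficient cells in a genotype group")
  y <- .window_log2_ratio(ratios$h1, ratios$h2, cre_idx)
  m <- tapply(y, grp, mean)
  list(log2fc = unname(m["mutant"] - m["WT"]),
       p = .gaussian_lrt(y, grp), n_cres = length(cre_idx))
}

.cis_ratio_matrix <- function(counts) {
  lib <- rowSums(counts$H1) + rowSums(counts$H2)
  lib[lib == 0] <- 1
  list(h1 = counts$H1 / lib * 1e6, h2 = counts$H2 / lib * 1e6)
}

.window_cre_idx <- function(cres, window) {
  mid <- (cres$start + cres$end) / 2
  which(cres$chrom == window$chrom & mid >= window$start & mid < window$end)
}

#' Sliding-window haplotype-cis scan with label-permutation adjusted p
#'
#' Runs \code{\link{window_lrt}} over all windows, then adjusts each
#' window's nominal p by randomly shuffling the per-cell genotype labels
#' \code{n_perm} times and counting permutations with an equal or lower
#' nominal p in that window (+1 smoothing, so adjusted p >= 1/(n_perm + 1)).
#' Windows with adjusted p below \code{threshold} are flagged significant.
#'
#' @param counts,genotype,min_cres as in \code{\link{window_lrt}}.
#' @param windows data.frame of windows from \code{\link{make_windows}}.
#' @param n_perm label permutations (default 1000).
#' @param threshold significance threshold on the adjusted p (default 0.1).
#' @param seed integer seed.
#' @return \code{CREWindowResult} data.frame: window coordinates, n_cres,
#'   log2fc, p_nominal, p_adj, significant.
#' @export
window_permutation_fdr <- function(counts, genotype, windows, n_perm = 1000,
                                   threshold = 0.1, min_cres = 3,
                                   seed = 1L) {
  set_seed_if(seed)
  ratios <- .cis_ratio_matrix(counts)
  grp <- factor(genotype, levels = c("WT", "mutant"))
  idx_list <- lapply(seq_len(nrow(windows)), function(i) {
    .window_cre_idx(counts$cres, windows[i, ])
  })
  testable <- vapply(idx_list, length, integer(1)) >= min_cres
  Y <- vapply(idx_list[testable], function(ix) {
    .window_log2_ratio(ratios$h1, ratios$h2, ix)
  }, numeric(nrow(counts$H1)))
  ## vectorized per-window LRT given a grouping
  lrt_cols <- function(Y, grp) {
    n <- nrow(Y)
    mu <- colMeans(Y)
    rss0 <- colSums(sweep(Y, 2, mu)^2)
    m1 <- colMeans(Y[grp == "mutant", , drop = FALSE])
    m0 <- colMeans(Y[grp == "WT", , drop = FALSE])
    fitted <- outer(as.integer(grp == "mutant"), m1) +
      outer(as.integer(grp == "WT"), m0)
    rss1 <- pmax(colSums((Y - fitted)^2), .Machine$double.eps)
    pchisq(n * log(rss0 / rss1), df = 1, lower.tail = FALSE)
  }
  p_obs <- lrt_cols(Y, grp)
  exceed <- integer(length(p_obs))
  for (b in seq_len(n_perm)) {
    pp <- lrt_cols(Y, sample(grp))
    exceed <- exceed + as.integer(pp <= p_obs)
  }
  p_adj <- (1 + exceed) / (n_perm + 1)
  m1 <- colMeans(Y[grp == "mutant", , drop = FALSE])
  m0 <- colMeans(Y[grp == "WT", , drop = FALSE])
  out <- data.frame(windows, n_cres = vapply(idx_list, length, integer(1)),
                    log2fc = NA_real_, p_nominal = NA_real_,
                    p_adj = NA_real_, significant = FALSE,
                    stringsAsFactors = FALSE)
  out$log2fc[testable] <- m1 - m0
  out$p_nominal[testable] <- p_obs
  out$p_adj[testable] <- p_adj
  out$significant[testable] <- p_adj < threshold
  out
}

#' Annotate significant windows with the nearest gene in the same TAD
#'
#' Candidate genes are those whose body lies within a TAD overlapping the
#' window (a window straddling a boundary considers both TADs); among them
#' the gene nearest to the window is chosen. Windows whose TAD(s) contain no
#' gene get an empty annotation.
#'
#' @param windows data.frame(chrom, start, end), e.g. significant rows of
#'   \code{\link{window_permutation_fdr}} output.
#' @param genes data.frame(gene, chrom, start, end).
#' @param tads data.frame(chrom, start, end).
#' @return windows with a \code{nearest_gene} column (NA when none).
#' @export
assign_nearest_gene <- function(windows, genes, tads) {
  win_gr <- as_granges0(windows)
  gene_gr <- as_granges0(genes)
  tad_gr <- as_granges0(tads)
  g2t <- GenomicRanges::findOverlaps(gene_gr, tad_gr,
                                     type = "within")
  windows$nearest_gene <- NA_character_
  for (i in seq_len(nrow(windows))) {
    wt <- S4Vectors::subjectHits(
      GenomicRanges::findOverlaps(win_gr[i], tad_gr))
    if (!length(wt)) next
    cand <- S4Vectors::queryHits(g2t)[S4Vectors::subjectHits(g2t) %in% wt]
    if (!length(cand)) next
    d <- GenomicRanges::distance(win_gr[i], gene_gr[cand])
    windows$nearest_gene[i] <- genes$gene[cand[which.min(d)]]
  }
  windows
}
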