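## Genome-binned SCE hotspot statistics and mSV-breakpoint overlap enrichment.

#' Tile a genome into fixed-width bins
#'
#' @param genome named numeric vector of chromosome lengths (bp).
#' @param bin_width bin width, default 500 kb; the last bin of each
#'   chromosome may be short.
#' @return data.frame(chrom, start, end), 0-based half-open.
#' @export
make_genome_bins <- function(genome, bin_width = 5e5) {
  tile_genome(genome, bin_width)
}

#' Count SCEs per genomic bin
#'
#' Each SCE increments exactly one bin: the bin containing the majority of
#' its confidence interval. An exact 50/50 split is broken toward the
#' lower-coordinate bin.
#'
#' @param sces data.frame with chrom, ci_start, ci_end (bp, 0-based
#'   half-open), e.g. \code{detect_sces(...)$calls}.
#' @param bins data.frame(chrom, start, end) tiling the genome.
#' @return integer vector of counts, one per bin (sums to \code{nrow(sces)}
#'   for SCEs whose CI lies within the binned genome).
#' @export
bin_sce_counts <- function(sces, bins) {
  counts <- integer(nrow(bins))
  if (!nrow(sces)) return(counts)
  bin_gr <- as_granges0(bins)
  sce_gr <- GenomicRanges::GRanges(
    sces$chrom, IRanges::IRanges(start = sces$ci_start + 1,
                                 end = pmax(sces$ci_end, sces$ci_start + 1)))
  ov <- GenomicRanges::findOverlaps(sce_gr, bin_gr)
  if (!length(ov)) return(counts)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(IRanges::ranges(sce_gr)[q],
                                          IRanges::ranges(bin_gr)[s]))
  ## per SCE keep the bin with maximal CI overlap; ties -> lower coordinate
  ord <- order(q, -w, s)
  q <- q[ord]; s <- s[ord]
  keep <- !duplicated(q)
  tab <- table(s[keep])
  counts[as.integer(names(tab))] <- as.integer(tab)
  counts
}

#' Fit a negative binomial model of per-bin SCE counts
#'
#' Maximum-likelihood fit of NB(size, mu) to the genome-wide per-bin counts
#' via \code{fitdistrplus::fitdist}.
#'
#' @param counts integer vector of per-bin SCE counts.
#' @return list of class \code{HotspotModel}: size, mu, loglik.
#' @export
fit_hotspot_model <- function(counts) {
  stopifnot(all(counts >= 0))
  if (length(unique(counts)) < 2) stop("cannot fit: degenerate counts")
  fit <- fitdistrplus::fitdist(as.integer(counts), "nbinom")
  structure(list(size = unname(fit$estimate["size"]),
                 mu = unname(fit$estimate["mu"]),
                 loglik = fit$loglik),
            class = "HotspotModel")
}

#' @export
print.HotspotModel <- function(x, ...) {
  cat(sprintf("HotspotModel: NB(size = %.7f, mu = %.7f), loglik = %.2f\n",
              x$size, x$mu, x$loglik))
  invisible(x)
}

#' Flag SCE hotspot bins under the fitted negative binomial model
#'
#' Per-bin upper-tail p-values P(X >= count) under NB(size, mu), adjusted by
#' Benjamini-Hochberg; bins with adjusted p below \code{alpha} are hotspots.
#'
#' @param bins data.frame(chrom, start, end).
#' @param counts per-bin SCE counts.
#' @param model a \code{HotspotModel}.
#' @param alpha hotspot threshold on BH-adjusted p (default 0.05).
#' @return \code{HotspotTable} data.frame: bin coordinates, sce_count,
#'   p_nominal, p_adj, is_hotspot.
#' @export
call_hotspots <- function(bins, counts, model, alpha = 0.05) {
  stopifnot(inherits(model, "HotspotModel"), nrow(bins) == length(counts))
  p <- pnbinom(counts - 1, size = model$size, mu = model$mu,
               lower.tail = FALSE)
  padj <- p.adjust(p, method = "BH")
  out <- data.frame(bins, sce_count = counts, p_nominal = p, p_adj = padj,
                    is_hotspot = padj < alpha, stringsAsFactors = FALSE)
  class(out) <- c("HotspotTable", class(out))
  out
}

## length-preserving uniform relocation of regions within their chromosome
.shuffle_regions <- function(widths, chrom, genome) {
  maxs <- pmax(genome[chrom] - widths, 1)
  start <- floor(runif(length(widths)) * maxs)
  data.frame(chrom = chrom, start = start, end = start + widths,
             stringsAsFactors = FALSE)
}

## per-chromosome merged feature intervals (0-based half-open), for the
## findInterval-based overlap counting used inside permutation loops
.merged_features <- function(features) {
  gr <- GenomicRanges::reduce(as_granges0(features))
  sp <- split(data.frame(start = GenomicRanges::start(gr) - 1,
                         end = GenomicRanges::end(gr)),
              as.character(GenomicRanges::seqnames(gr)))
  lapply(sp, function(d) d[order(d$start), , drop = FALSE])
}

## number of query regions overlapping any merged feature interval
.count_overlaps_fast <- function(chrom, start, end, merged) {
  hit <- logical(length(start))
  for (ch in unique(chrom)) {
    mf <- merged[[ch]]
    i <- which(chrom == ch)
    if (is.null(mf) || !nrow(mf)) next
    ## index of the last feature starting before the query end
    j <- findInterval(end[i] - 1e-9, mf$start)
    ok <- j >= 1
    hit[i[ok]] <- mf$end[j[ok]] > start[i[ok]]
  }
  sum(hit)
}

#' Permutation test of breakpoint-region overlap with hotspot bins
#'
#' The observed statistic is the number of breakpoint regions (reported
#' breakpoints padded to +/- \code{pad} bp) intersecting any hotspot
#' interval. Each permutation relocates the breakpoint regions uniformly
#' within their chromosome (length-preserving); the one-sided empirical p is
#' (1 + #\{perm >= observed\}) / (n_perm + 1).
#'
#' @param breakpoints data.frame(chrom, start, end) of reported breakpoints
#'   (0-based half-open).
#' @param hotspots data.frame(chrom, start, end) of hotspot intervals.
#' @param genome named numeric vector of chromosome lengths.
#' @param n_perm number of permutations (default 10000).
#' @param pad half-width added to each breakpoint (default 100 kb, giving
#'   200-kb breakpoint regions).
#' @param cross_chromosome if TRUE, permuted regions may relocate to any
#'   chromosome (sampled with probability proportional to length).
#' @param seed integer seed.
#' @return list of class \code{OverlapPermResult}: observed, perm (length
#'   n_perm), p_empirical, z.
#' @export
overlap_permutation_test <- function(breakpoints, hotspots, genome,
                                     n_perm = 10000, pad = 1e5,
                                     cross_chromosome = FALSE, seed = 1L) {
  set_seed_if(seed)
  bp <- data.frame(chrom = breakpoints$chrom,
                   start = pmax(0, breakpoints$start - pad),
                   end = pmin(genome[breakpoints$chrom],
                              breakpoints$end + pad),
                   stringsAsFactors = FALSE)
  merged <- .merged_features(hotspots)
  obs <- .count_overlaps_fast(bp$chrom, bp$start, bp$end, merged)
  widths <- bp$end - bp$start
  perm <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    ch <- if (cross_chromosome) {
      sample(names(genome), nrow(bp), replace = TRUE,
             prob = as.numeric(genome))
    } else bp$chrom
    r <- .shuffle_regions(widths, ch, genome)
    perm[i] <- .count_overlaps_fast(r$chrom, r$start, r$end, merged)
  }
  p <- perm_pvalue(obs, perm)
  z <- if (sd(perm) > 0) (obs - mean(perm)) / sd(perm) else NA_real_
  structure(list(observed = obs, perm = perm, p_empirical = p, z = z,
                 n_perm = n_perm),
            class = "OverlapPermResult")
}

#' @export
print.OverlapPermResult <- function(x, ...) {
  cat(sprintf(
    "OverlapPermResult: observed = %d, expected = %.2f, p = %.4g (n_perm = %d)\n",
    x$observed, mean(x$perm), x$p_empirical, x$n_perm))
  invisible(x)
}

#' Local enrichment Z-score of breakpoint/hotspot overlap under shifts
#'
#' Recomputes the breakpoint-region overlap with the regions translated by
#' +/- each offset (averaged over the two directions; shifted regions
#' exceeding chromosome ends are clipped, not wrapped) and expresses every
#' overlap count as a Z-score against the permutation null of
#' \code{\link{overlap_permutation_test}}. Genuine co-localization shows a
#' Z maximal at zero shift and decaying with offset.
#'
#' @param breakpoints,hotspots,genome,pad,seed as in
#'   \code{\link{overlap_permutation_test}}.
#' @param shifts numeric vector of offsets in bp (default 100 kb to 10 Mb).
#' @param n_perm permutations for the null (default 1000).
#' @return data.frame(shift, overlaps, z).
#' @export
local_shift_zscore <- function(breakpoints, hotspots, genome,
                               shifts = c(1e5, 2e5, 5e5, 1e6, 2e6, 5e6, 1e7),
                               n_perm = 1000, pad = 1e5, seed = 1L) {
  base <- overlap_permutation_test(breakpoints, hotspots, genome,
                                   n_perm = n_perm, pad = pad, seed = seed)
  mu <- mean(base$perm); s <- sd(base$perm)
  merged <- .merged_features(hotspots)
  bp <- data.frame(chrom = breakpoints$chrom,
                   start = pmax(0, breakpoints$start - pad),
                   end = pmin(genome[breakpoints$chrom],
                              breakpoints$end + pad),
                   stringsAsFactors = FALSE)
  shift_count <- function(offset) {
    n <- 0
    for (sgn in c(1, -1)) {
      st <- pmax(0, pmin(bp$start + sgn * offset, genome[bp$chrom] - 1))
      en <- pmax(st + 1, pmin(bp$end + sgn * offset, genome[bp$chrom]))
      n <- n + .count_overlaps_fast(bp$chrom, st, en, merged)
    }
    n / 2
  }
  res <- data.frame(shift = c(0, shifts))
  res$overlaps <- c(base$observed, vapply(shifts, shift_count, numeric(1)))
  res$z <- if (s > 0) (res$overlaps - mu) / s else NA_real_
  res
}
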