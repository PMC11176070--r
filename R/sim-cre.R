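#' Simulate haplotype-tagged nucleosome-occupancy counts at CREs
#'
#' Emulates per-cell, per-CRE fragment counts split by haplotype. In carrier
#' cells, CREs falling inside a planted window have their occupancy on the
#' planted haplotype scaled by the planted effect (an effect of 0.5 halves
#' occupancy, i.e. doubles inferred accessibility on that haplotype).
#'
#' @param cres data.frame(chrom, start, end) of cis-regulatory elements
#'   (0-based half-open).
#' @param n_cells number of cells.
#' @param carrier_fraction fraction of cells carrying the planted effect.
#' @param windows optional data.frame(chrom, start, end, haplotype, effect)
#'   of planted accessibility-shift windows; every window must contain at
#'   least one CRE.
#' @param mean_count expected fragments per CRE per haplotype per cell.
#' @param dispersion negative binomial size.
#' @param lib_size_sd lognormal sd of per-cell library scaling.
#' @param seed integer seed.
#' @return list with \code{counts} (list H1, H2 of cells-by-CRE matrices,
#'   plus \code{cres} and per-cell \code{genotype}) and \code{truth}
#'   (carrier cells, planted windows).
#' @export
simulate_cre_haplotype_counts <- function(cres, n_cells = 100,
                                          carrier_fraction = 0.25,
                                          windows = NULL, mean_count = 5,
                                          dispersion = 2, lib_size_sd = 0.2,
                                          seed = 1L) {
  stopifnot(all(c("chrom", "start", "end") %in% names(cres)),
            n_cells >= 2, carrier_fraction >= 0, carrier_fraction <= 1)
  set.seed(as.integer(seed))
  n_cre <- nrow(cres)
  cre_gr <- as_granges0(cres)
  in_window <- matrix(FALSE, n_cre, 0)
  if (!is.null(windows) && nrow(windows)) {
    stopifnot(all(c("chrom", "start", "end", "haplotype", "effect") %in%
                    names(windows)),
              all(windows$haplotype %in% c("H1", "H2")),
              all(windows$effect > 0))
    win_gr <- as_granges0(windows)
    ov <- GenomicRanges::findOverlaps(cre_gr, win_gr)
    if (!all(seq_len(nrow(windows)) %in% S4Vectors::subjectHits(ov))) {
      stop("planted window contains zero CREs")
    }
    in_window <- matrix(FALSE, n_cre, nrow(windows))
    in_window[cbind(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))] <- TRUE
  }

  cells <- sprintf("cell%03d", seq_len(n_cells))
  n_car <- round(carrier_fraction * n_cells)
  carriers <- sort(sample(cells, n_car))
  genotype <- ifelse(cells %in% carriers, "mutant", "WT")
  cell_factor <- exp(rnorm(n_cells, 0, lib_size_sd))

  base <- mean_count * exp(rnorm(n_cre, 0, 0.3))
  draw <- function(hap) {
    mu <- outer(cell_factor, base)
    if (!is.null(windows) && nrow(windows)) {
      for (w in seq_len(nrow(windows))) {
        if (windows$haplotype[w] != hap) next
        ci <- which(genotype == "mutant")
        gi <- which(in_window[, w])
        mu[ci, gi] <- mu[ci, gi] * windows$effect[w]
      }
    }
    matrix(rnbinom(length(mu), size = dispersion, mu = mu),
           n_cells, n_cre,
           dimnames = list(cells, sprintf("cre%04d", seq_len(n_cre))))
  }
  counts <- list(H1 = draw("H1"), H2 = draw("H2"),
                 cres = cres, genotype = setNames(genotype, cells))
  truth <- list(carriers = carriers, windows = windows)
  list(counts = counts, truth = truth)
}
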