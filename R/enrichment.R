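## Cell-type enrichment of mSV subclones versus a control composition.

#' One-sided binomial enrichment p-value
#'
#' P(X >= k) for X ~ Binomial(n, p0): is a cell type over-represented in a
#' subclone of size n relative to the control proportion p0?
#'
#' @param k observed cells of the type in the subclone.
#' @param n subclone size.
#' @param p0 control proportion of the type.
#' @return upper-tail p-value.
#' @examples
#' binomial_enrichment(10, 10, 0.5)  # 2^-10
#' @export
binomial_enrichment <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, p0 >= 0, p0 <= 1)
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Subclone cell-type enrichment with resampling-adjusted p-values
#'
#' For each cell type: a one-sided binomial test of the observed count in
#' the subclone against the control composition, plus an adjusted p-value
#' from repeatedly drawing subclone-sized samples (without replacement) from
#' the full cell population and tallying how often the resampled type count
#' reaches the observed one. BH correction across cell types; types with
#' adjusted q below \code{fdr} are flagged enriched.
#'
#' @param subclone_cells character vector of carrier cell ids.
#' @param celltypes named character vector: cell id -> cell type, for the
#'   entire single-cell population.
#' @param control_composition optional named numeric of control cell-type
#'   proportions (p0 for the binomial test); defaults to the population
#'   composition.
#' @param n_perm number of resamples (default 100000).
#' @param fdr BH threshold for the enriched flag (default 0.1).
#' @param seed integer seed.
#' @return \code{EnrichmentResult} data.frame: celltype, k, n, p0,
#'   p_binomial, p_perm, q, enriched.
#' @export
subclone_enrichment <- function(subclone_cells, celltypes,
                                control_composition = NULL,
                                n_perm = 1e5, fdr = 0.1, seed = 1L) {
  stopifnot(all(subclone_cells %in% names(celltypes)),
            length(subclone_cells) <= length(celltypes))
  set_seed_if(seed)
  pop <- factor(celltypes)
  types <- levels(pop)
  n <- length(subclone_cells)
  obs <- table(factor(celltypes[subclone_cells], levels = types))
  p0 <- if (is.null(control_composition)) {
    as.numeric(table(pop)) / length(pop)
  } else {
    stopifnot(all(types %in% names(control_composition)))
    as.numeric(control_composition[types])
  }
  p_binom <- vapply(seq_along(types), function(i) {
    binomial_enrichment(as.integer(obs[i]), n, p0[i])
  }, numeric(1))
  ## resample subclone-sized draws from the population, without replacement
  pop_int <- as.integer(pop)
  K <- length(types)
  counts_ge <- integer(K)
  for (b in seq_len(n_perm)) {
    s <- sample.int(length(pop_int), n)
    tab <- tabulate(pop_int[s], nbins = K)
    counts_ge <- counts_ge + as.integer(tab >= as.integer(obs))
  }
  p_perm <- (1 + counts_ge) / (n_perm + 1)
  q <- p.adjust(p_perm, method = "BH")
  data.frame(celltype = types, k = as.integer(obs), n = n, p0 = p0,
             p_binomial = p_binom, p_perm = p_perm, q = q,
             enriched = q < fdr, stringsAsFactors = FALSE)
}
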