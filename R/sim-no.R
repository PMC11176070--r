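#' Simulate a nucleosome-occupancy reference matrix with class signatures
#'
#' Emulates a cells-by-genes matrix of MNase-protected fragment counts over
#' gene bodies, for a declared set of cell types. Counts follow a negative
#' binomial around per-gene baselines; each class's signature genes are
#' shifted by \code{effect} on the log2 scale in cells of that class, which
#' is the structure the two-stage PLS-DA feature selection is designed to
#' recover.
#'
#' @param n_classes number of cell types (>= 2).
#' @param cells_per_class cells per type (recycled to \code{n_classes}).
#' @param n_genes total genes.
#' @param signature_size signature genes per class (disjoint sets).
#' @param effect log2 shift applied to a class's signature genes in its own
#'   cells; 0 gives inseparable classes (a warning is recorded in the truth).
#' @param dispersion negative binomial size parameter.
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-gene
#'   baseline log2 means.
#' @param lib_size_sd lognormal sd of per-cell library scaling.
#' @param seed integer seed.
#' @return list with \code{matrix} (an \code{NOMatrix}: counts, lib_size,
#'   labels, gene metadata) and \code{truth} (labels, per-class signature
#'   gene sets, effect).
#' @export
simulate_no_matrix <- function(n_classes = 8, cells_per_class = 40,
                               n_genes = 8000, signature_size = 40,
                               effect = 1, dispersion = 2,
                               baseline_log2_mean = 4, baseline_log2_sd = 1,
                               lib_size_sd = 0.2, seed = 1L) {
  stopifnot(n_classes >= 2, n_genes >= n_classes * signature_size,
            signature_size >= 0, dispersion > 0)
  set.seed(as.integer(seed))
  warn <- NULL
  if (effect == 0 && signature_size > 0) {
    warn <- "effect = 0: classes are not separable by construction"
    warning(warn)
  }
  cpc <- rep_len(cells_per_class, n_classes)
  n_cells <- sum(cpc)
  classes <- paste0("class", seq_len(n_classes))
  labels <- factor(rep(classes, cpc), levels = classes)
  cells <- sprintf("cell%03d", seq_len(n_cells))
  genes <- sprintf("gene%04d", seq_len(n_genes))

  base_log2 <- rnorm(n_genes, baseline_log2_mean, baseline_log2_sd)
  sig <- split(genes[seq_len(n_classes * signature_size)],
               rep(classes, each = signature_size))
  sig <- sig[classes]

  cell_factor <- exp(rnorm(n_cells, 0, lib_size_sd))
  log2mu <- matrix(rep(base_log2, each = n_cells), n_cells, n_genes)
  for (k in seq_len(n_classes)) {
    gi <- match(sig[[k]], genes)
    log2mu[labels == classes[k], gi] <-
      log2mu[labels == classes[k], gi] + effect
  }
  mu <- 2^log2mu * cell_factor
  counts <- matrix(rnbinom(n_cells * n_genes, size = dispersion, mu = mu),
                   n_cells, n_genes, dimnames = list(cells, genes))

  ## gene metadata: autosomal coordinates on a synthetic genome
  gene_meta <- data.frame(gene = genes,
                          chrom = paste0("chr", rep_len(1:4, n_genes)),
                          start = 1e4 * seq_len(n_genes),
                          end = 1e4 * seq_len(n_genes) + 5e3,
                          stringsAsFactors = FALSE)

  m <- structure(list(counts = counts, lib_size = rowSums(counts),
                      labels = labels, genes = gene_meta),
                 class = "NOMatrix")
  truth <- list(labels = labels, signature_genes = sig, effect = effect,
                warning = warn)
  list(matrix = m, truth = truth)
}

#' @export
print.NOMatrix <- function(x, ...) {
  cat("NOMatrix:", nrow(x$counts), "cells x", ncol(x$counts), "genes")
  if (!is.null(x$labels)) cat(";", nlevels(factor(x$labels)), "labelled classes")
  cat("\n")
  invisible(x)
}
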