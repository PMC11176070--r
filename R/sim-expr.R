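#' Simulate single-cell UMI expression with planted CNA clones
#'
#' Emulates a cells-by-genes UMI count matrix with genomic gene coordinates.
#' For each declared clone, genes inside the clone's CNA region are scaled by
#' the region dosage (0.5 for a heterozygous loss, 1.5 for a gain) in carrier
#' cells, producing the bimodal region-level expression structure that
#' targeted CNA re-calling exploits.
#'
#' @param genes data.frame(gene, chrom, start, end); 0-based half-open.
#' @param n_cells number of cells.
#' @param clones optional data.frame(clone, chrom, start, end, dosage,
#'   cell_fraction); carrier sets are drawn independently per clone unless
#'   \code{nested = TRUE}, in which case each clone's carriers are drawn from
#'   the previous clone's carriers.
#' @param nested draw nested carrier sets (subclonal structure).
#' @param mean_umi expected UMIs per gene per cell before scaling.
#' @param dispersion negative binomial size.
#' @param lib_size_sd lognormal sd of per-cell depth.
#' @param celltypes optional character vector of cell-type names to assign
#'   uniformly at random (stored as metadata, used by Fisher enrichment).
#' @param celltype_bias optional named numeric: for carrier cells of clone 1,
#'   multiply these types' sampling weight (plants lineage bias).
#' @param seed integer seed.
#' @return list with \code{matrix} (an \code{ExpressionMatrix}: counts, gene
#'   metadata, per-cell metadata) and \code{truth} (per-clone carrier sets).
#' @export
simulate_expression <- function(genes, n_cells = 500, clones = NULL,
                                nested = FALSE, mean_umi = 2,
                                dispersion = 2, lib_size_sd = 0.2,
                                celltypes = NULL, celltype_bias = NULL,
                                seed = 1L) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(genes)),
            n_cells >= 2)
  set.seed(as.integer(seed))
  n_genes <- nrow(genes)
  cells <- sprintf("cell%04d", seq_len(n_cells))
  base <- mean_umi * exp(rnorm(n_genes, 0, 0.5))
  cell_factor <- exp(rnorm(n_cells, 0, lib_size_sd))
  dosage_mat <- matrix(1, n_cells, n_genes)

  carriers <- list()
  if (!is.null(clones) && nrow(clones)) {
    stopifnot(all(c("clone", "chrom", "start", "end", "dosage",
                    "cell_fraction") %in% names(clones)),
              all(clones$dosage > 0),
              all(clones$cell_fraction >= 0 & clones$cell_fraction <= 1))
    gene_gr <- as_granges0(genes)
    pool <- cells
    for (i in seq_len(nrow(clones))) {
      k <- round(clones$cell_fraction[i] * n_cells)
      src <- if (nested && i > 1) carriers[[i - 1]] else pool
      k <- min(k, length(src))
      carriers[[i]] <- sort(sample(src, k))
      region <- as_granges0(clones[i, , drop = FALSE])
      gi <- which(GenomicRanges::countOverlaps(gene_gr, region) > 0)
      ci <- which(cells %in% carriers[[i]])
      dosage_mat[ci, gi] <- dosage_mat[ci, gi] * clones$dosage[i]
    }
    names(carriers) <- clones$clone
  }

  mu <- outer(cell_factor, base) * dosage_mat
  counts <- matrix(rnbinom(length(mu), size = dispersion, mu = mu),
                   n_cells, n_genes, dimnames = list(cells, genes$gene))

  meta <- data.frame(cell = cells, stringsAsFactors = FALSE)
  if (!is.null(celltypes)) {
    w <- rep(1, length(celltypes))
    ct <- character(n_cells)
    for (i in seq_len(n_cells)) {
      wi <- w
      if (!is.null(celltype_bias) && length(carriers) &&
          cells[i] %in% carriers[[1]]) {
        j <- match(names(celltype_bias), celltypes)
        wi[j] <- wi[j] * celltype_bias
      }
      ct[i] <- sample(celltypes, 1, prob = wi)
    }
    meta$celltype <- ct
  }

  m <- structure(list(counts = counts, genes = genes, meta = meta),
                 class = "ExpressionMatrix")
  list(matrix = m, truth = list(clone_carriers = carriers, clones = clones))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$counts), "cells x", ncol(x$counts),
      "genes\n")
  invisible(x)
}
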