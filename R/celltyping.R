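## Nucleosome-occupancy (NO) cell typing.
##
## Gene-body MNase fragment counts are normalized to reads per million,
## log2-transformed and per-gene standardized; a two-stage PLS-DA variable
## importance in projection (VIP) selection against permutation nulls picks
## signature genes (stage 1: multi-class, VIP > 90th null percentile;
## stage 2: one-vs-rest per class, VIP > 95th null percentile), and a
## supervised PLS-DA classifier on the signature set assigns cell types.
## Gene activity is inferred as the NO Z-score multiplied by -1 (high
## occupancy = closed chromatin = low activity).

.default_ncomp <- function(n_classes, n_cells, n_genes) {
  max(1, min(n_classes - 1, 10, n_cells - 2, n_genes))
}

#' Normalize a nucleosome-occupancy matrix
#'
#' Scales each cell to reads per million (RPM), applies log2(RPM + 1), and
#' standardizes each gene to zero mean and unit sd across cells. When
#' \code{params} (training means/sds) is supplied, those are used instead of
#' the data's own statistics, which is what keeps test cells out of the
#' training normalization.
#'
#' @param m an \code{NOMatrix} (list with counts, lib_size, optional labels
#'   and gene metadata) or a plain cells-by-genes count matrix.
#' @param params optional list(gene_means, gene_sds) from a training fit.
#' @param pseudocount added to RPM before log2 (default 1).
#' @return a \code{NormalizedNOMatrix}: z (cells x genes), log2rpm,
#'   gene_means, gene_sds, labels, genes.
#' @export
normalize_no <- function(m, params = NULL, pseudocount = 1) {
  counts <- if (inherits(m, "NOMatrix")) m$counts else as.matrix(m)
  lib <- if (inherits(m, "NOMatrix")) m$lib_size else rowSums(counts)
  stopifnot(all(counts >= 0), all(lib > 0))
  rpm <- counts / lib * 1e6
  l2 <- log2(rpm + pseudocount)
  if (is.null(params)) {
    mu <- colMeans(l2)
    sds <- apply(l2, 2, sd)
  } else {
    mu <- params$gene_means[colnames(l2)]
    sds <- params$gene_sds[colnames(l2)]
  }
  z <- sweep(l2, 2, mu, "-")
  z <- sweep(z, 2, ifelse(sds > 0, sds, 1), "/")
  z[, sds == 0] <- 0
  structure(list(z = z, log2rpm = l2, gene_means = mu, gene_sds = sds,
                 labels = if (inherits(m, "NOMatrix")) m$labels else NULL,
                 genes = if (inherits(m, "NOMatrix")) m$genes else NULL),
            class = "NormalizedNOMatrix")
}

#' Infer gene activity from normalized nucleosome occupancy
#'
#' Gene activity is the NO Z-score multiplied by -1: nucleosome occupancy is
#' inversely related to chromatin accessibility and hence to inferred
#' activity.
#'
#' @param norm a \code{NormalizedNOMatrix} or a Z-score matrix.
#' @return activity matrix (cells x genes).
#' @export
infer_gene_activity <- function(norm) {
  z <- if (inherits(norm, "NormalizedNOMatrix")) norm$z else as.matrix(norm)
  -z
}

## variable autosomal genes: training sd > sd_min and not on a sex chromosome
.stage_gene_filter <- function(norm, sd_min = 0) {
  ok <- norm$gene_sds > sd_min
  if (!is.null(norm$genes)) {
    auto <- !(norm$genes$chrom %in% c("chrX", "chrY", "X", "Y"))
    ok <- ok & auto[match(colnames(norm$z), norm$genes$gene)]
  }
  colnames(norm$z)[which(ok)]
}

.fit_vip <- function(X, y, ncomp) {
  fit <- mixOmics::plsda(X, y, ncomp = ncomp)
  v <- mixOmics::vip(fit)
  v[, ncol(v)]
}

#' Stage-1 PLS-DA VIP feature selection (multi-class)
#'
#' Fits a multi-class PLS-DA of the normalized NO matrix (variable autosomal
#' genes) against the cell-type labels, scores every gene by its VIP, and
#' retains genes whose VIP exceeds the 90th percentile of a pooled null
#' distribution built from \code{n_perm} label-permuted refits.
#'
#' @param norm a \code{NormalizedNOMatrix}.
#' @param labels factor of cell types (defaults to \code{norm$labels}).
#' @param n_perm label permutations for the null (must be >= 1).
#' @param null_quantile percentile of the pooled null used as threshold
#'   (default 0.90).
#' @param ncomp PLS components (default min(n_classes - 1, 10)).
#' @param seed integer seed.
#' @return data.frame \code{FeatureScore}: gene, vip, threshold, selected,
#'   stage = 1.
#' @export
select_features_stage1 <- function(norm, labels = norm$labels, n_perm = 20,
                                   null_quantile = 0.90, ncomp = NULL,
                                   seed = 1L) {
  stopifnot(inherits(norm, "NormalizedNOMatrix"), !is.null(labels))
  if (n_perm < 1) stop("null distribution requires permutations (n_perm >= 1)")
  labels <- droplevels(factor(labels))
  stopifnot(nlevels(labels) >= 2)
  set_seed_if(seed)
  genes <- .stage_gene_filter(norm)
  X <- norm$z[, genes, drop = FALSE]
  ncomp <- ncomp %||% .default_ncomp(nlevels(labels), nrow(X), ncol(X))
  vip_obs <- .fit_vip(X, labels, ncomp)
  null <- unlist(lapply(seq_len(n_perm), function(i) {
    .fit_vip(X, sample(labels), ncomp)
  }))
  thr <- quantile(null, null_quantile, names = FALSE)
  data.frame(gene = genes, vip = unname(vip_obs), threshold = thr,
             selected = unname(vip_obs) > thr, stage = 1L,
             stringsAsFactors = FALSE)
}

#' Stage-2 PLS-DA VIP feature selection (one class vs rest)
#'
#' For each cell type, fits a binary PLS-DA of the stage-1 genes against
#' membership in that type and keeps genes with VIP above the 95th
#' percentile of the class's label-permuted null. The signature set is the
#' union over classes, with class attribution.
#'
#' @param norm a \code{NormalizedNOMatrix}.
#' @param labels factor of cell types.
#' @param stage1_genes character vector of genes retained by stage 1.
#' @param n_perm label permutations per class.
#' @param null_quantile null percentile threshold (default 0.95).
#' @param ncomp PLS components for the binary fits (default 2).
#' @param seed integer seed.
#' @return list with \code{scores} (data.frame gene, class, vip, threshold,
#'   selected, stage = 2) and \code{signature} (data.frame gene, class of
#'   selected genes; union over classes).
#' @export
select_features_stage2 <- function(norm, labels = norm$labels, stage1_genes,
                                   n_perm = 20, null_quantile = 0.95,
                                   ncomp = 2, seed = 1L) {
  stopifnot(inherits(norm, "NormalizedNOMatrix"), length(stage1_genes) >= 2)
  if (n_perm < 1) stop("null distribution requires permutations (n_perm >= 1)")
  if (!is.factor(labels)) labels <- factor(labels)
  # declared factor levels are kept: an absent class must error, not vanish
  set_seed_if(seed)
  miss <- setdiff(levels(labels), unique(as.character(labels)))
  if (length(miss)) stop("class absent from labels: ",
                         paste(miss, collapse = ", "))
  X <- norm$z[, stage1_genes, drop = FALSE]
  out <- list()
  for (cl in levels(labels)) {
    y <- factor(ifelse(labels == cl, cl, "rest"), levels = c("rest", cl))
    nc <- max(1, min(ncomp, nrow(X) - 2))
    vip_obs <- .fit_vip(X, y, nc)
    null <- unlist(lapply(seq_len(n_perm), function(i) {
      .fit_vip(X, sample(y), nc)
    }))
    thr <- quantile(null, null_quantile, names = FALSE)
    out[[cl]] <- data.frame(gene = stage1_genes, class = cl,
                            vip = unname(vip_obs), threshold = thr,
                            selected = unname(vip_obs) > thr, stage = 2L,
                            stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, out)
  rownames(scores) <- NULL
  sig <- scores[scores$selected, c("gene", "class")]
  sig <- sig[!duplicated(sig$gene), , drop = FALSE]
  list(scores = scores, signature = sig)
}

#' Train a nucleosome-occupancy cell-type classifier
#'
#' Supervised PLS-DA on the signature genes. The training normalization
#' parameters (per-gene mean and sd of log2 RPM) are stored with the model
#' and reused verbatim at prediction time.
#'
#' @param norm a \code{NormalizedNOMatrix} of the training cells.
#' @param labels factor of cell types.
#' @param signature_genes character vector of signature genes.
#' @param ncomp PLS components (default min(n_classes - 1, 10)).
#' @return a \code{CellTypeClassifier}.
#' @export
train_celltype_classifier <- function(norm, labels = norm$labels,
                                      signature_genes, ncomp = NULL) {
  stopifnot(inherits(norm, "NormalizedNOMatrix"),
            all(signature_genes %in% colnames(norm$z)))
  labels <- droplevels(factor(labels))
  X <- norm$z[, signature_genes, drop = FALSE]
  ncomp <- ncomp %||% .default_ncomp(nlevels(labels), nrow(X), ncol(X))
  fit <- mixOmics::plsda(X, labels, ncomp = ncomp)
  structure(list(fit = fit, signature = signature_genes,
                 classes = levels(labels), ncomp = ncomp,
                 gene_means = norm$gene_means[signature_genes],
                 gene_sds = norm$gene_sds[signature_genes]),
            class = "CellTypeClassifier")
}

.softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

#' Classify cells with a trained NO cell-type classifier
#'
#' New cells are RPM/log2 normalized and standardized with the training
#' parameters stored in the classifier (never with test-set statistics),
#' scored by the PLS-DA discriminant, and the scores mapped to class
#' probabilities by softmax. Ties are broken by class order with a warning.
#'
#' @param clf a \code{CellTypeClassifier}.
#' @param m an \code{NOMatrix} or raw count matrix of new cells.
#' @return \code{CellTypePosterior} data.frame: cell, assigned class,
#'   margin (top1 - top2 probability) and one probability column per class.
#' @export
classify_cells <- function(clf, m) {
  stopifnot(inherits(clf, "CellTypeClassifier"))
  norm <- normalize_no(m, params = list(gene_means = clf$gene_means,
                                        gene_sds = clf$gene_sds))
  X <- norm$z[, clf$signature, drop = FALSE]
  pr <- predict(clf$fit, X)
  scores <- pr$predict[, , clf$ncomp, drop = TRUE]
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1,
                                             dimnames = list(rownames(X),
                                                             clf$classes))
  probs <- t(apply(scores, 1, .softmax))
  colnames(probs) <- clf$classes
  top <- apply(probs, 1, function(p) {
    o <- order(p, decreasing = TRUE)
    if (length(p) > 1 && p[o[1]] == p[o[2]]) {
      warning("tied class probabilities; breaking by class order")
    }
    c(which.max(p), sort(p, decreasing = TRUE)[1] -
        if (length(p) > 1) sort(p, decreasing = TRUE)[2] else 0)
  })
  data.frame(cell = rownames(X), class = clf$classes[top[1, ]],
             margin = top[2, ], probs, check.names = FALSE,
             stringsAsFactors = FALSE)
}

## rank-based (Mann-Whitney) AUC of scores for a binary indicator
.auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-out cross-validated per-class AUC
#'
#' For each cell: recompute the normalization on the remaining cells, refit
#' the PLS-DA on them (the signature gene set is held fixed), and score the
#' held-out cell. Per-class one-vs-rest AUCs are computed from the resulting
#' out-of-fold class scores. Classes with a single cell yield NA.
#'
#' @param norm a \code{NormalizedNOMatrix} (its \code{log2rpm} slot is used
#'   so each fold can restandardize on training cells only).
#' @param labels factor of cell types.
#' @param signature_genes signature gene set (held fixed across folds).
#' @param ncomp PLS components.
#' @return list with \code{auc} (named per-class vector), \code{mean_auc}
#'   and \code{scores} (out-of-fold cells x classes score matrix).
#' @export
loocv_auc <- function(norm, labels = norm$labels, signature_genes,
                      ncomp = NULL) {
  stopifnot(inherits(norm, "NormalizedNOMatrix"))
  labels <- droplevels(factor(labels))
  l2 <- norm$log2rpm[, signature_genes, drop = FALSE]
  n <- nrow(l2)
  ncomp <- ncomp %||% .default_ncomp(nlevels(labels), n - 1, ncol(l2))
  scores <- matrix(NA_real_, n, nlevels(labels),
                   dimnames = list(rownames(l2), levels(labels)))
  for (i in seq_len(n)) {
    tr <- l2[-i, , drop = FALSE]
    mu <- colMeans(tr); sds <- apply(tr, 2, sd)
    sds[sds == 0] <- 1
    Ztr <- sweep(sweep(tr, 2, mu, "-"), 2, sds, "/")
    Zte <- (l2[i, ] - mu) / sds
    fit <- mixOmics::plsda(Ztr, labels[-i], ncomp = ncomp)
    pr <- predict(fit, matrix(Zte, nrow = 1,
                              dimnames = list(rownames(l2)[i],
                                              colnames(l2))))
    s <- pr$predict[1, , ncomp]
    scores[i, colnames(pr$predict)] <- s
  }
  auc <- vapply(levels(labels), function(cl) {
    if (sum(labels == cl) < 2) return(NA_real_)
    .auc(scores[, cl], labels == cl)
  }, numeric(1))
  list(auc = auc, mean_auc = mean(auc, na.rm = TRUE), scores = scores)
}

#' Differential gene activity between genotype groups, cell-type aware
#'
#' Cell type is treated as a confounder: each gene's normalized NO is
#' regressed on the cell-type indicators and the genotype contrast is
#' evaluated on the residuals along the first PLS-DA latent direction. The
#' gene-level statistic is the gene's unnormalized component-1 weight, i.e.
#' the absolute covariance between its residual profile and the genotype
#' indicator (the cross-gene VIP normalization is deliberately not applied
#' to the test statistic: it couples every gene's null to the strongest
#' genes in the matrix and miscalibrates per-gene permutation p-values).
#' Significance per gene comes from \code{n_perm} genotype-label
#' permutations with BH FDR across genes. Direction is reported on the
#' activity scale (-Z): a gene whose residual NO is lower in mutant cells
#' has activity "up". Genes overlapping \code{masked_region} are flagged
#' and excluded from testing (no q-value).
#'
#' @param norm a \code{NormalizedNOMatrix} with gene metadata.
#' @param genotype factor/character with two levels; a level named "WT" is
#'   the baseline if present, otherwise the first factor level.
#' @param celltype factor of per-cell (predicted) cell types.
#' @param masked_region optional data.frame(chrom, start, end) of regions
#'   whose genes are masked (e.g. the deleted segment itself).
#' @param n_perm genotype permutations (default 500; the attainable p floor
#'   is 1/(n_perm + 1), so n_perm must be large relative to the number of
#'   genes divided by the FDR level for BH to have any power).
#' @param fdr BH threshold used for the significant flag (default 0.1).
#' @param seed integer seed.
#' @return data.frame \code{DiffNOResult}: gene, activity_effect (mutant -
#'   WT on the activity scale), direction, vip (relative VIP of the
#'   observed fit, for reference), p, q, masked, significant.
#' @export
differential_gene_activity <- function(norm, genotype, celltype = NULL,
                                       masked_region = NULL, n_perm = 500,
                                       fdr = 0.1, seed = 1L) {
  stopifnot(inherits(norm, "NormalizedNOMatrix"))
  genotype <- droplevels(factor(genotype))
  stopifnot(nlevels(genotype) == 2)
  if (min(table(genotype)) < 3) stop("insufficient cells in a genotype group")
  if ("WT" %in% levels(genotype)) genotype <- stats::relevel(genotype, "WT")
  set_seed_if(seed)
  Z <- norm$z
  ## regress out cell type per gene
  if (!is.null(celltype)) {
    ct <- droplevels(factor(celltype))
    if (nlevels(ct) >= 2) {
      mm <- stats::model.matrix(~ ct)
      qr_ <- qr(mm)
      Z <- Z - mm %*% qr.coef(qr_, Z)
    }
  }
  genes <- colnames(Z)
  masked <- rep(FALSE, length(genes))
  if (!is.null(masked_region) && !is.null(norm$genes)) {
    gm <- norm$genes[match(genes, norm$genes$gene), ]
    gg <- as_granges0(gm)
    mr <- as_granges0(masked_region)
    masked <- GenomicRanges::countOverlaps(gg, mr) > 0
  }
  keep <- which(!masked)
  Xk <- Z[, keep, drop = FALSE]
  vip_obs <- .fit_vip(Xk, genotype, 1)
  ## gene-level statistic: |comp-1 weight before normalization| =
  ## |cov(residual gene profile, genotype indicator)|
  yc <- as.numeric(genotype) - mean(as.numeric(genotype))
  stat_obs <- abs(drop(crossprod(Xk, yc)))
  exceed <- numeric(length(keep))
  for (b in seq_len(n_perm)) {
    sp <- abs(drop(crossprod(Xk, sample(yc))))
    exceed <- exceed + (sp >= stat_obs)
  }
  p <- (1 + exceed) / (n_perm + 1)
  q <- p.adjust(p, method = "BH")
  mut <- levels(genotype)[2]
  eff_no <- colMeans(Z[genotype == mut, , drop = FALSE]) -
    colMeans(Z[genotype != mut, , drop = FALSE])
  res <- data.frame(gene = genes, activity_effect = -eff_no,
                    direction = ifelse(-eff_no > 0, "up", "down"),
                    vip = NA_real_, p = NA_real_, q = NA_real_,
                    masked = masked, significant = FALSE,
                    stringsAsFactors = FALSE)
  res$vip[keep] <- vip_obs
  res$p[keep] <- p
  res$q[keep] <- q
  res$significant[keep] <- q < fdr
  rownames(res) <- NULL
  res
}
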