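## Targeted CNA re-calling from single-cell expression: per-region average
## expression is fit with 1- vs 2-component Gaussian mixtures; bimodality
## (BIC preference + chi-squared LRT at 1% FDR) indicates a dosage subclone,
## and component posteriors assign cells to clones at a 0.8 cutoff.

#' Normalize UMI counts to log2(CPM/10 + 1)
#'
#' @param m an \code{ExpressionMatrix} or raw cells-by-genes count matrix.
#' @return cells-by-genes normalized matrix.
#' @examples
#' m <- matrix(c(10, 0), 1, 2)
#' # with a library of 10 reads, CPM of gene 1 is 1e6
#' normalize_expression(m)
#' @export
normalize_expression <- function(m) {
  counts <- if (inherits(m, "ExpressionMatrix")) m$counts else as.matrix(m)
  stopifnot(all(counts >= 0))
  lib <- rowSums(counts)
  lib[lib == 0] <- 1
  cpm <- counts / lib * 1e6
  log2(cpm / 10 + 1)
}

## EM for a 1-D two-component Gaussian mixture with a shared variance
## (a copy-number dosage shift displaces the component mean; the
## measurement noise of the region score is common to both clones, and the
## shared-variance model stays identifiable at moderate separation where
## the free-variance mixture is not). Best of `restarts` random starts;
## the log-likelihood is checked to be non-decreasing within each run.
.em_mixture2 <- function(x, restarts = 10, tol = 1e-6, max_iter = 500,
                         seed = NULL) {
  set_seed_if(seed)
  n <- length(x)
  sd_floor <- max(sd(x), 1e-6) * 1e-3
  best <- NULL
  for (r in seq_len(restarts)) {
    mu <- as.numeric(quantile(x, sort(runif(2)), names = FALSE))
    s <- sd(x)
    w <- runif(1, 0.3, 0.7)
    ll_prev <- -Inf
    monotone <- TRUE
    for (it in seq_len(max_iter)) {
      d1 <- w * dnorm(x, mu[1], s)
      d2 <- (1 - w) * dnorm(x, mu[2], s)
      tot <- pmax(d1 + d2, .Machine$double.xmin)
      ll <- sum(log(tot))
      if (ll < ll_prev - 1e-8) monotone <- FALSE
      if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) break
      ll_prev <- ll
      g <- d1 / tot
      w <- min(max(mean(g), 1e-6), 1 - 1e-6)
      mu[1] <- sum(g * x) / sum(g)
      mu[2] <- sum((1 - g) * x) / sum(1 - g)
      s <- max(sqrt(sum(g * (x - mu[1])^2 + (1 - g) * (x - mu[2])^2) / n),
               sd_floor)
    }
    fit <- list(w = w, mu = mu, sd = c(s, s), loglik = ll_prev,
                converged = it < max_iter, monotone = monotone,
                iterations = it)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ## order components by mean
  if (best$mu[1] > best$mu[2]) {
    best$mu <- rev(best$mu); best$w <- 1 - best$w
  }
  best
}

#' Fit 1- vs 2-component mixtures to a region's expression scores
#'
#' The per-cell region score is the mean of the z-scaled (per gene, across
#' cells) normalized expression over the region's expressed genes, minus the
#' cell's grand mean over all genes. The grand-mean term removes the
#' per-cell depth/dropout common factor that otherwise skews the null score
#' distribution and inflates the mixture likelihood ratio. Regions
#' with fewer than \code{min_genes} expressed genes are skipped (returned
#' with \code{skipped = TRUE} and a reason). Otherwise a single Gaussian and
#' a shared-variance two-component Gaussian mixture (EM, \code{restarts}
#' random starts) are fit; the fit records both BICs and the chi-squared
#' LRT p-value (df = 2: extra mean and weight).
#'
#' @param norm normalized expression matrix from
#'   \code{\link{normalize_expression}}.
#' @param region_genes character vector of gene names in the region.
#' @param region_id identifier for reporting.
#' @param min_genes minimum expressed genes required (default 5).
#' @param restarts,seed EM restarts and seed.
#' @return a \code{MixtureFit} list: region, n_genes_expressed, scores,
#'   coverage (per-cell nonzero region genes), fit1, fit2, bic1, bic2,
#'   lrt_p, skipped/skip_reason.
#' @export
region_mixture_test <- function(norm, region_genes, region_id = "region",
                                min_genes = 5, restarts = 10, seed = 1L) {
  region_genes <- intersect(region_genes, colnames(norm))
  sub <- norm[, region_genes, drop = FALSE]
  expressed <- colSums(sub > 0) > 0
  n_expr <- sum(expressed)
  if (n_expr < min_genes) {
    return(structure(list(region = region_id, n_genes_expressed = n_expr,
                          skipped = TRUE,
                          skip_reason = sprintf(
                            "only %d expressed genes (< %d required)",
                            n_expr, min_genes)),
                     class = "MixtureFit"))
  }
  sub <- sub[, expressed, drop = FALSE]
  zscale <- function(m) {
    sds <- apply(m, 2, sd)
    sweep(sweep(m, 2, colMeans(m), "-"), 2, ifelse(sds > 0, sds, 1), "/")
  }
  ## per-cell normalization factor: grand mean over all (z-scaled) genes
  grand <- rowMeans(zscale(norm))
  raw <- rowMeans(zscale(sub)) - grand
  score <- (raw - mean(raw)) / max(sd(raw), 1e-12)
  n <- length(score)
  fit1 <- list(mu = mean(score), sd = max(sd(score), 1e-12))
  ll1 <- sum(dnorm(score, fit1$mu, fit1$sd, log = TRUE))
  fit2 <- .em_mixture2(score, restarts = restarts, seed = seed)
  if (!fit2$converged) {
    fit2 <- .em_mixture2(score, restarts = 2 * restarts,
                         seed = if (is.null(seed)) NULL else seed + 1L)
  }
  ll2 <- fit2$loglik
  bic1 <- -2 * ll1 + 2 * log(n)
  bic2 <- -2 * ll2 + 4 * log(n)
  lrt <- max(0, 2 * (ll2 - ll1))
  p <- pchisq(lrt, df = 2, lower.tail = FALSE)
  structure(list(region = region_id, n_genes_expressed = n_expr,
                 scores = score, coverage = rowSums(sub > 0),
                 fit1 = c(fit1, loglik = ll1), fit2 = fit2,
                 bic1 = bic1, bic2 = bic2, lrt_p = p,
                 skipped = FALSE, skip_reason = NA_character_),
            class = "MixtureFit")
}

#' @export
print.MixtureFit <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat("MixtureFit", x$region, "- skipped:", x$skip_reason, "\n")
  } else {
    cat(sprintf(
      "MixtureFit %s: %d expressed genes, BIC1 = %.1f, BIC2 = %.1f, LRT p = %.3g\n",
      x$region, x$n_genes_expressed, x$bic1, x$bic2, x$lrt_p))
  }
  invisible(x)
}

#' FDR-adjust mixture fits across regions and flag bimodality
#'
#' BH-adjusts the LRT p-values across all tested (non-skipped) regions; a
#' region is flagged bimodal when q < \code{fdr} AND the two-component BIC
#' beats the one-component BIC.
#'
#' @param fits list of \code{MixtureFit}s.
#' @param fdr FDR threshold (default 0.01).
#' @return the fits, each with \code{q} and \code{bimodal} set.
#' @export
adjust_mixture_fdr <- function(fits, fdr = 0.01) {
  tested <- !vapply(fits, function(f) isTRUE(f$skipped), logical(1))
  p <- vapply(fits[tested], function(f) f$lrt_p, numeric(1))
  q <- p.adjust(p, method = "BH")
  j <- 1
  for (i in seq_along(fits)) {
    if (!tested[i]) next
    fits[[i]]$q <- q[j]
    fits[[i]]$bimodal <- q[j] < fdr && fits[[i]]$bic2 < fits[[i]]$bic1
    j <- j + 1
  }
  fits
}

#' Assign cells to normal vs CNA clones from a bimodal fit
#'
#' Posterior responsibilities of the two components give each cell a
#' probability of belonging to the CNA clone: for a deletion (dosage < 1)
#' the lower-mean component is the CNA clone, for a duplication the
#' higher-mean one. Cells with posterior >= 0.8 for either clone are
#' assigned; the rest, and cells with zero region coverage, are unassigned.
#' CF is the fraction of CNA cells among assigned cells.
#'
#' @param fit a \code{MixtureFit} (not skipped).
#' @param dosage expected region dosage (e.g. 0.5 heterozygous loss, 1.5
#'   gain); required to orient the components.
#' @param posterior_cutoff assignment threshold (default 0.8).
#' @return \code{CNACallResult} list: per-cell posterior_cna, assignment
#'   (normal/CNA/unassigned), cf, n_assigned.
#' @export
assign_clones <- function(fit, dosage = NULL, posterior_cutoff = 0.8) {
  stopifnot(inherits(fit, "MixtureFit"), !isTRUE(fit$skipped))
  if (is.null(dosage)) stop("dosage direction required")
  f <- fit$fit2
  x <- fit$scores
  d1 <- f$w * dnorm(x, f$mu[1], f$sd[1])
  d2 <- (1 - f$w) * dnorm(x, f$mu[2], f$sd[2])
  post_low <- d1 / (d1 + d2)
  post_cna <- if (dosage < 1) post_low else 1 - post_low
  assignment <- ifelse(post_cna >= posterior_cutoff, "CNA",
                       ifelse(1 - post_cna >= posterior_cutoff, "normal",
                              "unassigned"))
  assignment[fit$coverage == 0] <- "unassigned"
  n_assigned <- sum(assignment != "unassigned")
  cf <- if (n_assigned) sum(assignment == "CNA") / n_assigned else NA_real_
  structure(list(region = fit$region, posterior_cna = post_cna,
                 assignment = assignment, cf = cf,
                 n_assigned = n_assigned),
            class = "CNACallResult")
}

#' @export
print.CNACallResult <- function(x, ...) {
  cat(sprintf("CNACallResult %s: CF = %.3f (%d of %d assigned cells)\n",
              x$region, x$cf, sum(x$assignment == "CNA"), x$n_assigned))
  invisible(x)
}

#' Fisher-test cell-type enrichment of an expression-defined clone
#'
#' Per cell type, a 2x2 Fisher's exact test (in clone vs not, is type vs
#' not) with BH correction across types.
#'
#' @param in_clone logical vector, cell in CNA clone.
#' @param celltype per-cell type labels (same length).
#' @param fdr BH threshold for the enriched flag (default 0.05).
#' @return data.frame: celltype, k_in, n_in, k_out, n_out, odds_ratio, p, q,
#'   enriched.
#' @export
clone_celltype_fisher <- function(in_clone, celltype, fdr = 0.05) {
  stopifnot(length(in_clone) == length(celltype))
  types <- sort(unique(as.character(celltype)))
  res <- lapply(types, function(tp) {
    tab <- matrix(c(sum(in_clone & celltype == tp),
                    sum(in_clone & celltype != tp),
                    sum(!in_clone & celltype == tp),
                    sum(!in_clone & celltype != tp)), 2, 2)
    ft <- fisher.test(tab)
    data.frame(celltype = tp, k_in = tab[1, 1], n_in = sum(tab[, 1]),
               k_out = tab[1, 2], n_out = sum(tab[, 2]),
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, method = "BH")
  out$enriched <- out$q < fdr & out$odds_ratio > 1
  out
}

#' Pairwise clone co-occurrence across CNA regions
#'
#' For each pair of regions, a 2x2 Fisher test of joint clone membership
#' among cells assigned in both regions, plus the nested-clone consistency
#' score P(carrier of B | carrier of A).
#'
#' @param assignments named list of \code{CNACallResult}s (or of character
#'   vectors of assignments) over the same cells.
#' @return data.frame: region_a, region_b, n_both_assigned, odds_ratio, p,
#'   p_b_given_a.
#' @export
clone_cooccurrence <- function(assignments) {
  get_assign <- function(a) if (inherits(a, "CNACallResult")) a$assignment else a
  nm <- names(assignments)
  stopifnot(length(assignments) >= 2, !is.null(nm))
  out <- list()
  for (i in seq_len(length(assignments) - 1)) {
    for (j in seq(i + 1, length(assignments))) {
      a <- get_assign(assignments[[i]]); b <- get_assign(assignments[[j]])
      keep <- a != "unassigned" & b != "unassigned"
      ca <- a[keep] == "CNA"; cb <- b[keep] == "CNA"
      tab <- table(factor(ca, c(FALSE, TRUE)), factor(cb, c(FALSE, TRUE)))
      ft <- fisher.test(tab)
      out[[length(out) + 1]] <- data.frame(
        region_a = nm[i], region_b = nm[j], n_both_assigned = sum(keep),
        odds_ratio = unname(ft$estimate), p = ft$p.value,
        p_b_given_a = if (sum(ca)) mean(cb[ca]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
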