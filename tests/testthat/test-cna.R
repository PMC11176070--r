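# Targeted CNA re-calling from expression: normalization, mixture fits,
# clone assignment, Fisher enrichment and co-occurrence.

test_that("expression normalization is log2(CPM/10 + 1) and depth-free", {
  m <- rbind(a = c(10, 999990), b = c(30, 299970))
  colnames(m) <- c("g1", "g2")
  norm <- normalize_expression(m)
  expect_equal(norm["a", "g1"], 1)          # CPM 10 -> log2(2) = 1
  expect_equal(normalize_expression(m * 3)["a", ], norm["a", ])
  expect_equal(normalize_expression(rbind(c(0, 5)))[1, 1], 0)
  expect_error(normalize_expression(rbind(c(-1, 5))))
})

test_that("regions below the expressed-gene minimum are skipped", {
  set.seed(1)
  m <- matrix(rpois(100 * 10, 3), 100, 10,
              dimnames = list(sprintf("c%03d", 1:100), paste0("g", 1:10)))
  m[, 5] <- 0L  # gene without any count is not expressed
  norm <- normalize_expression(m)
  fit <- region_mixture_test(norm, paste0("g", 1:5), min_genes = 5)
  expect_true(fit$skipped)
  expect_match(fit$skip_reason, "4 expressed")
  fit2 <- region_mixture_test(norm, paste0("g", 1:6), min_genes = 5)
  expect_false(fit2$skipped)
  expect_equal(fit2$n_genes_expressed, 5)
})

test_that("EM is monotone and matches the reference mixture fit", {
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  set.seed(4)
  x <- c(rnorm(300, -1, 0.5), rnorm(200, 1, 0.5))
  f <- mosaicscan:::.em_mixture2(x, restarts = 10, seed = 4)
  expect_true(f$monotone)
  expect_true(f$converged)
  ## independent oracle: mclust equal-variance two-component fit
  mc <- mclust::Mclust(x, G = 2, modelNames = "E", verbose = FALSE)
  expect_equal(f$loglik, mc$loglik, tolerance = 1e-4)
  expect_equal(sort(f$mu), sort(unname(mc$parameters$mean)),
               tolerance = 0.05)
})

test_that("planted dosage-0.5 clone is flagged bimodal and assigned accurately", {
  genes <- toy_gene_table(24, 1976)
  clones <- data.frame(clone = "del17", chrom = "chr17", start = 1e5,
                       end = 24e5 + 5e4, dosage = 0.5, cell_fraction = 0.5)
  sim <- simulate_expression(genes, n_cells = 800, clones = clones,
                             seed = 17)
  norm <- normalize_expression(sim$matrix)
  fit <- region_mixture_test(norm, genes$gene[1:24], region_id = "del17",
                             seed = 17)
  fit <- adjust_mixture_fdr(list(fit))[[1]]
  expect_true(fit$bimodal)
  expect_lt(fit$bic2, fit$bic1)
  expect_lt(fit$q, 0.01)
  cl <- assign_clones(fit, dosage = 0.5)
  expect_s3_class(cl, "CNACallResult")
  expect_setequal(unique(cl$assignment),
                  intersect(c("CNA", "normal", "unassigned"),
                            unique(cl$assignment)))
  truth <- rownames(sim$matrix$counts) %in% sim$truth$clone_carriers$del17
  a <- cl$assignment != "unassigned"
  acc <- mean((cl$assignment[a] == "CNA") == truth[a])
  expect_gte(acc, 0.9)
  expect_lt(abs(cl$cf - 0.5), 0.07)
})

test_that("null regions are rarely flagged bimodal at 1% FDR", {
  genes <- toy_gene_table(0, 600)
  sim <- simulate_expression(genes, n_cells = 500, clones = NULL, seed = 2)
  norm <- normalize_expression(sim$matrix)
  fits <- lapply(1:25, function(i) {
    region_mixture_test(norm, genes$gene[(i - 1) * 24 + 1:24],
                        region_id = paste0("r", i), seed = i)
  })
  fits <- adjust_mixture_fdr(fits)
  flagged <- vapply(fits, function(f) isTRUE(f$bimodal), logical(1))
  expect_lte(sum(flagged), 1)
})

test_that("assignment thresholds and dosage requirement are enforced", {
  fake <- structure(list(region = "r", scores = c(-2, -0.1, 2),
                         coverage = c(5, 5, 0),
                         fit2 = list(w = 0.5, mu = c(-1, 1),
                                     sd = c(0.7, 0.7))),
                    class = "MixtureFit")
  fake$skipped <- FALSE
  expect_error(assign_clones(fake), "dosage direction required")
  out <- assign_clones(fake, dosage = 0.5)
  # posterior for the middle cell is ~0.39/0.61: below 0.8 both ways
  expect_equal(out$assignment[2], "unassigned")
  expect_equal(out$assignment[1], "CNA")
  # the third cell is confidently normal by score but has zero coverage
  expect_equal(out$assignment[3], "unassigned")
  expect_equal(out$n_assigned, 1)
})

test_that("Fisher clone enrichment matches hypergeometric tail enumeration", {
  # oracle: two-sided Fisher p by enumerating all tables with the same
  # margins and summing probabilities <= that of the observed table
  oracle_fisher <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    lo <- max(0, k - n); hi <- min(k, m)
    probs <- vapply(lo:hi, function(x) {
      choose(m, x) * choose(n, k - x) / choose(m + n, k)
    }, numeric(1))
    obs <- probs[a - lo + 1]
    sum(probs[probs <= obs + 1e-12])
  }
  in_clone <- rep(c(TRUE, FALSE), c(100, 900))
  celltype <- c(rep("mono", 10), rep("other", 90),
                rep("mono", 50), rep("other", 850))
  res <- clone_celltype_fisher(in_clone, celltype)
  expect_equal(res$p[res$celltype == "mono"],
               oracle_fisher(10, 90, 50, 850), tolerance = 1e-8)
  # identical composition inside and outside: OR 1, p 1
  res0 <- clone_celltype_fisher(rep(c(TRUE, FALSE), each = 100),
                                rep(c("A", "B"), 100))
  expect_equal(res0$p, c(1, 1))
})

test_that("clone co-occurrence recognizes nested and disjoint structures", {
  cells <- sprintf("c%03d", 1:300)
  a <- ifelse(seq_along(cells) <= 150, "CNA", "normal")
  b <- ifelse(seq_along(cells) <= 75, "CNA", "normal")   # nested in a
  d <- ifelse(seq_along(cells) > 150, "CNA", "normal")   # disjoint from a
  res <- clone_cooccurrence(list(A = a, B = b, D = d))
  ab <- res[res$region_a == "A" & res$region_b == "B", ]
  expect_equal(ab$p_b_given_a, 0.5)
  ba_nested <- clone_cooccurrence(list(B = b, A = a))
  expect_equal(ba_nested$p_b_given_a, 1)  # every B carrier carries A
  ad <- res[res$region_a == "A" & res$region_b == "D", ]
  expect_lt(ad$odds_ratio, 1)
  expect_lt(ad$p, 1e-6)
})
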