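# Nucleosome-occupancy normalization, VIP selection, classification and
# differential activity.

small_no_sim <- function(effect = 1.5, seed = 1, n_classes = 3) {
  simulate_no_matrix(n_classes = n_classes, cells_per_class = 20,
                     n_genes = 400, signature_size = 15, effect = effect,
                     seed = seed)
}

test_that("normalization: RPM arithmetic, sd guard and scale invariance", {
  counts <- rbind(c(10, 999990), c(20, 199980))
  rownames(counts) <- c("a", "b"); colnames(counts) <- c("g1", "g2")
  m <- structure(list(counts = counts, lib_size = rowSums(counts)),
                 class = "NOMatrix")
  norm <- normalize_no(m)
  # cell a: library 1e6, count 10 -> RPM 10 -> log2(11)
  expect_equal(norm$log2rpm["a", "g1"], log2(10 + 1))
  # doubling every count of a cell leaves its RPM row unchanged
  counts2 <- counts; counts2["b", ] <- counts2["b", ] * 2
  m2 <- structure(list(counts = counts2, lib_size = rowSums(counts2)),
                  class = "NOMatrix")
  expect_equal(normalize_no(m2)$log2rpm["b", ], norm$log2rpm["b", ])
  # a gene constant across cells standardizes to zeros, not NaN
  cc <- cbind(g1 = c(5, 5), g2 = c(1, 9))
  rownames(cc) <- c("a", "b")
  mc <- structure(list(counts = cc, lib_size = c(10, 10)), class = "NOMatrix")
  expect_equal(unname(normalize_no(mc)$z[, "g1"]), c(0, 0))
})

test_that("gene activity is minus the NO Z-score (involution)", {
  z <- matrix(c(0, 2, -1.5, 0.3), 2, 2)
  act <- infer_gene_activity(z)
  expect_equal(act, -z)
  expect_equal(act[1, 1], 0)
  expect_equal(infer_gene_activity(act), z)
})

test_that("stage-1 selection requires permutations and is null-calibrated", {
  sim <- small_no_sim(effect = 1.2, seed = 3)
  norm <- normalize_no(sim$matrix)
  expect_error(select_features_stage1(norm, n_perm = 0),
               "requires permutations")
  # under label permutation the 90th-percentile null threshold retains
  # about 10% of genes
  set.seed(4)
  null_labels <- sample(sim$truth$labels)
  s1 <- select_features_stage1(norm, labels = null_labels, n_perm = 20,
                               seed = 4)
  frac <- mean(s1$selected)
  expect_lt(abs(frac - 0.10), 4 * sqrt(0.1 * 0.9 / nrow(s1)))
})

test_that("two-stage selection recovers planted signature genes", {
  # a realistic signature-to-background ratio: with nearly every stage-1
  # gene informative, permuted-label fits concentrate relative VIP on
  # whatever correlates by chance and the stage-2 null threshold saturates
  sim <- simulate_no_matrix(n_classes = 3, cells_per_class = 25,
                            n_genes = 1000, signature_size = 10,
                            effect = 1.5, seed = 5)
  norm <- normalize_no(sim$matrix)
  s1 <- select_features_stage1(norm, n_perm = 10, seed = 5)
  truth <- unlist(sim$truth$signature_genes)
  expect_gte(mean(truth %in% s1$gene[s1$selected]), 0.8)
  s2 <- select_features_stage2(norm, stage1_genes = s1$gene[s1$selected],
                               n_perm = 10, seed = 5)
  expect_true(all(s2$signature$gene %in% s1$gene[s1$selected]))
  expect_true(all(s2$signature$class %in% levels(sim$truth$labels)))
  # the signature is strongly enriched for planted genes over chance
  prec <- mean(s2$signature$gene %in% truth)
  expect_gt(prec, 5 * length(truth) / 1000)
  expect_gte(mean(truth %in% s2$signature$gene), 0.3)
  # under permuted labels each one-vs-rest stage keeps about 5% of genes
  set.seed(55)
  s2n <- select_features_stage2(norm, labels = sample(sim$truth$labels),
                                stage1_genes = s1$gene, n_perm = 20,
                                seed = 55)
  frac <- mean(s2n$scores$selected)
  expect_lt(abs(frac - 0.05), 4 * sqrt(0.05 * 0.95 / nrow(s2n$scores)))
  # a class absent from the labels is an error
  expect_error(
    select_features_stage2(norm, labels = factor(rep("classX", 60),
                                                 levels = c("classX", "classY")),
                           stage1_genes = s1$gene[s1$selected], n_perm = 2),
    "absent")
})

test_that("classifier: proper probabilities, centroid sanity, held-out accuracy", {
  sim <- small_no_sim(effect = 1.5, seed = 6)
  norm <- normalize_no(sim$matrix)
  truth <- unlist(sim$truth$signature_genes)
  clf <- train_celltype_classifier(norm, signature_genes = truth)
  post <- classify_cells(clf, sim$matrix)
  probs <- as.matrix(post[, clf$classes])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)))
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(post$class, as.character(sim$truth$labels))  # training acc 1
  # held-out cells from the same generative process
  sim2 <- small_no_sim(effect = 1.5, seed = 60)
  post2 <- classify_cells(clf, sim2$matrix)
  expect_gte(mean(post2$class == as.character(sim2$truth$labels)), 0.9)
})

test_that("train/test hygiene: held-out library scaling does not move features", {
  # classification uses training normalization parameters, so multiplying a
  # held-out cell's counts (library size) by a constant must not change its
  # posterior (RPM is scale-free and standardization is frozen)
  sim <- small_no_sim(effect = 1.5, seed = 8)
  norm <- normalize_no(sim$matrix)
  clf <- train_celltype_classifier(
    norm, signature_genes = unlist(sim$truth$signature_genes))
  cell <- sim$matrix$counts[1, , drop = FALSE]
  m1 <- structure(list(counts = cell, lib_size = sum(cell)),
                  class = "NOMatrix")
  m3 <- structure(list(counts = cell * 3, lib_size = sum(cell) * 3),
                  class = "NOMatrix")
  expect_equal(classify_cells(clf, m1)[, clf$classes],
               classify_cells(clf, m3)[, clf$classes])
})

test_that("LOOCV separates real labels from permuted labels", {
  sim <- small_no_sim(effect = 1.5, seed = 9)
  norm <- normalize_no(sim$matrix)
  sig <- unlist(sim$truth$signature_genes)
  cv <- loocv_auc(norm, signature_genes = sig)
  expect_gte(cv$mean_auc, 0.95)
  set.seed(10)
  cvn <- loocv_auc(norm, labels = sample(sim$truth$labels),
                   signature_genes = sig)
  expect_lt(abs(cvn$mean_auc - 0.5), 0.12)
  # single-cell class has no defined AUC
  lab <- as.character(sim$truth$labels)
  lab[1] <- "rare"; lab <- factor(lab)
  cv1 <- loocv_auc(norm, labels = lab, signature_genes = sig)
  expect_true(is.na(cv1$auc[["rare"]]))
})

test_that("differential activity is confounder-aware, masked and directional", {
  set.seed(12)
  n <- 60
  genes <- data.frame(gene = sprintf("g%03d", 1:200),
                      chrom = c(rep("chr7", 50), rep("chr2", 150)),
                      start = 1e5 * (1:200), end = 1e5 * (1:200) + 5e4)
  counts <- matrix(rnbinom(n * 200, size = 4, mu = 50), n, 200,
                   dimnames = list(sprintf("c%02d", 1:n), genes$gene))
  genotype <- rep(c("WT", "mutant"), each = n / 2)
  celltype <- rep(c("A", "B"), n / 2)
  # plant: genes 51-70 have lower NO (higher activity) in mutant cells;
  # genes 1-10 (inside the masked deleted region) get a huge shift that
  # must never be tested
  counts[genotype == "mutant", 51:70] <-
    matrix(rnbinom(sum(genotype == "mutant") * 20, size = 4, mu = 20),
           ncol = 20)
  counts[genotype == "mutant", 1:10] <- 0L
  m <- structure(list(counts = counts, lib_size = rowSums(counts),
                      labels = NULL, genes = genes), class = "NOMatrix")
  norm <- normalize_no(m)
  masked_region <- data.frame(chrom = "chr7", start = 0, end = 1.2e6 + 5e4)
  res <- differential_gene_activity(norm, genotype, celltype,
                                    masked_region = masked_region,
                                    n_perm = 500, fdr = 0.1, seed = 12)
  expect_true(all(res$masked[1:10]))
  expect_true(all(is.na(res$q[res$masked])))
  hits <- res$gene[which(res$significant)]
  planted <- genes$gene[51:70]
  expect_gte(mean(planted %in% hits), 0.7)
  expect_true(all(res$direction[res$gene %in% planted] == "up"))
  # group smaller than 3 cells is an error
  expect_error(
    differential_gene_activity(norm, c("mutant", rep("WT", n - 1)),
                               celltype, n_perm = 10),
    "insufficient")
})
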