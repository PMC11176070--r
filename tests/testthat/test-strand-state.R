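# Strand-state segmentation, SCE calling and footprint genotyping.

test_that("a pure Watson chromosome is a single WW segment", {
  bins <- toy_bins(n = 20)
  m <- manual_strand_matrix(bins, "cellA",
                            copies_w = matrix(2, 1, 20),
                            copies_c = matrix(0, 1, 20))
  seg <- call_strand_states(m)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$state, "WW")
  expect_equal(seg$start, 0)
  expect_equal(seg$end, 20e6)
})

test_that("a WW-to-WC transition yields two segments and one padded SCE call", {
  bins <- toy_bins(n = 40)
  cw <- matrix(c(rep(2, 20), rep(1, 20)), 1, 40)
  cc <- matrix(c(rep(0, 20), rep(1, 20)), 1, 40)
  m <- manual_strand_matrix(bins, "cellA", cw, cc)
  seg <- call_strand_states(m)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$state, c("WW", "WC"))
  sces <- detect_sces(seg)
  expect_equal(nrow(sces$calls), 1)
  # changepoint at the bin-20 boundary (20 Mb), padded by exactly 1 bp
  expect_equal(sces$calls$ci_start, 20e6 - 1)
  expect_equal(sces$calls$ci_end, 20e6 + 1)
})

test_that("multi-changepoint chromosomes go to review, not the callset", {
  bins <- toy_bins(n = 60)
  cw <- matrix(c(rep(2, 20), rep(1, 20), rep(2, 20)), 1, 60)
  cc <- matrix(c(rep(0, 20), rep(1, 20), rep(0, 20)), 1, 60)
  m <- manual_strand_matrix(bins, "cellA", cw, cc)
  sces <- detect_sces(call_strand_states(m))
  expect_equal(nrow(sces$calls), 0)
  expect_equal(nrow(sces$review), 1)
  expect_equal(sces$review$n_changepoints, 2)
})

test_that("a WW-to-CC change is flagged as candidate mSV, not SCE", {
  bins <- toy_bins(n = 40)
  cw <- matrix(c(rep(2, 20), rep(0, 20)), 1, 40)
  cc <- matrix(c(rep(0, 20), rep(2, 20)), 1, 40)
  sces <- detect_sces(call_strand_states(
    manual_strand_matrix(bins, "cellA", cw, cc)))
  expect_equal(nrow(sces$calls), 0)
  expect_equal(nrow(sces$msv_candidates), 1)
  expect_equal(sces$msv_candidates$flip, "WW>CC")
})

test_that("noise-free planted SCEs are recovered with precision = recall = 1", {
  # SCE positions confined to mid-chromosome so no changepoint falls within
  # the min_bins merge distance of a chromosome end
  g <- toy_genome(3)
  hs <- data.frame(chrom = names(g), start = 5e6, end = 45e6, rate = 1e6)
  cfg <- sim_config(g, bin_width = 1e6, n_cells = 30, reads_per_cell = 3000,
                    sce_rate = 1.5, sce_hotspots = hs,
                    background_noise = 0, seed = 21)
  sim <- simulate_strand_cells(cfg)
  seg <- call_strand_states(sim$matrix, error_rate = 0.01)
  sces <- detect_sces(seg)
  truth <- sim$truth$sce_positions
  truth_n <- table(truth$cell, truth$chrom)
  # precision: every call sits within one bin of a true SCE breakpoint
  # (SCE pairs closer than the bin resolution legitimately merge, leaving a
  # single observable changepoint at the remaining true breakpoint)
  n_single <- 0; n_hit <- 0
  for (i in seq_len(nrow(sces$calls))) {
    cl <- sces$calls[i, ]
    tr <- truth[truth$cell == cl$cell & truth$chrom == cl$chrom, ]
    expect_gte(nrow(tr), 1)
    expect_lt(min(abs(tr$pos - (cl$ci_start + cl$ci_end) / 2)), 1e6 + 1)
  }
  for (cell in rownames(truth_n)) for (ch in colnames(truth_n)) {
    if (truth_n[cell, ch] == 1) {
      n_single <- n_single + 1
      n_hit <- n_hit + any(sces$calls$cell == cell & sces$calls$chrom == ch)
    }
  }
  expect_equal(n_hit, n_single)  # recall = 1
})

test_that("footprint genotyper reads exact diagnostic footprints on WC ground", {
  # WC ground state; interval bins 21-30 carry the event footprint
  bins <- toy_bins(n = 50)
  mk <- function(w_in, c_in) {
    cw <- matrix(1, 1, 50); cc <- matrix(1, 1, 50)
    cw[21:30] <- w_in; cc[21:30] <- c_in
    manual_strand_matrix(bins, "cellA", cw, cc, depth_per_copy = 20)
  }
  events <- data.frame(chrom = "chr1", start = 20e6, end = 30e6)
  run <- function(m) {
    seg <- call_strand_states(m)
    genotype_footprints(m, seg, events)
  }
  expect_equal(run(mk(0, 1))$class, "del")     # 0W+1C: del of W homolog
  expect_equal(run(mk(0, 2))$class, "inv")     # 0W+2C: inversion of W homolog
  expect_equal(run(mk(2, 1))$class, "dup")     # 2W+1C: dup of W homolog
  expect_equal(nrow(run(mk(1, 1))), 0)         # reference: no call
})

test_that("genotyper recovers class, carriers and CF from simulation", {
  ev <- data.frame(class = c("del", "inv"), chrom = c("chr1", "chr2"),
                   start = c(10e6, 15e6), end = c(25e6, 35e6),
                   haplotype = c("H1", "H2"), cell_fraction = c(0.3, 0.226))
  cfg <- sim_config(toy_genome(2), bin_width = 1e6, n_cells = 100,
                    reads_per_cell = 800, sce_rate = 0, msv_events = ev,
                    background_noise = 0.02, seed = 13)
  sim <- simulate_strand_cells(cfg)
  seg <- call_strand_states(sim$matrix)
  calls <- genotype_footprints(sim$matrix, seg,
                               ev[, c("chrom", "start", "end")])
  expect_equal(calls$class, c("del", "inv"))
  for (i in 1:2) {
    truth_car <- sim$truth$msv_carriers[[paste0("event", i)]]
    expect_lt(abs(calls$cell_fraction[i] - length(truth_car) / 100), 0.05)
    acc <- mean(calls$carriers[[i]] %in% truth_car)
    expect_gte(acc, 0.95)
  }
})

test_that("interval shorter than one bin is rejected", {
  bins <- toy_bins(n = 10)
  m <- manual_strand_matrix(bins, "cellA", matrix(1, 1, 10), matrix(1, 1, 10))
  seg <- call_strand_states(m)
  expect_error(
    genotype_footprints(m, seg, data.frame(chrom = "chr1", start = 0,
                                           end = 1e5)),
    "shorter than one bin")
})

test_that("singleton/subclonal labelling and CF percentages", {
  calls <- data.frame(n_carriers = c(1, 19, 0), n_cells = c(43, 84, 50))
  expect_warning(out <- classify_singleton_subclonal(calls), "dropped")
  expect_equal(out$status, c("singleton", "subclonal"))
  expect_equal(out$cf_pct, c(2.3, 22.6))
  # CF monotone in carrier count
  k <- 0:84
  expect_true(all(diff(cf_pct(k, 84)) >= 0))
})
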