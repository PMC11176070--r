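#' Simulation configuration for strand-resolved single cells
#'
#' Declares the genome, per-cell sequencing depth, SCE rate (optionally
#' hotspot-weighted), planted mSV events and strand-mapping noise used by
#' \code{\link{simulate_strand_cells}}.
#'
#' @param genome named numeric vector of chromosome lengths (bp).
#' @param bin_width genomic bin width (bp).
#' @param n_cells number of cells.
#' @param reads_per_cell expected total reads per cell.
#' @param sce_rate expected SCEs per cell (Poisson).
#' @param sce_hotspots optional data.frame(chrom, start, end, rate) giving
#'   intervals with a relative SCE rate multiplier (0-based half-open).
#' @param msv_events optional data.frame(class, chrom, start, end, haplotype,
#'   cell_fraction) with class in del/dup/inv/invdup/chrom_loss and haplotype
#'   in H1/H2; coordinates 0-based half-open.
#' @param background_noise probability that a read maps to the wrong strand.
#' @param seed integer; fully determines the simulated output.
#' @return a \code{sim_config} list, validated.
#' @export
sim_config <- function(genome, bin_width = 1e6, n_cells = 50,
                       reads_per_cell = 400 * length(genome),
                       sce_rate = 4, sce_hotspots = NULL, msv_events = NULL,
                       background_noise = 0.02, seed = 1L) {
  stopifnot(length(genome) >= 1, !is.null(names(genome)), bin_width > 0,
            n_cells >= 1, reads_per_cell > 0, sce_rate >= 0,
            background_noise >= 0, background_noise < 0.5)
  if (!is.null(msv_events) && nrow(msv_events)) {
    stopifnot(all(c("class", "chrom", "start", "end", "haplotype",
                    "cell_fraction") %in% names(msv_events)))
    stopifnot(all(msv_events$class %in%
                    c("del", "dup", "inv", "invdup", "chrom_loss")),
              all(msv_events$haplotype %in% c("H1", "H2")),
              all(msv_events$cell_fraction >= 0 &
                    msv_events$cell_fraction <= 1),
              all(msv_events$chrom %in% names(genome)),
              all(msv_events$start >= 0),
              all(msv_events$end <= genome[msv_events$chrom]),
              all(msv_events$start < msv_events$end))
    ## events on the same haplotype must not overlap
    for (h in c("H1", "H2")) {
      ev <- msv_events[msv_events$haplotype == h, , drop = FALSE]
      if (nrow(ev) > 1) {
        gr <- as_granges0(ev)
        if (any(GenomicRanges::countOverlaps(gr, gr) > 1)) {
          stop("overlapping mSV events configured on the same haplotype")
        }
      }
    }
  }
  if (!is.null(sce_hotspots) && nrow(sce_hotspots)) {
    stopifnot(all(c("chrom", "start", "end", "rate") %in% names(sce_hotspots)),
              all(sce_hotspots$chrom %in% names(genome)),
              all(sce_hotspots$rate >= 0))
  }
  structure(list(genome = genome, bin_width = bin_width, n_cells = n_cells,
                 reads_per_cell = reads_per_cell, sce_rate = sce_rate,
                 sce_hotspots = sce_hotspots, msv_events = msv_events,
                 background_noise = background_noise,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## tile a genome into bins; returns data.frame(chrom,start,end) 0-based half-open
tile_genome <- function(genome, bin_width) {
  out <- lapply(names(genome), function(ch) {
    starts <- seq(0, genome[[ch]] - 1, by = bin_width)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_width, genome[[ch]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## fraction of each homolog copy in Watson orientation per bin, given the
## ground orientation and SCE breakpoints on that homolog (distal flips)
homolog_w_fraction <- function(bin_start, bin_end, ground_is_w, breaks) {
  n <- length(bin_start)
  if (!length(breaks)) return(rep(as.numeric(ground_is_w), n))
  breaks <- sort(breaks)
  ## orientation at position x flips once per breakpoint <= x
  fw <- numeric(n)
  for (i in seq_len(n)) {
    cuts <- breaks[breaks > bin_start[i] & breaks < bin_end[i]]
    edges <- c(bin_start[i], cuts, bin_end[i])
    widths <- diff(edges)
    nflips_before <- sum(breaks <= bin_start[i])
    ori <- (nflips_before + seq_along(widths) - 1) %% 2 == 0
    w <- ifelse(xor(!ground_is_w, ori), 1, 0)  # ori TRUE = ground orientation
    fw[i] <- sum(widths * w) / (bin_end[i] - bin_start[i])
  }
  fw
}

#' Simulate binned Watson/Crick strand counts for single cells
#'
#' Each cell inherits a random template-strand orientation per homolog per
#' chromosome (giving WW/WC/CW/CC ground states), accumulates Poisson read
#' counts per bin split across strands, acquires SCEs that flip one homolog
#' distal to a breakpoint, and — for carrier cells — the configured mSV
#' footprints (del: one haplotype copy lost in the interval; dup: gained;
#' inv: the haplotype's reads flip strand; invdup: an inverted extra copy;
#' chrom_loss: whole-chromosome haplotype loss). Strand-mapping noise
#' reassigns reads between Watson and Crick.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{matrix} (a \code{StrandCountMatrix}: bins, cells,
#'   W and C count matrices) and \code{truth} (SCE positions, ground states,
#'   carrier sets per event).
#' @examples
#' g <- c(chr1 = 50e6)
#' cfg <- sim_config(g, bin_width = 1e6, n_cells = 10, sce_rate = 1, seed = 7)
#' sim <- simulate_strand_cells(cfg)
#' dim(sim$matrix$W)
#' @export
simulate_strand_cells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genome <- config$genome
  bins <- tile_genome(genome, config$bin_width)
  n_bins <- nrow(bins)
  n_cells <- config$n_cells
  cells <- sprintf("cell%03d", seq_len(n_cells))
  bin_w <- bins$end - bins$start
  lambda_copy <- config$reads_per_cell * bin_w / sum(as.numeric(genome)) / 2

  ## ground states: homolog orientation per cell x chromosome
  chroms <- names(genome)
  gs1 <- matrix(runif(n_cells * length(chroms)) < 0.5, n_cells,
                dimnames = list(cells, chroms))
  gs2 <- matrix(runif(n_cells * length(chroms)) < 0.5, n_cells,
                dimnames = list(cells, chroms))

  ## SCE positions: per-bp weights, uniform or hotspot-weighted
  sce_list <- vector("list", n_cells)
  hs <- config$sce_hotspots
  chrom_weight <- as.numeric(genome)
  if (!is.null(hs) && nrow(hs)) {
    extra <- vapply(chroms, function(ch) {
      hh <- hs[hs$chrom == ch, , drop = FALSE]
      sum((hh$end - hh$start) * (hh$rate - 1))
    }, numeric(1))
    chrom_weight <- chrom_weight + extra
  }
  draw_sce_pos <- function(k) {
    ch <- sample(chroms, k, replace = TRUE, prob = chrom_weight)
    pos <- numeric(k)
    for (i in seq_len(k)) {
      L <- genome[[ch[i]]]
      hh <- if (is.null(hs)) NULL else hs[hs$chrom == ch[i], , drop = FALSE]
      if (is.null(hh) || !nrow(hh)) {
        pos[i] <- runif(1, 0, L)
      } else {
        w_hot <- (hh$end - hh$start) * hh$rate
        w_base <- L - sum(hh$end - hh$start)
        j <- sample(length(w_hot) + 1, 1, prob = c(w_base, w_hot))
        if (j == 1) {
          repeat {
            p <- runif(1, 0, L)
            inside <- any(p >= hh$start & p < hh$end)
            if (!inside) break
          }
          pos[i] <- p
        } else {
          pos[i] <- runif(1, hh$start[j - 1], hh$end[j - 1])
        }
      }
    }
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }
  for (ci in seq_len(n_cells)) {
    k <- rpois(1, config$sce_rate)
    if (k > 0) {
      d <- draw_sce_pos(k)
      d$cell <- cells[ci]
      d$homolog <- sample(1:2, k, replace = TRUE)
      sce_list[[ci]] <- d[, c("cell", "chrom", "pos", "homolog")]
    }
  }
  sce_truth <- if (length(sl <- Filter(Negate(is.null), sce_list))) {
    do.call(rbind, sl)
  } else {
    data.frame(cell = character(), chrom = character(),
               pos = numeric(), homolog = integer())
  }

  ## mSV carriers
  ev <- config$msv_events
  carriers <- list()
  if (!is.null(ev) && nrow(ev)) {
    for (e in seq_len(nrow(ev))) {
      k <- round(ev$cell_fraction[e] * n_cells)
      carriers[[e]] <- sort(sample(cells, k))
    }
    names(carriers) <- sprintf("event%d", seq_len(nrow(ev)))
  }

  W <- matrix(0L, n_cells, n_bins, dimnames = list(cells, NULL))
  C <- matrix(0L, n_cells, n_bins, dimnames = list(cells, NULL))
  noise <- config$background_noise

  for (ci in seq_len(n_cells)) {
    muW <- numeric(n_bins); muC <- numeric(n_bins)
    for (ch in chroms) {
      idx <- which(bins$chrom == ch)
      bs <- bins$start[idx]; be <- bins$end[idx]
      sc <- sce_list[[ci]]
      for (h in 1:2) {
        ground_w <- if (h == 1) gs1[ci, ch] else gs2[ci, ch]
        brk <- if (is.null(sc)) numeric(0) else
          sc$pos[sc$chrom == ch & sc$homolog == h]
        fw <- homolog_w_fraction(bs, be, ground_w, brk)
        copies <- rep(1, length(idx))
        cw <- fw; cc <- 1 - fw
        if (!is.null(ev) && nrow(ev)) {
          hap <- paste0("H", h)
          for (e in seq_len(nrow(ev))) {
            if (ev$haplotype[e] != hap || ev$chrom[e] != ch) next
            if (!(cells[ci] %in% carriers[[e]])) next
            if (ev$class[e] == "chrom_loss") {
              cw[] <- 0; cc[] <- 0
              next
            }
            frac <- pmax(0, pmin(be, ev$end[e]) - pmax(bs, ev$start[e])) /
              (be - bs)
            cw2 <- cw; cc2 <- cc
            if (ev$class[e] == "del") {
              cw2 <- cw * (1 - frac); cc2 <- cc * (1 - frac)
            } else if (ev$class[e] == "dup") {
              cw2 <- cw * (1 + frac); cc2 <- cc * (1 + frac)
            } else if (ev$class[e] == "inv") {
              cw2 <- (1 - frac) * cw + frac * cc
              cc2 <- (1 - frac) * cc + frac * cw
            } else if (ev$class[e] == "invdup") {
              cw2 <- cw + frac * cc; cc2 <- cc + frac * cw
            }
            cw <- cw2; cc <- cc2
          }
        }
        muW[idx] <- muW[idx] + lambda_copy[idx] * cw
        muC[idx] <- muC[idx] + lambda_copy[idx] * cc
      }
    }
    ## strand-mapping noise mixes expectations, then Poisson draws
    mW <- (1 - noise) * muW + noise * muC
    mC <- (1 - noise) * muC + noise * muW
    W[ci, ] <- rpois(n_bins, mW)
    C[ci, ] <- rpois(n_bins, mC)
  }

  m <- structure(list(bins = bins, cells = cells, W = W, C = C),
                 class = "StrandCountMatrix")
  truth <- list(sce_positions = sce_truth,
                ground_state_h1 = gs1, ground_state_h2 = gs2,
                msv_events = ev, msv_carriers = carriers)
  list(matrix = m, truth = truth)
}

#' @export
print.StrandCountMatrix <- function(x, ...) {
  cat("StrandCountMatrix:", length(x$cells), "cells x", nrow(x$bins),
      "bins over", length(unique(x$bins$chrom)), "chromosome(s)\n")
  cat("  total reads:", sum(x$W) + sum(x$C), "\n")
  invisible(x)
}
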