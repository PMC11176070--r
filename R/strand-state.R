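## Strand-state segmentation, SCE calling and mSV footprint genotyping.
##
## The observable signal per (cell, chromosome) is the per-bin Watson read
## fraction. With strand-mapping error e, the three distinguishable ground
## states have expected Watson fractions WW: 1-e, WC: 0.5, CC: e (WC and CW
## differ only by haplotype phase, which binned counts do not carry; mixed
## states are reported as "WC").

.state_probs <- function(error_rate) {
  e <- min(max(error_rate, 1e-6), 0.49)
  c(WW = 1 - e, WC = 0.5, CC = e)
}

## Exact maximum-penalized-likelihood segmentation of one (cell, chrom)
## W/C count vector pair by optimal partitioning: maximize the sum of
## per-segment best-state binomial log-likelihoods minus `penalty` per
## segment. Dynamic programming is exact and, unlike greedy binary
## splitting, recovers interior flip-back patterns (state A - state B -
## state A), where no single split improves the likelihood because the
## WC-state likelihood does not depend on the observed Watson fraction.
## Returns the integer vector of segment end indices (bin indices).
.segment_bins <- function(w, n, error_rate, penalty) {
  p <- .state_probs(error_rate)
  logp <- log(p); log1p_ <- log(1 - p)
  cw <- c(0, cumsum(w)); cn <- c(0, cumsum(n))
  nb <- length(w)
  best <- c(0, rep(-Inf, nb))  # best[j + 1]: optimum over bins 1..j
  prev <- integer(nb)
  for (j in seq_len(nb)) {
    i <- seq_len(j)
    sw <- cw[j + 1] - cw[i]
    sn <- cn[j + 1] - cn[i]
    ll <- pmax(sw * logp[1] + (sn - sw) * log1p_[1],
               sw * logp[2] + (sn - sw) * log1p_[2],
               sw * logp[3] + (sn - sw) * log1p_[3])
    cand <- best[i] + ll - penalty
    k <- which.max(cand)
    best[j + 1] <- cand[k]
    prev[j] <- k - 1L
  }
  ends <- integer(0)
  j <- nb
  while (j > 0) {
    ends <- c(j, ends)
    j <- prev[j]
  }
  ends
}

.ml_state <- function(sw, sn, error_rate) {
  p <- .state_probs(error_rate)
  ll <- sw * log(p) + (sn - sw) * log(1 - p)
  names(p)[which.max(ll)]
}

#' Segment per-cell strand states from binned Watson/Crick counts
#'
#' Fits a piecewise-constant strand-state model per (cell, chromosome)
#' under a binomial likelihood of the per-bin Watson fraction, with
#' expected fractions 1-e (WW), 0.5 (WC) and e (CC) for strand-mapping
#' error rate e. Changepoints are found by exact dynamic-programming
#' segmentation (optimal partitioning) with a BIC-style penalty per
#' segment; segments shorter than \code{min_bins} are merged into the
#' likelier neighbor.
#'
#' @param m a \code{StrandCountMatrix}.
#' @param min_bins minimum segment length in bins (shorter segments merged).
#' @param error_rate background probability of a read mapping to the wrong
#'   strand.
#' @param min_reads minimum reads per (cell, chromosome); below this the
#'   chromosome is reported as a single "unknown" segment and excluded from
#'   downstream calling.
#' @return data.frame of segments: cell, chrom, start, end (bp, 0-based
#'   half-open), state (WW/WC/CC/unknown), w_frac, n_bins.
#' @export
call_strand_states <- function(m, min_bins = 3, error_rate = 0.02,
                               min_reads = 20) {
  stopifnot(inherits(m, "StrandCountMatrix"))
  bins <- m$bins
  out <- list()
  for (cell in m$cells) {
    for (ch in unique(bins$chrom)) {
      idx <- which(bins$chrom == ch)
      w <- m$W[cell, idx]; cc <- m$C[cell, idx]
      n <- w + cc
      if (sum(n) < min_reads) {
        out[[length(out) + 1]] <- data.frame(
          cell = cell, chrom = ch, start = bins$start[idx[1]],
          end = bins$end[idx[length(idx)]], state = "unknown",
          w_frac = NA_real_, n_bins = length(idx),
          stringsAsFactors = FALSE)
        next
      }
      penalty <- 2 * log(length(idx))
      ends <- .segment_bins(w, n, error_rate, penalty)
      starts <- c(1, head(ends, -1) + 1)
      ## merge segments shorter than min_bins into the likelier neighbor
      repeat {
        len <- ends - starts + 1
        short <- which(len < min_bins)
        if (!length(short) || length(ends) == 1) break
        s <- short[1]
        if (s == 1) tgt <- 2
        else if (s == length(ends)) tgt <- s - 1
        else {
          fl <- function(a, b) {
            sw <- sum(w[starts[a]:ends[b]]); sn <- sum(n[starts[a]:ends[b]])
            p <- .state_probs(error_rate)
            max(sw * log(p) + (sn - sw) * log(1 - p))
          }
          tgt <- if (fl(s - 1, s) >= fl(s, s + 1)) s - 1 else s + 1
        }
        a <- min(s, tgt); b <- max(s, tgt)
        starts <- starts[-b]; ends <- ends[-a]
      }
      st <- vapply(seq_along(starts), function(i) {
        .ml_state(sum(w[starts[i]:ends[i]]), sum(n[starts[i]:ends[i]]),
                  error_rate)
      }, character(1))
      ## collapse adjacent equal states
      keep <- c(TRUE, st[-1] != st[-length(st)])
      grp <- cumsum(keep)
      starts <- tapply(starts, grp, min); ends <- tapply(ends, grp, max)
      st <- st[keep]
      for (i in seq_along(starts)) {
        sel <- idx[starts[i]:ends[i]]
        out[[length(out) + 1]] <- data.frame(
          cell = cell, chrom = ch, start = bins$start[sel[1]],
          end = bins$end[sel[length(sel)]], state = st[i],
          w_frac = sum(m$W[cell, sel]) /
            max(1, sum(m$W[cell, sel]) + sum(m$C[cell, sel])),
          n_bins = length(sel), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

## single-homolog flip consistency: one homolog changes strand
.single_flip <- function(s1, s2) {
  ok <- list(c("WW", "WC"), c("WC", "WW"), c("WC", "CC"), c("CC", "WC"))
  any(vapply(ok, function(p) s1 == p[1] && s2 == p[2], logical(1)))
}

#' Call sister chromatid exchanges from strand-state segments
#'
#' An SCE is a single strand-state changepoint on a (cell, chromosome)
#' consistent with one homolog flipping strand (WW<->WC or WC<->CC).
#' Chromosomes with two or more changepoints go to a review list, not the
#' callset; single changepoints inconsistent with any one-homolog flip
#' (e.g. WW->CC) are flagged as candidate mSVs. The changepoint confidence
#' interval is the gap between flanking segments, padded by exactly 1 bp on
#' each side.
#'
#' @param segments output of \code{\link{call_strand_states}}.
#' @return list with \code{calls} (data.frame cell, chrom, ci_start, ci_end,
#'   flip), \code{review} (multi-changepoint chromosomes) and
#'   \code{msv_candidates} (inconsistent single changepoints).
#' @export
detect_sces <- function(segments) {
  calls <- list(); review <- list(); cand <- list()
  key <- interaction(segments$cell, segments$chrom, drop = TRUE)
  for (k in levels(key)) {
    seg <- segments[key == k, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    if (any(seg$state == "unknown")) next
    ncp <- nrow(seg) - 1
    if (ncp == 0) next
    if (ncp >= 2) {
      review[[length(review) + 1]] <-
        data.frame(cell = seg$cell[1], chrom = seg$chrom[1],
                   n_changepoints = ncp, stringsAsFactors = FALSE)
      next
    }
    s1 <- seg$state[1]; s2 <- seg$state[2]
    rec <- data.frame(cell = seg$cell[1], chrom = seg$chrom[1],
                      ci_start = seg$end[1] - 1, ci_end = seg$start[2] + 1,
                      flip = paste0(s1, ">", s2), stringsAsFactors = FALSE)
    if (.single_flip(s1, s2)) calls[[length(calls) + 1]] <- rec
    else cand[[length(cand) + 1]] <- rec
  }
  empty <- function(l, cols) {
    if (length(l)) do.call(rbind, l) else
      as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  }
  list(calls = empty(calls, c("cell", "chrom", "ci_start", "ci_end", "flip")),
       review = empty(review, c("cell", "chrom", "n_changepoints")),
       msv_candidates = empty(cand,
                              c("cell", "chrom", "ci_start", "ci_end", "flip")))
}

## expected (W, C) strand copy numbers per hypothesis given ground copies.
## Some footprints coincide without haplotype phase (e.g. on a WC chromosome
## a dup of the C homolog and an invdup of the W homolog are both 1W+2C);
## duplicates collapse onto the earlier entry, so insertion order encodes
## the tie-break: ref, then del < dup < inv < invdup (simpler class wins).
.footprint_hypotheses <- function(gW, gC) {
  hyp <- list(ref = c(gW, gC))
  add <- function(name, w, c) {
    if (w >= 0 && c >= 0) hyp[[name]] <<- c(w, c)
  }
  if (gW >= 1) add("del_W", gW - 1, gC)
  if (gC >= 1) add("del_C", gW, gC - 1)
  if (gW >= 1) add("dup_W", gW + 1, gC)
  if (gC >= 1) add("dup_C", gW, gC + 1)
  if (gW >= 1) add("inv_W", gW - 1, gC + 1)
  if (gC >= 1) add("inv_C", gW + 1, gC - 1)
  if (gW >= 1) add("invdup_W", gW, gC + 1)
  if (gC >= 1) add("invdup_C", gW + 1, gC)
  keys <- vapply(hyp, paste, character(1), collapse = ",")
  hyp[!duplicated(keys)]
}

#' Genotype mSV diagnostic footprints at candidate intervals
#'
#' For each cell and candidate interval, compares the observed Watson/Crick
#' read counts against the expected strand copy numbers of each SV class
#' given the cell's chromosomal ground state (e.g. on a WC chromosome a
#' heterozygous deletion of the Watson homolog leaves 0W+1C; an inversion of
#' it 0W+2C; a duplication 2W+1C), using Poisson likelihoods with per-cell
#' depth estimated from bins outside the interval. The maximum-likelihood
#' class is assigned per cell (ties broken toward the reference class), and
#' carriers aggregated into one call per interval with cell fraction and
#' singleton/subclonal status.
#'
#' @param m a \code{StrandCountMatrix}.
#' @param segments strand-state segments from \code{\link{call_strand_states}}.
#' @param events data.frame(chrom, start, end) of candidate intervals
#'   (0-based half-open). Intervals spanning >= 95\% of their chromosome are
#'   reported as class "chrom_loss" when a deletion footprint is found.
#' @param error_rate strand-mapping error used in expected counts.
#' @return data.frame of \code{MosaicCall}s: event_id, class, chrom, start,
#'   end, haplotype (strand label of the affected homolog, majority vote),
#'   n_carriers, n_cells, cell_fraction, cf_pct, status; per-cell detail in
#'   \code{attr(, "cell_calls")} including class posteriors.
#' @export
genotype_footprints <- function(m, segments, events, error_rate = 0.02) {
  stopifnot(inherits(m, "StrandCountMatrix"),
            all(c("chrom", "start", "end") %in% names(events)))
  bins <- m$bins
  bin_mid <- (bins$start + bins$end) / 2
  calls <- list(); cell_calls <- list()
  for (e in seq_len(nrow(events))) {
    ch <- events$chrom[e]
    if (events$end[e] - events$start[e] <
        min(bins$end[bins$chrom == ch] - bins$start[bins$chrom == ch])) {
      stop("candidate interval shorter than one bin")
    }
    idx_ch <- which(bins$chrom == ch)
    inside <- idx_ch[bin_mid[idx_ch] >= events$start[e] &
                       bin_mid[idx_ch] < events$end[e]]
    outside <- setdiff(idx_ch, inside)
    if (!length(inside)) stop("candidate interval covers no bin")
    chrom_len <- max(bins$end[idx_ch])
    spans_chrom <- (events$end[e] - events$start[e]) >= 0.95 * chrom_len
    per_cell <- list()
    for (cell in m$cells) {
      seg <- segments[segments$cell == cell & segments$chrom == ch, ,
                      drop = FALSE]
      if (!nrow(seg) || all(seg$state == "unknown")) next
      ## ground state from segments outside the interval (bin-weighted)
      segout <- seg[seg$state != "unknown", , drop = FALSE]
      ov <- pmax(0, pmin(segout$end, events$start[e]) - segout$start) +
        pmax(0, segout$end - pmax(segout$start, events$end[e]))
      gstate <- if (any(ov > 0)) {
        segout$state[which.max(ov)]
      } else segout$state[which.max(segout$n_bins)]
      gcopies <- switch(gstate, WW = c(2, 0), WC = c(1, 1), CC = c(0, 2))
      if (length(outside)) {
        lam <- sum(m$W[cell, outside] + m$C[cell, outside]) /
          (2 * length(outside))
      } else {
        lam <- sum(m$W[cell, idx_ch] + m$C[cell, idx_ch]) /
          (2 * length(idx_ch))
      }
      lam <- max(lam, 1e-3)
      obsW <- sum(m$W[cell, inside]); obsC <- sum(m$C[cell, inside])
      nb <- length(inside)
      hyp <- .footprint_hypotheses(gcopies[1], gcopies[2])
      eW <- vapply(hyp, `[`, numeric(1), 1)
      eC <- vapply(hyp, `[`, numeric(1), 2)
      er <- max(error_rate, 1e-4)
      muW <- lam * nb * ((1 - er) * eW + er * eC) + 1e-9
      muC <- lam * nb * ((1 - er) * eC + er * eW) + 1e-9
      ll <- dpois(obsW, muW, log = TRUE) + dpois(obsC, muC, log = TRUE)
      post <- exp(ll - max(ll)); post <- post / sum(post)
      best <- names(hyp)[which.max(ll + c(1e-9, rep(0, length(ll) - 1)))]
      per_cell[[length(per_cell) + 1]] <- data.frame(
        event = e, cell = cell, ground_state = gstate, class_full = best,
        posterior = post[which(names(hyp) == best)],
        post_ref = unname(post["ref"]), stringsAsFactors = FALSE)
    }
    pc <- do.call(rbind, per_cell)
    cell_calls[[e]] <- pc
    n_analyzed <- nrow(pc)
    car <- pc[pc$class_full != "ref", , drop = FALSE]
    if (!nrow(car)) next
    cls <- sub("_[WC]$", "", car$class_full)
    major <- names(sort(table(cls), decreasing = TRUE))[1]
    carriers <- car$cell[cls == major]
    hap <- sub("^.*_", "", car$class_full[cls == major])
    if (spans_chrom && major == "del") major <- "chrom_loss"
    k <- length(carriers)
    calls[[length(calls) + 1]] <- data.frame(
      event_id = sprintf("event%d", e), class = major, chrom = ch,
      start = events$start[e], end = events$end[e],
      haplotype = names(sort(table(hap), decreasing = TRUE))[1],
      n_carriers = k, n_cells = n_analyzed,
      cell_fraction = k / n_analyzed, cf_pct = cf_pct(k, n_analyzed),
      status = if (k == 1) "singleton" else "subclonal",
      stringsAsFactors = FALSE)
    attr(calls[[length(calls)]], "carriers") <- carriers
    calls[[length(calls)]]$carriers <- I(list(carriers))
  }
  res <- if (length(calls)) do.call(rbind, calls) else
    data.frame(event_id = character(0))
  attr(res, "cell_calls") <- do.call(rbind, cell_calls)
  res
}

#' Label calls as singleton or subclonal and report CF
#'
#' Singleton mosaicism is an event detected in exactly one analyzed cell;
#' anything with two or more carriers is a subclone. Cell fractions are
#' reported as percentages with one decimal. Calls without carriers are
#' dropped with a warning.
#'
#' @param calls data.frame with columns n_carriers and n_cells (e.g. from
#'   \code{\link{genotype_footprints}}).
#' @return the calls with status, cell_fraction and cf_pct columns set.
#' @examples
#' classify_singleton_subclonal(data.frame(n_carriers = 19, n_cells = 84))
#' @export
classify_singleton_subclonal <- function(calls) {
  stopifnot(all(c("n_carriers", "n_cells") %in% names(calls)))
  drop <- calls$n_carriers == 0
  if (any(drop)) {
    warning(sum(drop), " call(s) without carriers dropped")
    calls <- calls[!drop, , drop = FALSE]
  }
  calls$cell_fraction <- calls$n_carriers / calls$n_cells
  calls$cf_pct <- cf_pct(calls$n_carriers, calls$n_cells)
  calls$status <- ifelse(calls$n_carriers == 1, "singleton", "subclonal")
  calls
}
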