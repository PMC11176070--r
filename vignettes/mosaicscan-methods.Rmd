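---
title: "mosaicscan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mosaicscan: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the tunable parameters with defaults and
why, what the synthetic-data generator does and does not emulate, and the
design choices made where the design was genuinely open. The companion
`README.md` shows a worked example; `scripts/acceptance.R` recomputes every
headline number from scratch.

## 1. The strand-state model

The substrate is a cells × bins matrix of Watson (W, minus-strand) and
Crick (C, plus-strand) read counts. Each chromosome of each cell inherits
one template strand per homolog, so the per-bin Watson fraction is expected
to be `1 − e` (WW), `0.5` (WC or CW) or `e` (CC), where `e` is the
strand-mapping error rate (default `error_rate = 0.02`). WC and CW differ
only by haplotype phase, which binned counts do not carry; mixed states are
reported as "WC". Per (cell, chromosome) we fit a piecewise-constant state
model under a binomial likelihood of the Watson fraction.

**Segmentation is exact, not greedy.** Changepoints are found by optimal
partitioning (dynamic programming) maximizing the summed per-segment
best-state log-likelihood minus a BIC-style penalty of `2·log(n_bins)` per
segment. Greedy binary splitting was considered and rejected: the WC
state's likelihood equals `n·log 0.5` *independently of the observed
Watson fraction*, so for an interior flip-back pattern (WC → CC → WC —
exactly what two sister chromatid exchanges on the same homolog produce) no
single split improves the likelihood and greedy recursion stops before
finding either changepoint. In simulation this lost roughly a fifth of
isolated interior SCEs; the exact program recovers them at identical cost
at these problem sizes (a few hundred bins per chromosome). Segments
shorter than `min_bins = 3` are merged into the likelier neighbor, a guard
against single-bin artifacts; the penalty already controls false
changepoints statistically, so `min_bins` mostly affects events within
three bins of a chromosome end, which are sacrificed deliberately.

**SCE calling is conservative.** Only chromosomes with exactly one
changepoint, consistent with a single homolog flipping strand
(WW ↔ WC or WC ↔ CC), yield SCE calls. Chromosomes with two or more
changepoints go to a review list; a single WW ↔ CC change cannot be one
SCE and is flagged as a candidate mSV instead. The changepoint confidence
interval is the gap between the flanking segments padded by exactly 1 bp.
When a per-cell SCE *rate* is wanted, the changepoints parked on review
chromosomes are counted too — the conservative callset exists for
positional statistics, not rate estimation.

**Footprint genotyping.** For a candidate interval, each cell's observed
(W, C) counts are scored under Poisson likelihoods against the expected
strand copy numbers of each SV class given the cell's chromosomal ground
state, with per-cell per-copy depth estimated from bins outside the
interval. Without haplotype phase some footprints coincide (on a WC
chromosome, duplication of the C-mapped homolog and inverted duplication of
the W-mapped homolog are both 1W+2C); ambiguous footprints resolve to the
simpler class (ref < del < dup < inv < invdup), and exact likelihood ties
break toward the reference — conservative calling in both senses. Carriers
aggregate into one call per interval with cell fraction
CF = carriers / analyzed cells, reported as a percentage with one decimal;
one carrier is a "singleton", two or more a "subclone". Intervals covering
≥95% of a chromosome with a deletion footprint are relabelled chromosome
loss.

## 2. SCE hotspots and breakpoint overlap

SCE confidence intervals are counted into 500-kb genome bins — each SCE
into exactly one bin, the one holding the majority of its interval, ties to
the lower coordinate. The genome-wide counts are fit by maximum likelihood
to a negative binomial NB(size, mu) (via `fitdistrplus::fitdist`); per-bin
upper-tail p-values `P(X ≥ count)` are BH-corrected, hotspots flagged at
adjusted p < 0.05 (the threshold is exposed because no canonical value
exists). Note a power consequence of the NB's heavy dispersion at these
parameters (size ≈ 1.25, mu ≈ 0.48): a bin whose *expected* rate is a few
times the genome mean still frequently draws small counts, so only intense
hotspots — tens of times the mean rate, which is what empirical SCE
hotspots look like — are reliably detectable.

Breakpoint–hotspot overlap uses a permutation test: breakpoint regions
(reported breakpoints ± 100 kb) are relocated uniformly *within their
chromosome* (length-preserving; chromosome-preserving respects
chromosome-level rate differences, with a cross-chromosome mode behind a
flag), and the one-sided empirical p is `(1 + #{perm ≥ obs})/(n_perm + 1)`
— never zero by construction. The local-shift diagnostic recomputes the
overlap with regions translated ±100 kb … ±10 Mb (averaged over the two
directions, clipped at chromosome ends rather than wrapped, to avoid
artificial overlaps) and expresses each as a Z-score against the
permutation null: genuine co-localization decays with offset.

## 3. Nucleosome-occupancy cell typing

Gene-body MNase fragment counts are normalized per cell to reads per
million, transformed `log2(RPM + 1)` (pseudocount 1), and standardized per
gene. Training normalization parameters (per-gene mean, sd) are frozen
into the classifier and reused verbatim at prediction time; a held-out
cell's own library size therefore cannot move its features (asserted by a
metamorphic test).

Feature selection is two-stage PLS-DA with variance-importance-in-projection
(VIP) scores against permutation nulls: stage 1 fits all classes at once
(components = min(classes − 1, 10)) and keeps genes with VIP above the
90th percentile of a null pooled over label-permuted refits; stage 2
re-fits one-vs-rest per class on the stage-1 genes (2 components) and
keeps VIP above the 95th null percentile, the signature being the union
with class attribution. Pooling the null across genes and permutations is
deliberate: it gives one stable threshold at the stated percentile, and
under pure label permutation the selected fraction calibrates to ~10% and
~5% (both asserted). The number of permutations (default 10–20) moves the
threshold's precision, not its location.

Two practical notes measured on synthetic data. First, selection power
depends on the signature-to-background ratio: the generator's default of
320 signature genes among 8,000 (4%) mirrors a realistic reference
(hundreds of markers among ~19k expressed genes); shrinking the background
makes *relative* VIP thresholds saturate and recovery degrades — visible in
the unit tests, which run tiny matrices. Second, for *per-gene* inference
(differential activity, below) the VIP's cross-gene normalization is
unsuitable as a test statistic: in label permutations where nothing
correlates, whatever correlates slightly earns a large relative VIP, so
each gene's permutation null is coupled to the whole matrix. The
differential-activity test therefore uses the unnormalized component-1
weight — the absolute covariance between the (cell-type-residualized) gene
profile and the genotype indicator — permuted per gene, BH-corrected, with
genes inside a deleted region masked from testing entirely. The p-value
floor is `1/(n_perm + 1)`; with hundreds of genes under BH the default is
`n_perm = 500`, and fewer permutations than `genes/FDR` simply cannot reach
significance.

Classification maps PLS-DA discriminant scores to probabilities by softmax
(temperature 1); ties break by class order with a warning. LOOCV refits
the model for every left-out cell, recomputing normalization on the
training cells only; the signature gene set is held fixed across folds
(full re-selection per fold is disproportionate at these sizes and the
selection is itself permutation-calibrated). Inferred gene activity is the
NO Z-score multiplied by −1: occupancy is inversely related to
accessibility and activity.

## 4. Subclone cell-type enrichment

For a subclone of n cells, each cell type is tested two ways: a one-sided
binomial `P(X ≥ k | n, p0)` against a control composition `p0` (an input
table — e.g. elderly donors without mSVs — defaulting to the population
composition), and an adjusted p from drawing n cells *without replacement*
from the full population 100,000 times (hypergeometric-style, because the
population is finite; the two agree in the small-subclone limit, which is
asserted). BH across cell types, enriched at FDR 10%.

## 5. Haplotype-resolved cis-window testing

To find cis-regulatory effects of a balanced rearrangement, 300-kb windows
sliding by 10 kb cover the region; a window is tested if it holds ≥3
covered CREs (ratio estimates from fewer are unstable). Per cell the
H1/H2 occupancy ratio (RPM-normalized, pseudocount 0.5 per haplotype
against zeros) is summed over the window's CREs and log2-transformed;
mutant vs WT cells are compared by a Gaussian likelihood-ratio test of
equal versus separate means with shared variance (1 df) — the simplest
concrete likelihood for a location shift in a log-ratio. log2FC is
mean(mutant) − mean(WT): with occupancy in the numerator convention, halved
H1 occupancy (doubled accessibility) in carriers gives log2FC ≈ −1.
Multiplicity is handled exactly as a label permutation: genotype labels are
shuffled 1,000 times, each window's adjusted p is the (+1-smoothed)
fraction of permutations with an equal or lower nominal p in that window,
and windows below 0.1 are significant. Significant windows are annotated
with the nearest gene whose body lies within the same TAD (a window
straddling a boundary considers both TADs); TADs without genes leave the
annotation empty.

## 6. CNA re-calling from expression

UMI counts are normalized to `log2(CPM/10 + 1)`. A region is testable only
with ≥5 expressed genes — the rule that excludes short regions regardless
of effect size. The per-cell region score is the mean of per-gene z-scaled
normalized expression minus the cell's grand mean over all genes; the
grand-mean term removes the depth/dropout common factor that otherwise
skews null scores and inflates the mixture test (measured: ~16% of null
regions flagged at nominal 1% FDR without it, 0/25 with it). One- and
two-component Gaussian mixtures are fit by EM (10 random quantile-seeded
restarts, tolerance 1e-6, max 500 iterations, per-iteration log-likelihood
monotonicity asserted). The two components share a variance: a dosage
shift displaces the mean while the score's measurement noise is common to
both clones, and the free-variance 1-D mixture is weakly identified at
moderate separation — both our EM and an independent reference
implementation drift to one-wide/one-narrow solutions that bias the weight
and hence the recovered cell fraction. With the shared variance the model
has 4 parameters against 2, so the chi-squared LRT uses 2 df; bimodality
requires both BH-adjusted LRT q < 0.01 *and* the two-component BIC winning
(the mixture LRT is anticonservative near the boundary, and the double
gate absorbs that). Cells are assigned to the CNA clone (the lower-mean
component for dosage < 1, higher for > 1 — the direction must be declared)
at posterior ≥ 0.8, to the normal clone symmetrically, otherwise
unassigned; cells with zero region coverage are always unassigned and
excluded from the CF denominator. Clone–cell-type association and
clone–clone co-occurrence use Fisher's exact test with BH correction.

## 7. The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the tests run under. Strand counts are generated at *bin*
level: per homolog per bin, copy numbers and strand orientation are
modified by planted events (del −1 copy, dup +1, inv flips the homolog's
strand, invdup adds an inverted copy, chrom_loss removes a homolog), SCE
breakpoints are drawn at bp resolution (uniform or hotspot-weighted) and
recorded exactly, reads are Poisson per strand, and noise reassigns reads
between strands. Read-level artifacts — GC bias, BrdU incorporation
variability, doublets, mappability — are *not* emulated, so passing tests
demonstrate the statistics behave as designed on data that matches the
model's assumptions, not robustness to every library artifact of real
Strand-seq. NO, CRE and expression counts are negative binomial around
lognormal baselines with dispersion `size = 2` (empirical overdispersion is
not published for these assays; 2 is deliberately pessimistic), planted
class/haplotype/dosage effects on the log2 scale, and lognormal per-cell
library factors. Two scaling choices matter and are intentional: the NO
reference simulates 8,000 genes so the signature fraction matches a real
reference (see §3), and expression simulations include a genome-wide
background (≥1,000–2,000 genes) so per-cell libraries reach a few thousand
UMIs — with only a region's genes simulated, `log2(CPM/10+1)` degenerates
into a near-binary zero/high code that no QC-passing cell shows. Every
generator is deterministic given its seed; carrier sets round
`cell_fraction × n_cells`.

## 8. Problem sizes and orchestration

The default test-suite and acceptance runs use 50-Mb chromosomes in small
genomes (2–4 chromosomes), 500-kb or 1-Mb bins, 40–150 cells for strand
analyses (7,200 reads per chromosome, the study's per-cell depth scaled to
a 50-Mb chromosome, where depth matters), a 304-cell/8-class/8,000-gene NO
reference, 500-cell populations for enrichment, 84 cells for the cis scan
(mirroring an inversion subclone of 19 of 84 cells), and 2,000 cells for
CNA re-calling. These sizes keep every property measurable with
comfortable margins while a full run stays in the minutes range on one
CPU.

`run_pipeline()` executes stages in dependency order from a single config
(list or YAML), derives per-stage seeds deterministically from the global
seed so stages can be rerun independently, and writes a manifest with md5
hashes of every artifact. The package's functions and this pipeline
runner are the interface; there is no shell wrapper — users of an analysis
library drive it from R.

## Known limitations

* No haplotype phasing: WC/CW are indistinguishable, haplotype labels on
  footprint calls are strand labels, and dup-vs-invdup ambiguities resolve
  by convention rather than phase.
* Complex rearrangement reconstruction is out of scope; ≥3 co-occurring
  breakpoints in one cell are only flagged.
* The mixture LRT's chi-squared reference is approximate near the
  boundary; the BIC+FDR double gate compensates empirically but the
  nominal p alone should not be interpreted strictly.
* Events shorter than one bin, or within `min_bins` bins of a chromosome
  end, are invisible by construction.
* The NB hotspot model is genome-wide; per-donor stratification is not
  implemented.
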