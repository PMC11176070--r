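#' Cell fraction as a percentage
#'
#' Cell fractions (CF) are reported as percentages with one decimal, the
#' convention used for subclone sizes throughout the package.
#'
#' @param k number of carrier cells.
#' @param n number of analyzed cells.
#' @return numeric percentage rounded to one decimal.
#' @examples
#' cf_pct(1, 43)   # 2.3
#' cf_pct(19, 84)  # 22.6
#' @export
cf_pct <- function(k, n) {
  stopifnot(n > 0, k >= 0, k <= n)
  round(100 * k / n, 1)
}

## empirical one-sided permutation p with +1 smoothing; never 0
perm_pvalue <- function(observed, permuted) {
  (1 + sum(permuted >= observed)) / (length(permuted) + 1)
}

## derive a per-stage 31-bit seed from a global seed and a label
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## set RNG locally if a seed is given
set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
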