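`%||%` <- function(x, y) if (is.null(x)) y else x

## lower median: for even counts return the smaller of the two middle values,
## so delineated boundaries stay at observed coordinates
lower_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

## deterministic per-sample seed derived from a cohort seed (kept < 2^31)
sample_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 7919) %% 2147483647L)
}

stop_domain <- function(...) stop(..., call. = FALSE)
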