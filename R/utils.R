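# internal helpers

# Truncated-normal draws by inverse CDF; lower/upper are hard score bounds.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  x <- stats::qnorm(stats::runif(n, plo, phi), mean, sd)
  pmin(pmax(x, lower), upper)
}

# Round to a fractional grid (e.g. step = 0.25 for threshold scores).
round_to_step <- function(x, step) round(x / step) * step

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

# log-sum-exp over matrix rows
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
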