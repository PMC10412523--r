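# internal helpers: classed conditions, small numerics

cb_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "cb_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_format     <- function(msg) cb_abort(msg, "cb_format_error")
abort_validation <- function(msg) cb_abort(msg, "cb_validation_error")
abort_argument   <- function(msg) cb_abort(msg, "cb_argument_error")
abort_config     <- function(msg) cb_abort(msg, "cb_config_error")
abort_coverage   <- function(msg) cb_abort(msg, "cb_coverage_error")
abort_schedule   <- function(msg) cb_abort(msg, "cb_schedule_error")
abort_estimation <- function(msg) cb_abort(msg, "cb_estimation_error")
abort_generation <- function(msg) cb_abort(msg, "cb_generation_error")

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

vnorm <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort_argument("cannot normalise a zero vector")
  v / n
}

# row-normalise an n x 3 matrix
unit_rows <- function(m) {
  n <- sqrt(rowSums(m * m))
  m / n
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# overlap length of [a1, a2) with [b1, b2), >= 0
interval_overlap <- function(a1, a2, b1, b2) {
  pmax(0, pmin(a2, b2) - pmax(a1, b1))
}

# evaluate `code` under a temporary RNG state seeded with `seed`;
# a NULL seed leaves the RNG stream alone
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

is_strictly_increasing <- function(x) all(diff(x) > 0)

first_violation_index <- function(x) which(diff(x) <= 0)[1] + 1L

# lognormal truncated above at `upper` (inverse-CDF sampling)
rlnorm_trunc <- function(n, meanlog, sdlog, upper) {
  if (sdlog <= 0) return(rep(exp(meanlog), n)) # degenerate law
  p_hi <- plnorm(upper, meanlog, sdlog)
  qlnorm(runif(n, 0, p_hi), meanlog, sdlog)
}

# lognormal truncated to [lower, upper]
rlnorm_trunc2 <- function(n, meanlog, sdlog, lower, upper) {
  p_lo <- plnorm(lower, meanlog, sdlog)
  p_hi <- plnorm(upper, meanlog, sdlog)
  qlnorm(runif(n, p_lo, p_hi), meanlog, sdlog)
}
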