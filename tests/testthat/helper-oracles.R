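# Independent naive oracles used to cross-check package computations.

# Linear-interpolation quantile computed directly from the sorted sample.
naive_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

# Closed-form median of a triangular distribution.
triangular_median <- function(low, mode, high) {
  if (mode >= (low + high) / 2) {
    low + sqrt((high - low) * (mode - low) / 2)
  } else {
    high - sqrt((high - low) * (high - mode) / 2)
  }
}

# Spreadsheet-style forward dosimetry, written independently of the package.
oracle_dose_to_conc <- function(doses, ratios, fue, urine_output) {
  total <- 0
  for (i in seq_along(doses)) total <- total + doses[i] * ratios[i]
  unname(total * fue / urine_output * 1000)
}
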