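# internal helpers shared across modules

# draw from a normal truncated to (lo, hi) by inverse-CDF; vectorised over n
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) {
    return(rep(pmin(pmax(mean, lo), hi), n))
  }
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

# Gaussian spot evaluated at integer sample positions 0..(n-1)
gaussian_spot <- function(n, center, amplitude, sigma) {
  i <- seq_len(n) - 1
  amplitude * exp(-0.5 * ((i - center) / sigma)^2)
}

# index (1-based) of the maximum of `values` restricted to relative band
# [lo, hi] of the vector, or NA if the band maximum is not a local maximum
# (it must exceed the values at the band's outer flanks).
band_local_max <- function(values, lo, hi) {
  n <- length(values)
  pos <- (seq_len(n) - 1) / (n - 1)
  band <- which(pos >= lo & pos <= hi)
  if (length(band) == 0) {
    return(NA_integer_)
  }
  i_max <- band[which.max(values[band])]
  left <- values[pos < lo]
  right <- values[pos > hi]
  flank <- c(
    if (length(left)) max(left[max(1, length(left) - 4):length(left)]),
    if (length(right)) max(right[1:min(5, length(right))])
  )
  if (length(flank) == 0 || values[i_max] > max(flank)) i_max else NA_integer_
}

# mean of the leading / trailing ceil(frac * n) samples
terminal_means <- function(samples, terminal_fraction) {
  n <- length(samples)
  w <- ceiling(terminal_fraction * n)
  c(lead = mean(samples[seq_len(w)]), trail = mean(samples[seq(n - w + 1, n)]))
}

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, lo, hi),
          class = "polegrow_config_error")
  }
  invisible(x)
}
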