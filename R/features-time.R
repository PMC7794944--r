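#' Time-domain features (19)
#'
#' Amplitude statistics and waveform-shape factors of the raw samples.
#' Conventions: skewness and kurtosis are the moment estimators (kurtosis
#' non-excess, so a Gaussian scores 3); the crest, shape, impulse and margin
#' factors use the signed maximum while peak-to-RMS uses the absolute
#' maximum; Shannon energy is \eqn{-\sum x^2 \ln x^2} with zero terms
#' skipped (positive when |x| < 1); log energy is \eqn{\sum \ln x^2} with
#' |x| clamped at 1e-12; average frequency is the zero-crossing count per
#' sample interval; jitter is the mean absolute successive difference of
#' inter-peak intervals in milliseconds (peaks: local maxima at least 0.4 s
#' apart with prominence >= 0.3 sd).
#'
#' Degenerate inputs (constant signal, fewer than 3 detected peaks) yield
#' sentinel 0 for the undefined entries, with a warning.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz (for the jitter peak spacing).
#' @return named numeric vector of length 19.
#' @export
time_domain_features <- function(x, fs = 1000) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  mu <- mean(x)
  sdev <- stats::sd(x)
  m2 <- mean((x - mu)^2)
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else NA_real_
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else NA_real_
  rms <- sqrt(mean(x^2))
  mabs <- mean(abs(x))
  xmax <- max(x)
  x2 <- x^2
  shannon <- -sum(x2[x2 > 0] * log(x2[x2 > 0]))
  logen <- sum(log(pmax(x2, 1e-24)))

  peaks <- find_peaks(x, min_dist = round(0.4 * fs),
                      min_prominence = 0.3 * sdev)
  jitter_ms <- if (length(peaks) >= 3) {
    ipi <- diff(peaks) / fs * 1000
    mean(abs(diff(ipi)))
  } else NA_real_

  v <- c(
    "Mean" = mu,
    "Standard Deviation" = sdev,
    "Skewness" = skew,
    "Kurtosis" = kurt,
    "Peak to Peak Value" = xmax - min(x),
    "Root Mean Square" = rms,
    "Crest Factor" = xmax / rms,
    "Shape Factor" = rms / mabs,
    "Impulse Factor" = xmax / mabs,
    "Margin Factor" = xmax / mean(sqrt(abs(x)))^2,
    "Energy" = sum(x2),
    "Peak to RMS Value" = max(abs(x)) / rms,
    "Root Sum of Squares" = sqrt(sum(x2)),
    "Shannon Energy" = shannon,
    "Log Energy" = logen,
    "Mean Absolute Deviation" = mean(abs(x - mu)),
    "Median Absolute Deviation" = stats::median(abs(x - stats::median(x))),
    "Average Frequency" = zero_crossings(x) / (n - 1),
    "Jitter" = jitter_ms
  )
  sanitize_features(v, "time_domain_features")
}

# Local maxima filtered by prominence, then greedy minimum-distance pruning
# (highest peaks kept first).
find_peaks <- function(x, min_dist = 1L, min_prominence = 0) {
  n <- length(x)
  cand <- local_extrema(x)$max
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    left <- x[seq_len(i - 1)]
    right <- x[seq(i + 1, n)]
    higher_l <- which(left > x[i])
    higher_r <- which(right > x[i])
    base_l <- min(x[seq(if (length(higher_l)) max(higher_l) else 1, i)])
    base_r <- min(x[seq(i, i + (if (length(higher_r)) min(higher_r) else n - i))])
    x[i] - max(base_l, base_r)
  }, numeric(1))
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer(0))
  keep <- logical(length(cand))
  for (j in order(x[cand], decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[j]) < min_dist)) keep[j] <- TRUE
  }
  sort(cand[keep])
}
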