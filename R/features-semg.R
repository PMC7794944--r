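#' sEMG-style amplitude and slope features (13)
#'
#' The standard surface-EMG time-domain descriptor set applied to the pulse
#' waveform. Enhanced mean absolute value (EMAV) and enhanced wavelength
#' (EWL) use exponent p = 0.75 inside the central 60% of the record and
#' p = 0.5 outside; EMAV averages |x|^p while EWL sums |dx|^p. WL is the
#' cumulative waveform length, SSC the count of slope sign changes whose
#' surrounding difference product exceeds `thresh`, AAC = WL/(N-1), DASDV
#' the RMS of the first difference, log detector exp(mean ln |x|), MMAV and
#' MMAV2 the trapezoid-weighted mean absolute values, pulse percentage rate
#' the fraction of |x| > `thresh`, SSI the energy, WAMP the count of
#' |dx| > `thresh`, and MFL = ln sqrt(sum dx^2).
#'
#' @param x numeric signal.
#' @param thresh amplitude/slope threshold shared by SSC, PPR and WAMP.
#' @return named numeric vector of length 13.
#' @export
semg_features <- function(x, thresh = 0.01) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  i <- seq_len(n)
  p_exp <- ifelse(i >= 0.2 * n & i <= 0.8 * n, 0.75, 0.5)
  dx <- diff(x)
  d2x <- diff(x, differences = 2)
  emav <- mean(abs(x)^p_exp)
  ewl <- sum(abs(dx)^p_exp[-1])
  wl <- sum(abs(dx))
  ssc <- sum((x[2:(n - 1)] - x[1:(n - 2)]) * (x[2:(n - 1)] - x[3:n]) >= thresh)
  w_mmav <- ifelse(i >= 0.25 * n & i <= 0.75 * n, 1, 0.5)
  w_mmav2 <- ifelse(i < 0.25 * n, 4 * i / n,
                    ifelse(i > 0.75 * n, 4 * (n - i) / n, 1))
  v <- c(
    "Enhanced Mean Absolute Value" = emav,
    "Enhanced Wavelength" = ewl,
    "Wavelength" = wl,
    "Slope Sign Change" = ssc,
    "Average Amplitude Change" = wl / (n - 1),
    "Difference Absolute Std. Dev." = sqrt(sum(dx^2) / (n - 1)),
    "Log Detector" = exp(mean(log(pmax(abs(x), 1e-12)))),
    "Modified Mean Absolute Value" = mean(w_mmav * abs(x)),
    "Modified Mean Absolute Value 2" = mean(w_mmav2 * abs(x)),
    "Pulse Percentage Rate" = mean(abs(x) > thresh),
    "Simple Square Integral" = sum(x^2),
    "Willison Amplitude" = sum(abs(dx) > thresh),
    "Maximum Fractal Length" = log(sqrt(sum(dx^2)))
  )
  sanitize_features(v, "semg_features")
}

#' Root-squared moment descriptors (6)
#'
#' Temporal-descriptor family built from the root-squared moments of the
#' signal and its differences: m0 = sqrt(sum x^2), m2 = sqrt(sum dx^2),
#' m4 = sqrt(sum d2x^2). The three moments are reported on the log scale;
#' sparseness is ln(m0 / sqrt((m0-m2)(m0-m4))), the irregularity factor
#' ln(m2 / sqrt(m0 m4)), and the waveform-length ratio
#' ln(sum |dx| / sum |d2x|). Degenerate inputs (constant or linear ramps,
#' where a moment or a log argument collapses) yield sentinel 0 with a
#' warning.
#'
#' @param x numeric signal.
#' @return named numeric vector of length 6.
#' @export
moment_features <- function(x) {
  n <- length(x)
  if (n < 5) stop("need at least 5 samples", call. = FALSE)
  dx <- diff(x)
  d2x <- diff(x, differences = 2)
  m0 <- sqrt(sum(x^2))
  m2 <- sqrt(sum(dx^2))
  m4 <- sqrt(sum(d2x^2))
  safe_log <- function(a) if (is.finite(a) && a > 0) log(a) else NA_real_
  v <- c(
    "Root Squared Zero Order Moment" = safe_log(m0),
    "Root Squared 2nd Order Moment" = safe_log(m2),
    "Root Squared 4th Order Moment" = safe_log(m4),
    "Sparseness" = safe_log(m0 / sqrt((m0 - m2) * (m0 - m4))),
    "Irregularity Factor" = safe_log(m2 / sqrt(m0 * m4)),
    "Waveform Length Ratio" = safe_log(sum(abs(dx)) / sum(abs(d2x)))
  )
  sanitize_features(v, "moment_features")
}

#' Hjorth descriptors: complexity and mobility (2)
#'
#' Mobility = sqrt(var(dx)/var(x)); complexity = mobility(dx)/mobility(x).
#' For a pure sinusoid of angular frequency w sampled at interval dt,
#' mobility approaches w*dt and complexity approaches 1; broadband noise
#' scores higher on both.
#'
#' @param x numeric signal.
#' @return named numeric vector `c("Complexity", "Mobility")` (registry
#'   order).
#' @export
hjorth_features <- function(x) {
  if (stats::var(x) == 0)
    stop("constant signal: Hjorth descriptors undefined", call. = FALSE)
  mob <- function(v) sqrt(stats::var(diff(v)) / stats::var(v))
  m <- mob(x)
  v <- c("Complexity" = mob(diff(x)) / m, "Mobility" = m)
  sanitize_features(v, "hjorth_features")
}
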