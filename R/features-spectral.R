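#' Spectral features (17)
#'
#' Descriptors of the one-sided FFT magnitude spectrum, DC bin excluded.
#' The distributional statistics (spectral mean/std/skewness/kurtosis) are
#' moments of the magnitude values themselves; centroid and spread are
#' frequency moments with power (magnitude squared) weights, as are mean
#' frequency (power-weighted mean) and median frequency (50% cumulative
#' power). Roll-off is the frequency below which `rolloff` (default 95%) of
#' the spectral energy lies. Flatness is the geometric-to-arithmetic mean
#' ratio of the power spectrum, crest the peak-to-total power ratio, and
#' flux the mean L2 change between unit-normalised magnitude spectra of
#' successive 1 s frames hopped by 0.5 s. SFDR, SINAD and THD (in dB, 5
#' harmonics) treat the largest nonzero-frequency peak as the fundamental.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param rolloff energy fraction for the roll-off point.
#' @param n_harmonics harmonics counted by THD.
#' @return named numeric vector of length 17.
#' @export
spectral_features <- function(x, fs, rolloff = 0.95, n_harmonics = 5L) {
  n <- length(x)
  if (n < 64) stop("need at least 64 samples", call. = FALSE)
  sp <- one_sided_spectrum(x, fs)
  f <- sp$freq[-1]
  m <- sp$mag[-1]
  p <- m^2
  ptot <- sum(p)
  if (ptot <= 0) stop("all-zero signal: spectrum undefined", call. = FALSE)

  mm <- mean(m); ms <- stats::sd(m)
  mom2 <- mean((m - mm)^2)
  centroid <- sum(f * p) / ptot
  spread <- sqrt(sum((f - centroid)^2 * p) / ptot)
  cum <- cumsum(p)
  roll <- f[which(cum >= rolloff * ptot)[1]]
  medf <- f[which(cum >= 0.5 * ptot)[1]]
  flat <- exp(mean(log(pmax(p, 1e-300)))) / mean(p)
  crest <- max(p) / ptot
  kk <- seq_along(m)
  decrease <- sum((m[-1] - m[1]) / (kk[-1] - 1)) / sum(m[-1])
  mn <- m / sum(m)
  slope <- stats::cov(f, mn) / stats::var(f)

  # harmonic analysis around the dominant peak
  i0 <- which.max(m)
  f0 <- f[i0]
  win <- 1L # +/- bins pooled around each line
  pool <- function(i) sum(p[pmax(1, i - win):pmin(length(p), i + win)])
  p_fund <- pool(i0)
  p_harm <- 0
  for (h in 2:(n_harmonics + 1L)) {
    fh <- h * f0
    if (fh > max(f)) break
    ih <- which.min(abs(f - fh))
    p_harm <- p_harm + pool(ih)
  }
  excl <- unlist(lapply(0:(n_harmonics + 1L), function(h) {
    ih <- if (h == 0) i0 else which.min(abs(f - h * f0))
    (ih - win):(ih + win)
  }))
  excl <- unique(pmax(1, pmin(length(p), excl)))
  spur <- if (length(p) > length(excl)) max(p[-excl]) else NA_real_
  noise_dist <- ptot - p_fund
  v <- c(
    "Spectral Mean" = mm,
    "Spectral Standard Deviation" = ms,
    "Spectral Skewness" = if (mom2 > 0) mean((m - mm)^3) / mom2^1.5 else NA_real_,
    "Spectral Kurtosis" = if (mom2 > 0) mean((m - mm)^4) / mom2^2 else NA_real_,
    "Spectral Centroid" = centroid,
    "Spectral Flux" = spectral_flux(x, fs),
    "Spectral Roll-off" = roll,
    "Spectral Flatness" = flat,
    "Spectral Crest" = crest,
    "Spectral Decrease" = decrease,
    "Spectral Slope" = slope,
    "Spectral Spread" = spread,
    "Mean Frequency" = centroid,
    "Median Frequency" = medf,
    "Spurious-free Dynamic Range" = 10 * log10(p_fund / spur),
    "Signal to Noise Distortion" = 10 * log10(p_fund / max(noise_dist, 1e-300)),
    "Total Harmonic Distortions" = 10 * log10(max(p_harm, 1e-300) / p_fund)
  )
  sanitize_features(v, "spectral_features")
}

# Mean L2 frame-to-frame change of unit-normalised magnitude spectra;
# 1 s frames, 0.5 s hop.
spectral_flux <- function(x, fs) {
  frame <- min(length(x), round(fs))
  hop <- max(1L, round(fs / 2))
  starts <- seq(1L, length(x) - frame + 1L, by = hop)
  if (length(starts) < 2) return(0)
  specs <- vapply(starts, function(s) {
    m <- Mod(stats::fft(x[s:(s + frame - 1L)]))[seq_len(floor(frame / 2) + 1L)]
    tot <- sqrt(sum(m^2))
    if (tot > 0) m / tot else m
  }, numeric(floor(frame / 2) + 1L))
  mean(sqrt(colSums((specs[, -1, drop = FALSE] -
                       specs[, -ncol(specs), drop = FALSE])^2)))
}
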