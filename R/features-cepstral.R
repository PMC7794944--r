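# Framed power spectra: Hann-windowed frames (frame samples, hop samples),
# one-sided power spectrum per frame as columns.
framed_power_spectra <- function(x, frame = 1024L, hop = 512L) {
  n <- length(x)
  if (n < frame) stop("signal shorter than one frame", call. = FALSE)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, frame - 1) / (frame - 1))
  starts <- seq(1L, n - frame + 1L, by = hop)
  nb <- floor(frame / 2) + 1L
  mat <- vapply(starts, function(s) {
    Mod(stats::fft(x[s:(s + frame - 1L)] * w))[seq_len(nb)]^2
  }, numeric(nb))
  list(power = mat)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank: n_filters x n_bins weights.
mel_filterbank <- function(n_filters, n_bins, fs, frame) {
  f_bins <- (seq_len(n_bins) - 1L) * fs / frame
  edges <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(fs / 2),
                         length.out = n_filters + 2L))
  fb <- matrix(0, n_filters, n_bins)
  for (i in seq_len(n_filters)) {
    lo <- edges[i]; cen <- edges[i + 1]; hi <- edges[i + 2]
    up <- (f_bins - lo) / (cen - lo)
    dn <- (hi - f_bins) / (hi - cen)
    fb[i, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

hz_to_erb <- function(f) 21.4 * log10(1 + 0.00437 * f)
erb_to_hz <- function(e) (10^(e / 21.4) - 1) / 0.00437

# 4th-order gammatone magnitude-squared responses sampled on the FFT grid.
gammatone_filterbank <- function(n_filters, n_bins, fs, frame, f_lo = 10) {
  f_bins <- (seq_len(n_bins) - 1L) * fs / frame
  fc <- erb_to_hz(seq(hz_to_erb(f_lo), hz_to_erb(fs / 2),
                      length.out = n_filters))
  fb <- matrix(0, n_filters, n_bins)
  for (i in seq_len(n_filters)) {
    b <- 1.019 * 24.7 * (4.37 * fc[i] / 1000 + 1)
    fb[i, ] <- (1 + ((f_bins - fc[i]) / b)^2)^(-4) # |H|^2 of a 4th-order filter
  }
  fb
}

# Orthonormal DCT-II matrix rows 1..n_out applied to a vector.
dct_ii <- function(v, n_out) {
  n <- length(v)
  k <- seq_len(n) - 1L
  out <- vapply(seq_len(n_out) - 1L, function(j) {
    a <- if (j == 0) sqrt(1 / n) else sqrt(2 / n)
    a * sum(v * cos(pi * (k + 0.5) * j / n))
  }, numeric(1))
  out
}

#' Cepstral features: MFCC and GFCC coefficients 1-4 (8 values)
#'
#' Frames of 1024 samples with hop 512 and a Hann window. MFCC: 20-filter
#' triangular mel bank spanning 0 to fs/2, log filter energies, orthonormal
#' DCT-II, coefficients 0-3 averaged over frames. GFCC: 20-channel
#' gammatone bank (ERB-spaced centres from 10 Hz to fs/2, 4th-order
#' magnitude responses applied in the frequency domain), cube-root
#' compression, DCT-II, coefficients 0-3 averaged over frames.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param frame,hop framing parameters in samples.
#' @param n_filters filterbank size.
#' @return named numeric vector of length 8.
#' @export
cepstral_features <- function(x, fs, frame = 1024L, hop = 512L,
                              n_filters = 20L) {
  ps <- framed_power_spectra(x, frame, hop)$power
  nb <- nrow(ps)
  mel <- mel_filterbank(n_filters, nb, fs, frame)
  gt <- gammatone_filterbank(n_filters, nb, fs, frame)
  mfcc <- rowMeans(apply(ps, 2, function(p) {
    dct_ii(log(pmax(mel %*% p, 1e-300)), 4L)
  }))
  gfcc <- rowMeans(apply(ps, 2, function(p) {
    dct_ii((pmax(gt %*% p, 0))^(1 / 3), 4L)
  }))
  v <- c(mfcc, gfcc)
  names(v) <- c(paste(ordinal(1:4), "Coefficient of MFCC"),
                paste(ordinal(1:4), "Coefficient of GFCC"))
  sanitize_features(v, "cepstral_features")
}

#' Chroma features (12)
#'
#' Short-time magnitude spectra (same framing as [cepstral_features()])
#' mapped to 12 pitch classes with A440 as the reference for class 1; bin
#' magnitudes accumulate per class within a frame and are averaged over
#' frames. The vector is unnormalised. For a pure 440 Hz tone the first
#' class dominates; transposing by one equal-tempered semitone rotates the
#' dominant class by one position.
#'
#' @inheritParams cepstral_features
#' @return named numeric vector of length 12.
#' @export
chroma_features <- function(x, fs, frame = 1024L, hop = 512L) {
  ps <- framed_power_spectra(x, frame, hop)$power
  mag <- sqrt(ps)
  f_bins <- (seq_len(nrow(mag)) - 1L) * fs / frame
  usable <- f_bins > 0
  cls <- (round(12 * log2(f_bins[usable] / 440)) %% 12) + 1L
  acc <- vapply(seq_len(ncol(mag)), function(j) {
    as.numeric(tapply(mag[usable, j], factor(cls, levels = 1:12), sum,
                      default = 0))
  }, numeric(12))
  v <- rowMeans(acc)
  names(v) <- paste(ordinal(1:12), "Coefficient of Chroma Vector")
  sanitize_features(v, "chroma_features")
}
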