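# Small deterministic signal builders shared across tests.

tone <- function(freq, fs = 1000, dur = 1, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (seq_len(round(dur * fs)) - 1) / fs + phase)
}

# A clean quasi-pulse: 1.2 Hz train of Gaussian bumps (no noise).
clean_pulse <- function(fs = 1000, dur = 10, f0 = 1.2) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  onsets <- seq(0, dur + 1, by = 1 / f0)
  rowSums(vapply(onsets, function(o) exp(-(t - o)^2 / (2 * 0.04^2)),
                 numeric(length(t))))
}

# dB power ratio of the FFT bin nearest `freq` between two signals.
bin_power_db <- function(x, fs, freq) {
  n <- length(x)
  m <- Mod(stats::fft(x))[seq_len(floor(n / 2) + 1)]
  f <- (seq_along(m) - 1) * fs / n
  i <- which.min(abs(f - freq))
  10 * log10(sum(m[max(1, i - 1):min(length(m), i + 1)]^2))
}

two_blobs <- function(n = 50, d = 3, sep = 8, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n * d), n, d),
             matrix(stats::rnorm(n * d, mean = sep), n, d))
  list(x = x, y = factor(rep(c("normal", "hypertension"), each = n),
                         levels = c("normal", "hypertension")))
}
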