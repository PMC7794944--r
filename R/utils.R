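#' @keywords internal
"_PACKAGE"

# One-sided magnitude spectrum, DC bin included (bin k maps to (k-1)*fs/N Hz).
one_sided_spectrum <- function(x, fs) {
  n <- length(x)
  k <- seq_len(floor(n / 2) + 1L)
  list(
    freq = (k - 1L) * fs / n,
    mag  = Mod(stats::fft(x))[k] / n
  )
}

# Power-spectrum centroid (Hz) of a component; 0 for an all-zero component.
spectral_centroid_hz <- function(x, fs) {
  sp <- one_sided_spectrum(x, fs)
  p <- sp$mag^2
  p[1] <- 0 # ignore DC when locating oscillatory content
  tot <- sum(p)
  if (tot <= 0) return(0)
  sum(sp$freq * p) / tot
}

# Replace non-finite feature values by 0, warning once per offender set.
sanitize_features <- function(v, context = "features") {
  bad <- !is.finite(v)
  if (any(bad)) {
    warning(sprintf("%s: %d non-finite value(s) replaced by sentinel 0 (%s)",
                    context, sum(bad), paste(names(v)[bad], collapse = ", ")),
            call. = FALSE)
    v[bad] <- 0
  }
  v
}

# Derive a per-item 32-bit seed from a run seed and integer keys.
derive_seed <- function(seed, ...) {
  keys <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in keys) s <- (s * 48271 + as.double(k)) %% 2147483647
  as.integer(s)
}

# Ordinal label: 1 -> "1st", 2 -> "2nd", 11 -> "11th", ...
ordinal <- function(i) {
  suffix <- ifelse(i %% 100 %in% 11:13, "th",
                   c("st", "nd", "rd", rep("th", 7))[pmin(i %% 10 + (i %% 10 == 0) * 10, 10)])
  paste0(i, suffix)
}

# Strict interior local maxima/minima indices (plateaus collapse to one point).
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  # collapse exact plateaus so diff signs are well defined
  d <- diff(x)
  s <- sign(d)
  # propagate last nonzero slope through flats
  nz <- s != 0
  if (!any(nz)) return(list(max = integer(0), min = integer(0)))
  s_filled <- s
  idx <- which(nz)
  s_filled <- s[cummax(ifelse(nz, seq_along(s), 0L))]
  s_filled[seq_len(idx[1] - 1)] <- s[idx[1]]
  ds <- diff(s_filled)
  list(max = which(ds < 0) + 1L, min = which(ds > 0) + 1L)
}

zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}
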