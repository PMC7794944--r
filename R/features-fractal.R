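#' Higuchi fractal dimension
#'
#' Classic curve-length estimator: mean normalised length L(k) over lag
#' k = 1..kmax, FD = -slope of log L(k) vs log k. A straight line scores 1,
#' white noise approaches 2.
#'
#' @param x numeric signal.
#' @param kmax largest lag.
#' @return scalar fractal dimension.
#' @export
higuchi_fd <- function(x, kmax = 10L) {
  n <- length(x)
  lk <- vapply(seq_len(kmax), function(k) {
    lm_ <- vapply(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2) return(NA_real_)
      (sum(abs(diff(x[idx]))) * (n - 1) / (k * (length(idx) - 1))) / k
    }, numeric(1))
    mean(lm_, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(lk) & lk > 0
  if (sum(ok) < 2) return(1)
  -stats::coef(stats::lm(log(lk[ok]) ~ log(seq_len(kmax)[ok])))[[2]]
}

#' Katz fractal dimension
#'
#' Treats the series as a planar curve with unit abscissa steps:
#' FD = log10(n) / (log10(n) + log10(d/L)) with L the total curve length
#' and d the maximal distance from the first point.
#'
#' @param x numeric signal.
#' @return scalar fractal dimension.
#' @export
katz_fd <- function(x) {
  n <- length(x) - 1L
  steps <- sqrt(1 + diff(x)^2)
  L <- sum(steps)
  d <- max(sqrt((seq_along(x) - 1)^2 + (x - x[1])^2))
  log10(n) / (log10(n) + log10(d / L))
}

#' Approximate entropy
#'
#' ApEn(m, r): regularity statistic comparing matching frequencies of
#' embedded templates of length m and m+1 under the Chebyshev distance with
#' tolerance r (default 0.2 sd). Periodic signals score near 0.
#'
#' @param x numeric signal.
#' @param m template length.
#' @param r tolerance (absolute units; default `0.2 * sd(x)`).
#' @return scalar entropy (nats).
#' @export
approx_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  phi <- function(mm) {
    nv <- n - mm + 1L
    emb <- stats::embed(x, mm) # rows are reversed templates; distance unaffected
    cnt <- rep(0L, nv)
    maxd <- matrix(0, nv, nv)
    for (j in seq_len(mm)) {
      dj <- abs(outer(emb[, j], emb[, j], "-"))
      maxd <- pmax(maxd, dj)
    }
    mean(log(rowMeans(maxd <= r)))
  }
  phi(m) - phi(m + 1L)
}

# Delay from the first zero crossing of the autocorrelation.
acf_zero_delay <- function(x, max_lag = min(length(x) - 2L, 500L)) {
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  z <- which(a <= 0)[1]
  if (is.na(z)) max(1L, round(max_lag / 4)) else z
}

time_delay_embed <- function(x, m, tau) {
  n <- length(x) - (m - 1L) * tau
  if (n < 2) stop("series too short for embedding", call. = FALSE)
  sapply(seq_len(m), function(j) x[seq_len(n) + (j - 1L) * tau])
}

# Delay for embedding: autocorrelation zero crossing, capped so at least
# half the series survives the embedding.
embed_delay <- function(x, m) {
  max(1L, min(acf_zero_delay(x), floor(length(x) / (2L * (m - 1L))) - 1L))
}

#' Largest Lyapunov exponent (Rosenstein estimator)
#'
#' Time-delay embedding (dimension `m`, delay from the first
#' autocorrelation zero crossing), nearest neighbour outside a Theiler
#' window, then the least-squares slope of the mean log-divergence curve
#' over 0 to `horizon_s` seconds, reported per second.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param m embedding dimension.
#' @param horizon_s divergence-fit horizon in seconds.
#' @return scalar exponent (1/s).
#' @export
lyapunov_rosenstein <- function(x, fs, m = 5L, horizon_s = 1) {
  tau <- embed_delay(x, m)
  emb <- time_delay_embed(x, m, tau)
  n <- nrow(emb)
  d2 <- as.matrix(stats::dist(emb))
  theiler <- max(tau, 10L)
  idx <- seq_len(n)
  for (i in idx) d2[i, abs(idx - i) <= theiler] <- Inf
  nn <- apply(d2, 1, which.min)
  horizon <- min(round(horizon_s * fs), n - 1L)
  steps <- seq_len(horizon)
  mean_logd <- vapply(steps, function(k) {
    valid <- which(idx + k <= n & nn + k <= n)
    if (length(valid) < 2) return(NA_real_)
    dd <- sqrt(rowSums((emb[valid + k, , drop = FALSE] -
                          emb[nn[valid] + k, , drop = FALSE])^2))
    mean(log(pmax(dd, 1e-300)))
  }, numeric(1))
  ok <- is.finite(mean_logd)
  if (sum(ok) < 2) return(0)
  stats::coef(stats::lm(mean_logd[ok] ~ I(steps[ok] / fs)))[[2]]
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Embedding dimension `m`, delay from the autocorrelation zero crossing.
#' The correlation sum C(r) is evaluated on a log-spaced radius grid and
#' the dimension is the least-squares slope of log C vs log r over the
#' middle decade of the distance distribution.
#'
#' @param x numeric signal.
#' @param m embedding dimension.
#' @return scalar dimension estimate.
#' @export
correlation_dimension <- function(x, m = 5L) {
  tau <- embed_delay(x, m)
  emb <- time_delay_embed(x, m, tau)
  d <- stats::dist(emb)
  d <- d[d > 0]
  if (!length(d)) return(0)
  lo <- stats::quantile(d, 0.05)
  hi <- stats::quantile(d, 0.95)
  centre <- sqrt(lo * hi)
  rs <- exp(seq(log(max(centre / sqrt(10), min(d))),
                log(min(centre * sqrt(10), hi)), length.out = 12))
  cr <- vapply(rs, function(r) mean(d <= r), numeric(1))
  ok <- cr > 0
  if (sum(ok) < 2) return(0)
  stats::coef(stats::lm(log(cr[ok]) ~ log(rs[ok])))[[2]]
}

#' Fractal and chaos features (5)
#'
#' Higuchi (kmax = 10) and Katz fractal dimensions are computed on the
#' full-resolution signal; the largest Lyapunov exponent (Rosenstein,
#' m = 5), approximate entropy (m = 2, r = 0.2 sd) and the
#' Grassberger-Procaccia correlation dimension (m = 5) are computed after
#' decimation to `chaos_fs` Hz (pulse content lives far below the raw
#' 1 kHz rate, and the embedding statistics are quadratic in length).
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param kmax Higuchi lag bound.
#' @param chaos_fs target rate for the embedding-based estimators.
#' @return named numeric vector of length 5.
#' @export
fractal_features <- function(x, fs, kmax = 10L, chaos_fs = 125) {
  if (length(x) < 100) stop("need at least 100 samples", call. = FALSE)
  q <- max(1L, round(fs / chaos_fs))
  if (q > 1L) { # 8th-order Butterworth anti-alias, then subsample
    bf <- signal::butter(8, 0.8 / q, type = "low")
    xf <- as.numeric(signal::filtfilt(bf, x))
    xd <- xf[seq(1L, length(x), by = q)]
  } else xd <- x
  fsd <- fs / q
  guarded <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  v <- c(
    "Higuchi's Fractal Dimension" = guarded(higuchi_fd(x, kmax)),
    "Katz Fractal Dimension" = guarded(katz_fd(x)),
    "Lyapunov Exponent" = guarded(lyapunov_rosenstein(xd, fsd)),
    "Approximate Entropy" = guarded(approx_entropy(xd)),
    "Correlation Dimension" = guarded(correlation_dimension(xd))
  )
  sanitize_features(v, "fractal_features")
}
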