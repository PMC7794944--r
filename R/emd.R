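#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by sifting:
#' repeatedly subtracting the mean of the upper and lower cubic-spline
#' envelopes until the candidate satisfies the IMF conditions (number of
#' extrema and zero crossings equal or differing by at most one, and
#' near-zero envelope mean). Sifting for one IMF stops when the normalised
#' standard-deviation criterion
#' \eqn{SD = \sum (h_{k-1}-h_k)^2 / \sum h_{k-1}^2} drops below
#' `sd_threshold` or `max_sift` iterations are reached; extraction stops when
#' the residual has fewer than 3 extrema or `max_imfs` IMFs were produced.
#' Envelope splines use mirrored boundary extrema to tame end effects.
#'
#' The decomposition is exactly additive: `Reduce("+", imfs) + residual`
#' reproduces the input to machine precision, because every IMF is obtained
#' by subtraction.
#'
#' @param x numeric signal (or a `pupg` object).
#' @param fs sampling rate in Hz (taken from `x` if it is a `pupg` object).
#' @param max_imfs maximum number of IMFs.
#' @param sd_threshold sifting stop criterion (canonical 0.2).
#' @param max_sift maximum sifting iterations per IMF.
#' @return an `imf_set`: list with `imfs` (list, IMF1 = highest frequency),
#'   `residual`, `fs`.
#' @export
emd_decompose <- function(x, fs = NULL, max_imfs = 10L, sd_threshold = 0.2,
                          max_sift = 10L) {
  if (inherits(x, "pupg")) { fs <- x$fs; x <- x$samples }
  if (is.null(fs)) stop("fs required", call. = FALSE)
  if (length(x) < 10) stop("signal too short for EMD", call. = FALSE)
  if (!all(is.finite(x))) stop("signal must be finite", call. = FALSE)

  imfs <- list()
  residual <- x
  while (length(imfs) < max_imfs) {
    ext <- local_extrema(residual)
    if (length(ext$max) + length(ext$min) < 3) break
    h <- residual
    for (iter in seq_len(max_sift)) {
      env <- envelope_mean(h)
      if (is.null(env)) break
      h_new <- h - env
      sd_crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
      h <- h_new
      if (sd_crit < sd_threshold) break
    }
    imfs[[length(imfs) + 1L]] <- h
    residual <- residual - h
  }
  structure(list(imfs = imfs, residual = residual, fs = fs),
            class = "imf_set")
}

# Mean of upper/lower cubic-spline envelopes; NULL when too few extrema.
envelope_mean <- function(x) {
  n <- length(x)
  ext <- local_extrema(x)
  if (length(ext$max) < 2 || length(ext$min) < 2) return(NULL)
  up <- spline_envelope(ext$max, x, n)
  lo <- spline_envelope(ext$min, x, n)
  (up + lo) / 2
}

# Natural cubic spline through (idx, x[idx]) with two mirrored boundary
# extrema on each side, evaluated at 1..n.
spline_envelope <- function(idx, x, n) {
  xi <- as.double(idx)
  yi <- x[idx]
  k <- min(2L, length(idx) - 1L)
  if (k >= 1) {
    left_x <- 2 * xi[1] - xi[1 + seq_len(k)]
    left_y <- yi[1 + seq_len(k)]
    m <- length(xi)
    right_x <- 2 * xi[m] - xi[m - seq_len(k)]
    right_y <- yi[m - seq_len(k)]
    xi <- c(rev(left_x), xi, right_x)
    yi <- c(rev(left_y), yi, right_y)
  }
  stats::spline(xi, yi, xout = seq_len(n), method = "natural")$y
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMF(s) + residual, n=%d, fs=%g Hz\n",
              length(x$imfs), length(x$residual), x$fs))
  invisible(x)
}

#' Per-component energy and mean-frequency summary of an IMF set
#'
#' Relative energy of component i is \eqn{100 \sum c_i^2 / \sum_j \sum
#' c_j^2} over all IMFs plus the residual, so the column sums to 100%.
#' Mean frequency is the power-spectrum centroid of the component.
#'
#' @param imfset an [emd_decompose()] result.
#' @return data frame with `component`, `mean_frequency_hz`,
#'   `relative_energy_pct`.
#' @export
imf_stats <- function(imfset) {
  stopifnot(inherits(imfset, "imf_set"))
  comps <- c(imfset$imfs, list(imfset$residual))
  names(comps) <- c(paste0("IMF", seq_along(imfset$imfs)), "Residual")
  energies <- vapply(comps, function(c) sum(c^2), numeric(1))
  tot <- sum(energies)
  if (tot <= 0) stop("all-zero decomposition: relative energy undefined",
                     call. = FALSE)
  data.frame(
    component = names(comps),
    mean_frequency_hz = vapply(comps, spectral_centroid_hz, numeric(1),
                               fs = imfset$fs),
    relative_energy_pct = 100 * energies / tot,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' EMD-based denoising
#'
#' Default rule drops IMF1 (the highest-frequency mode, which carries the
#' wideband noise and powerline residue) and reconstructs the signal from
#' all remaining IMFs plus the residual. The generalised rule instead drops
#' every IMF whose relative energy is below `energy_max_pct` *and* whose
#' mean frequency exceeds `freq_min_hz`.
#'
#' @param x numeric signal or `pupg` object.
#' @param fs sampling rate in Hz.
#' @param drop_rule `"first"` (default), `"energy_frequency"`, or `"none"`
#'   (keep everything; identity).
#' @param energy_max_pct,freq_min_hz thresholds for the generalised rule.
#' @param ... passed to [emd_decompose()].
#' @return denoised signal; a `pupg` object in, `pupg` object out.
#' @export
emd_denoise <- function(x, fs = NULL, drop_rule = c("first",
                                                    "energy_frequency",
                                                    "none"),
                        energy_max_pct = 2, freq_min_hz = 40, ...) {
  drop_rule <- match.arg(drop_rule)
  sig <- NULL
  if (inherits(x, "pupg")) { sig <- x; fs <- x$fs; x <- x$samples }
  dec <- emd_decompose(x, fs, ...)
  if (length(dec$imfs) == 0) {
    warning("EMD produced no IMFs; signal returned unchanged", call. = FALSE)
    out <- x
  } else {
    drop <- switch(drop_rule,
      none = rep(FALSE, length(dec$imfs)),
      first = seq_along(dec$imfs) == 1L,
      energy_frequency = {
        st <- imf_stats(dec)
        k <- length(dec$imfs)
        st$relative_energy_pct[seq_len(k)] < energy_max_pct &
          st$mean_frequency_hz[seq_len(k)] > freq_min_hz
      })
    out <- Reduce(`+`, dec$imfs[!drop], dec$residual)
  }
  if (!is.null(sig)) { sig$samples <- out; sig } else out
}
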