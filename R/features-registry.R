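#' The fixed 102-feature registry
#'
#' Ordered names of the 102 features produced by [extract_features()],
#' grouped into nine families: time-domain (19), spectral (17), cepstral
#' (8), chroma (12), sEMG-style (13), moment descriptors (6), Hjorth (2),
#' fractal-chaos (5) and local ternary patterns (20). The order is fixed
#' and versioned; downstream rank tables and selection masks refer to these
#' names.
#'
#' @return character vector of length 102 with a `"group"` attribute.
#' @export
feature_registry <- function() {
  groups <- list(
    time = c("Mean", "Standard Deviation", "Skewness", "Kurtosis",
             "Peak to Peak Value", "Root Mean Square", "Crest Factor",
             "Shape Factor", "Impulse Factor", "Margin Factor", "Energy",
             "Peak to RMS Value", "Root Sum of Squares", "Shannon Energy",
             "Log Energy", "Mean Absolute Deviation",
             "Median Absolute Deviation", "Average Frequency", "Jitter"),
    spectral = c("Spectral Mean", "Spectral Standard Deviation",
                 "Spectral Skewness", "Spectral Kurtosis",
                 "Spectral Centroid", "Spectral Flux", "Spectral Roll-off",
                 "Spectral Flatness", "Spectral Crest", "Spectral Decrease",
                 "Spectral Slope", "Spectral Spread", "Mean Frequency",
                 "Median Frequency", "Spurious-free Dynamic Range",
                 "Signal to Noise Distortion", "Total Harmonic Distortions"),
    cepstral = c(paste(ordinal(1:4), "Coefficient of MFCC"),
                 paste(ordinal(1:4), "Coefficient of GFCC")),
    chroma = paste(ordinal(1:12), "Coefficient of Chroma Vector"),
    semg = c("Enhanced Mean Absolute Value", "Enhanced Wavelength",
             "Wavelength", "Slope Sign Change", "Average Amplitude Change",
             "Difference Absolute Std. Dev.", "Log Detector",
             "Modified Mean Absolute Value", "Modified Mean Absolute Value 2",
             "Pulse Percentage Rate", "Simple Square Integral",
             "Willison Amplitude", "Maximum Fractal Length"),
    moment = c("Root Squared Zero Order Moment",
               "Root Squared 2nd Order Moment",
               "Root Squared 4th Order Moment", "Sparseness",
               "Irregularity Factor", "Waveform Length Ratio"),
    hjorth = c("Complexity", "Mobility"),
    fractal = c("Higuchi's Fractal Dimension", "Katz Fractal Dimension",
                "Lyapunov Exponent", "Approximate Entropy",
                "Correlation Dimension"),
    ltp = paste(ordinal(1:20), "Coefficient of LTP")
  )
  reg <- unlist(groups, use.names = FALSE)
  attr(reg, "group") <- rep(names(groups), lengths(groups))
  reg
}

#' Feature-extraction parameters
#'
#' @param semg_thresh amplitude/slope threshold for the sEMG family.
#' @param ltp_t ternary threshold for the LTP family.
#' @param chaos_fs decimation target for the embedding-based estimators.
#' @param frame,hop framing for cepstral/chroma features.
#' @param rolloff spectral roll-off energy fraction.
#' @return named list.
#' @export
feature_params <- function(semg_thresh = 0.01, ltp_t = 0.01, chaos_fs = 125,
                           frame = 1024L, hop = 512L, rolloff = 0.95) {
  list(semg_thresh = semg_thresh, ltp_t = ltp_t, chaos_fs = chaos_fs,
       frame = frame, hop = hop, rolloff = rolloff)
}

#' Extract all 102 features from one signal
#'
#' Concatenates the nine feature families in registry order. Non-finite
#' intermediate values are replaced by sentinel 0 with a warning, so the
#' returned vector is always finite.
#'
#' @param x numeric signal or `pupg` object.
#' @param fs sampling rate in Hz.
#' @param params a [feature_params()] list.
#' @return named numeric vector of length 102.
#' @export
extract_features <- function(x, fs = NULL, params = feature_params()) {
  if (inherits(x, "pupg")) { fs <- x$fs; x <- x$samples }
  if (is.null(fs)) stop("fs required", call. = FALSE)
  v <- c(
    time_domain_features(x, fs),
    spectral_features(x, fs, rolloff = params$rolloff),
    cepstral_features(x, fs, frame = params$frame, hop = params$hop),
    chroma_features(x, fs, frame = params$frame, hop = params$hop),
    semg_features(x, thresh = params$semg_thresh),
    moment_features(x),
    hjorth_features(x),
    fractal_features(x, fs, chaos_fs = params$chaos_fs),
    ltp_features(x, t = params$ltp_t)
  )
  reg <- feature_registry()
  stopifnot(identical(names(v), as.character(reg)))
  v
}

#' Extract a feature matrix from a list of signals
#'
#' @param signals list of `pupg` objects (e.g. read via
#'   [read_pupg_manifest()] + [read_pupg_signal()]).
#' @param params a [feature_params()] list.
#' @param preprocess optional function applied to each signal first (e.g.
#'   `emd_denoise` or `dwt_denoise`).
#' @return a `feature_matrix`: list with `x` (N x 102 matrix, rownames =
#'   ids), `labels` (character).
#' @export
extract_feature_matrix <- function(signals, params = feature_params(),
                                   preprocess = NULL) {
  rows <- lapply(signals, function(s) {
    if (!is.null(preprocess)) s <- preprocess(s)
    extract_features(s, params = params)
  })
  x <- do.call(rbind, rows)
  rownames(x) <- vapply(signals, function(s) s$id, character(1))
  structure(list(x = x,
                 labels = vapply(signals, function(s) s$label, character(1))),
            class = "feature_matrix")
}

#' Write / read a feature matrix as CSV
#'
#' Columns: `id`, `label`, then the 102 registry names.
#'
#' @param fm a `feature_matrix`.
#' @param path CSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(id = rownames(fm$x), label = fm$labels,
                   fm$x, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @param path CSV path.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(x) <- df$id
  structure(list(x = x, labels = df$label), class = "feature_matrix")
}
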