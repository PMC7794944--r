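#' Configuration for the synthetic PuPG generator
#'
#' Builds the parameter set used by [pupg_signal()] and [pupg_dataset()].
#' The generator emulates a finger pulse-plethysmograph recording: a
#' quasi-periodic train of beats, each the sum of a systolic Gaussian pulse
#' and a delayed, smaller dicrotic Gaussian, plus low-frequency baseline
#' wander, a 50 Hz powerline tone, and band-limited wideband noise. Recorded
#' polarity follows the piezoelectric sensor convention (beats deflect
#' downward), which gives the waveform its characteristic negative skew.
#'
#' Class contrast (defaults): the hypertensive class has a dicrotic wave of
#' half the normotensive amplitude, a shorter dicrotic delay, a slightly
#' higher and more variable heart rate, and a 30% wider noise bandwidth,
#' giving it the broader spectral content and damped notch seen in
#' hypertensive pulse morphology.
#'
#' @param n_per_class signals per class.
#' @param duration_s record length in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer seed; every signal derives its own RNG stream from
#'   `(seed, class, index)` so generation order does not matter.
#' @param normal,hypertension per-class morphology lists; see
#'   [pupg_class_params()] for fields and defaults.
#' @param powerline_amp amplitude of the 50 Hz mains tone.
#' @param powerline_hz mains frequency in Hz.
#' @param noise_sd standard deviation of the wideband noise before band
#'   limiting.
#' @param wander_amp,wander_freq_hz baseline-wander amplitude and frequency.
#' @return an object of class `pupg_config`.
#' @export
pupg_config <- function(n_per_class = 100L,
                        duration_s = 10,
                        fs = 1000,
                        seed = 1L,
                        normal = pupg_class_params("normal"),
                        hypertension = pupg_class_params("hypertension"),
                        powerline_amp = 0.02,
                        powerline_hz = 50,
                        noise_sd = 0.03,
                        wander_amp = 0.1,
                        wander_freq_hz = 0.25) {
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive", call. = FALSE)
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  for (cls in list(normal, hypertension)) {
    if (cls$dicrotic_amp < 0 || cls$dicrotic_amp >= cls$systolic_amp)
      stop("require 0 <= dicrotic_amp < systolic_amp", call. = FALSE)
  }
  structure(list(
    n_per_class = as.integer(n_per_class), duration_s = duration_s, fs = fs,
    seed = as.integer(seed), normal = normal, hypertension = hypertension,
    powerline_amp = powerline_amp, powerline_hz = powerline_hz,
    noise_sd = noise_sd, wander_amp = wander_amp,
    wander_freq_hz = wander_freq_hz
  ), class = "pupg_config")
}

#' Per-class morphology parameters
#'
#' @param class `"normal"` or `"hypertension"`.
#' @param ... overrides for individual fields: `heart_rate_bpm`,
#'   `heart_rate_jitter_bpm`, `systolic_amp`, `systolic_width_s`,
#'   `dicrotic_amp`, `dicrotic_delay_s`, `dicrotic_width_s`,
#'   `beat_jitter_frac` (per-beat onset jitter as a fraction of the period)
#'   and `noise_bw_hz` (low-pass cutoff of the wideband noise).
#' @return a named list.
#' @export
pupg_class_params <- function(class = c("normal", "hypertension"), ...) {
  class <- match.arg(class)
  p <- if (class == "normal") {
    list(heart_rate_bpm = 72, heart_rate_jitter_bpm = 3,
         systolic_amp = 1, systolic_width_s = 0.045,
         dicrotic_amp = 0.35, dicrotic_delay_s = 0.30,
         dicrotic_width_s = 0.06, beat_jitter_frac = 0.02,
         noise_bw_hz = 60)
  } else {
    list(heart_rate_bpm = 78, heart_rate_jitter_bpm = 5,
         systolic_amp = 1, systolic_width_s = 0.045,
         dicrotic_amp = 0.175, dicrotic_delay_s = 0.22,
         dicrotic_width_s = 0.06, beat_jitter_frac = 0.03,
         noise_bw_hz = 78)
  }
  utils::modifyList(p, list(...))
}

#' Noise-free beat template
#'
#' The deterministic waveform of a single beat with onset `onset_s`:
#' a systolic Gaussian plus a delayed dicrotic Gaussian, with the sensor's
#' downward polarity applied.
#'
#' @param t time axis in seconds.
#' @param onset_s beat onset (location of the systolic peak).
#' @param params a [pupg_class_params()] list.
#' @return numeric vector of `length(t)`.
#' @export
pupg_beat_template <- function(t, onset_s, params) {
  sys <- params$systolic_amp *
    exp(-(t - onset_s)^2 / (2 * params$systolic_width_s^2))
  dic <- params$dicrotic_amp *
    exp(-(t - onset_s - params$dicrotic_delay_s)^2 /
          (2 * params$dicrotic_width_s^2))
  -(sys + dic)
}

#' Generate one synthetic PuPG signal
#'
#' Deterministic in `(cfg$seed, label, index)`: the same triple always
#' produces a bit-identical signal regardless of generation order.
#'
#' @param cfg a [pupg_config()].
#' @param label `"normal"` or `"hypertension"`.
#' @param index 1-based signal index within the class.
#' @return a `pupg` object: list with `samples`, `fs`, `id`, `label`.
#' @export
pupg_signal <- function(cfg, label = c("normal", "hypertension"), index = 1L) {
  stopifnot(inherits(cfg, "pupg_config"))
  label <- match.arg(label)
  params <- cfg[[label]]
  n <- round(cfg$duration_s * cfg$fs)
  t <- (seq_len(n) - 1) / cfg$fs
  cls_id <- if (label == "normal") 1L else 2L

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, cls_id, index))

  hr <- params$heart_rate_bpm + stats::rnorm(1, 0, params$heart_rate_jitter_bpm)
  hr <- max(hr, 30)
  period <- 60 / hr
  n_beats <- ceiling(cfg$duration_s / period) + 2L
  onsets <- (seq_len(n_beats) - 1) * period +
    stats::rnorm(n_beats, 0, params$beat_jitter_frac * period)

  x <- numeric(n)
  for (o in onsets) x <- x + pupg_beat_template(t, o, params)

  wander <- cfg$wander_amp *
    sin(2 * pi * cfg$wander_freq_hz * t + stats::runif(1, 0, 2 * pi))
  powerline <- cfg$powerline_amp * sin(2 * pi * cfg$powerline_hz * t)
  noise <- stats::rnorm(n, 0, cfg$noise_sd)
  if (cfg$noise_sd > 0 && params$noise_bw_hz < cfg$fs / 2) {
    bf <- signal::butter(4, params$noise_bw_hz / (cfg$fs / 2), type = "low")
    noise <- as.numeric(signal::filtfilt(bf, noise))
  }

  structure(list(
    samples = x + wander + powerline + noise,
    fs = cfg$fs,
    id = sprintf("%s_%03d", label, index),
    label = label
  ), class = "pupg")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.pupg <- function(x, ...) {
  cat(sprintf("<pupg signal> id=%s label=%s n=%d fs=%g Hz\n",
              x$id, x$label, length(x$samples), x$fs))
  invisible(x)
}

#' Generate a two-class synthetic PuPG dataset on disk
#'
#' Writes one plain-text file per signal (one sample per line) and a
#' manifest CSV with columns `id,path,label`; paths are relative to the
#' manifest location.
#'
#' @param cfg a [pupg_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest data frame (with a `"manifest_path"`
#'   attribute).
#' @export
pupg_dataset <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pupg_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create out_dir: ", out_dir, call. = FALSE)
  rows <- list()
  for (label in c("normal", "hypertension")) {
    for (i in seq_len(cfg$n_per_class)) {
      sig <- pupg_signal(cfg, label, i)
      path <- paste0(sig$id, ".txt")
      writeLines(formatC(sig$samples, format = "g", digits = 17),
                 file.path(out_dir, path))
      rows[[length(rows) + 1L]] <- data.frame(
        id = sig$id, path = path, label = label, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  attr(manifest, "manifest_path") <- mpath
  invisible(manifest)
}

#' Read a PuPG dataset manifest
#'
#' @param manifest_path path to a `manifest.csv` written by [pupg_dataset()]
#'   (or hand-built with the same `id,path,label` columns).
#' @return data frame with absolute `path` column.
#' @export
read_pupg_manifest <- function(manifest_path) {
  m <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("id", "path", "label")
  if (!all(need %in% names(m)))
    stop("manifest must have columns id, path, label", call. = FALSE)
  m$path <- file.path(dirname(manifest_path), m$path)
  m
}

#' Read one PuPG signal file
#'
#' Accepts one-sample-per-line text or two-column `time,value` CSV.
#'
#' @param path file path.
#' @param fs sampling rate in Hz.
#' @param id,label metadata attached to the returned object.
#' @return a `pupg` object.
#' @export
read_pupg_signal <- function(path, fs = 1000, id = basename(path),
                             label = "unlabeled") {
  first <- readLines(path, n = 1)
  if (grepl(",", first, fixed = TRUE)) {
    d <- utils::read.csv(path, header = grepl("[A-Za-z]", first))
    samples <- as.numeric(d[[2]])
  } else {
    samples <- as.numeric(readLines(path))
  }
  if (anyNA(samples) || !all(is.finite(samples)))
    stop("non-finite samples in ", path, call. = FALSE)
  structure(list(samples = samples, fs = fs, id = id, label = label),
            class = "pupg")
}
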