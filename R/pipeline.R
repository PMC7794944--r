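#' Run configuration for the end-to-end pipeline
#'
#' @param method preprocessing route: `"emd"` (EMD denoising, the headline
#'   configuration) or `"dwt"` (wavelet denoising).
#' @param manifest path to the dataset manifest CSV (`id,path,label`).
#' @param workdir artifact directory; one subdirectory per run.
#' @param fs sampling rate of the signal files.
#' @param classifier roster name.
#' @param k_top features kept by mean-rank fusion.
#' @param n_components KPCA components (use [component_preset()] for the
#'   S1..S6 presets).
#' @param kernel KPCA kernel.
#' @param folds cross-validation folds.
#' @param holdout optional holdout fraction instead of k-fold.
#' @param seed run seed.
#' @param feature_params a [feature_params()] list.
#' @return a validated `run_config`.
#' @export
run_config <- function(method = c("emd", "dwt"), manifest, workdir = tempdir(),
                       fs = 1000, classifier = "KNN-W", k_top = 24L,
                       n_components = 5L, kernel = "rbf", folds = 10L,
                       holdout = NULL, seed = 1L, feature_params = NULL) {
  if (is.null(feature_params))
    feature_params <- get("feature_params", envir = parent.env(environment()),
                          mode = "function")()
  method <- match.arg(method)
  if (!file.exists(manifest)) stop("manifest not found: ", manifest,
                                   call. = FALSE)
  if (k_top < 1 || n_components < 1 || folds < 2)
    stop("invalid HFSR/CV parameters", call. = FALSE)
  structure(list(method = method, manifest = normalizePath(manifest),
                 workdir = workdir, fs = fs, classifier = classifier,
                 k_top = as.integer(k_top),
                 n_components = as.integer(n_components), kernel = kernel,
                 folds = as.integer(folds), holdout = holdout,
                 seed = as.integer(seed), feature_params = feature_params),
            class = "run_config")
}

#' Denoise one signal according to the configured route
#'
#' @param x numeric signal or `pupg` object.
#' @param fs sampling rate in Hz.
#' @param method `"emd"` or `"dwt"`.
#' @return denoised signal of the same type.
#' @export
preprocess_signal <- function(x, fs = NULL, method = c("emd", "dwt")) {
  method <- match.arg(method)
  if (method == "emd") emd_denoise(x, fs) else dwt_denoise(x, fs)
}

load_signals <- function(config) {
  m <- read_pupg_manifest(config$manifest)
  lapply(seq_len(nrow(m)), function(i)
    read_pupg_signal(m$path[i], fs = config$fs, id = m$id[i],
                     label = m$label[i]))
}

#' Compute the preprocessed feature matrix for a run
#'
#' Reads every signal in the manifest, denoises it via the configured
#' route and extracts the 102-feature vector.
#'
#' @param config a [run_config()].
#' @return a `feature_matrix`.
#' @export
pipeline_features <- function(config) {
  stopifnot(inherits(config, "run_config"))
  signals <- load_signals(config)
  extract_feature_matrix(
    signals, params = config$feature_params,
    preprocess = function(s) preprocess_signal(s, method = config$method))
}

run_dir <- function(config) {
  key <- paste(config$method, config$classifier, config$k_top,
               config$n_components, config$kernel, config$folds,
               config$seed, basename(config$manifest), sep = "_")
  file.path(config$workdir, paste0("run_", gsub("[^A-Za-z0-9_.-]", "", key)))
}

#' Execute one end-to-end run
#'
#' preprocess -> feature extraction -> cross-validated HFSR + classifier.
#' Artifacts written to the run directory: `features.csv`, `ranks.csv`
#' (rank table on the full data, for reporting), `kpca.json`,
#' `report.json` and `run.log` (all stage parameters and durations).
#'
#' @param config a [run_config()].
#' @param features optional precomputed `feature_matrix` (skips
#'   extraction; used by [sweep_components()]).
#' @return the `eval_report`, with the artifact directory in
#'   `attr(, "artifacts")`.
#' @export
run_method <- function(config, features = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir <- run_dir(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(dir, "run.log")
  log_line <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                                sprintf(...), "\n", sep = "",
                                file = log_path, append = TRUE)
  cat("", file = log_path)
  log_line("config: %s", jsonlite::toJSON(
    config[setdiff(names(config), "feature_params")], auto_unbox = TRUE))
  log_line("feature_params: %s",
           jsonlite::toJSON(config$feature_params, auto_unbox = TRUE))

  t0 <- Sys.time()
  if (is.null(features)) features <- pipeline_features(config)
  write_feature_matrix(features, file.path(dir, "features.csv"))
  log_line("features: %d x %d in %.1fs", nrow(features$x), ncol(features$x),
           as.numeric(difftime(Sys.time(), t0, units = "secs")))

  t1 <- Sys.time()
  rt <- rank_table(features$x, features$labels)
  write_rank_table(rt, file.path(dir, "ranks.csv"))
  full_hfsr <- hfsr_fit(features$x, features$labels, k_top = config$k_top,
                        n_components = config$n_components,
                        kernel = config$kernel)
  save_kpca(full_hfsr$kpca, file.path(dir, "kpca.json"))
  log_line("hfsr: top-%d of %d features -> %d components in %.1fs",
           config$k_top, ncol(features$x), config$n_components,
           as.numeric(difftime(Sys.time(), t1, units = "secs")))

  t2 <- Sys.time()
  report <- cross_validate(features, classifier = config$classifier,
                           folds = config$folds, seed = config$seed,
                           hfsr = TRUE, k_top = config$k_top,
                           n_components = config$n_components,
                           kernel = config$kernel, holdout = config$holdout)
  report_to_json(report, file.path(dir, "report.json"))
  log_line("cv: %s in %.1fs", paste(sprintf("%s=%.4f", names(report$metrics),
                                            report$metrics), collapse = " "),
           as.numeric(difftime(Sys.time(), t2, units = "secs")))
  attr(report, "artifacts") <- dir
  attr(report, "selected") <- full_hfsr$selected
  report
}

#' Side-by-side comparison of two runs
#'
#' Runs both configurations (which must point at the same manifest) and
#' tabulates accuracy, sensitivity, specificity, error and the number of
#' transformed features.
#'
#' @param config_a,config_b [run_config()] objects.
#' @param features_a,features_b optional precomputed feature matrices.
#' @return data frame with a `Performance` column and one column per
#'   method.
#' @export
compare_methods <- function(config_a, config_b, features_a = NULL,
                            features_b = NULL) {
  if (config_a$manifest != config_b$manifest)
    stop("both configurations must use the same manifest", call. = FALSE)
  ra <- run_method(config_a, features_a)
  rb <- run_method(config_b, features_b)
  fmt <- function(r, cfg) c(
    sprintf("%.2f%%", 100 * r$metrics[c("accuracy", "sensitivity",
                                        "specificity", "error")]),
    as.character(cfg$n_components))
  data.frame(
    Performance = c("Accuracy", "Sensitivity", "Specificity", "Error",
                    "# of features"),
    method_a = fmt(ra, config_a),
    method_b = fmt(rb, config_b),
    stringsAsFactors = FALSE
  )
}

#' Performance as a function of the component count
#'
#' Re-evaluates the configured pipeline for each component count in
#' `presets` (features are extracted once and reused).
#'
#' @param config a [run_config()].
#' @param presets integer component counts (default 1..24).
#' @param features optional precomputed `feature_matrix`.
#' @return data frame with `components`, `accuracy`, `sensitivity`,
#'   `specificity`, `error`.
#' @export
sweep_components <- function(config, presets = 1:24, features = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(features)) features <- pipeline_features(config)
  rows <- lapply(presets, function(nc) {
    r <- cross_validate(features, classifier = config$classifier,
                        folds = config$folds, seed = config$seed,
                        hfsr = TRUE, k_top = config$k_top,
                        n_components = nc, kernel = config$kernel)
    c(components = nc, r$metrics)
  })
  as.data.frame(do.call(rbind, rows))
}
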