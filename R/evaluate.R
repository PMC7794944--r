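POSITIVE_CLASS <- "hypertension"

confusion_counts <- function(truth, pred, positive = POSITIVE_CLASS) {
  truth <- as.character(truth); pred <- as.character(pred)
  c(TP = sum(truth == positive & pred == positive),
    FN = sum(truth == positive & pred != positive),
    FP = sum(truth != positive & pred == positive),
    TN = sum(truth != positive & pred != positive))
}

report_metrics <- function(cm) {
  n <- sum(cm)
  acc <- as.numeric(cm["TP"] + cm["TN"]) / n
  c(accuracy = acc,
    sensitivity = as.numeric(cm["TP"]) / as.numeric(cm["TP"] + cm["FN"]),
    specificity = as.numeric(cm["TN"]) / as.numeric(cm["TN"] + cm["FP"]),
    error = 1 - acc)
}

#' Stratified cross-validation of the full pipeline
#'
#' Splits the samples into stratified folds (shuffled with `seed`), fits
#' the hybrid feature selection and reduction stage and the classifier on
#' each training fold only, predicts the held-out fold, and pools the
#' per-fold confusion matrices into one report. Sensitivity is the
#' true-positive rate on the hypertension class, specificity the
#' true-negative rate on the normal class. Holdout evaluation (single
#' stratified train/test split) is available through `holdout`.
#'
#' @param x feature matrix (samples x features) or a `feature_matrix`.
#' @param y class labels (ignored when `x` is a `feature_matrix`).
#' @param classifier roster name (see [baseline_roster()]).
#' @param folds fold count (>= 2); each class must have at least `folds`
#'   members.
#' @param seed RNG seed for fold assignment (and any stochastic learner).
#' @param hfsr logical: run rank fusion + KPCA inside each training fold.
#' @param k_top,n_components,kernel HFSR parameters.
#' @param holdout optional test fraction (e.g. 0.2, 0.25); overrides
#'   `folds`.
#' @param positive positive-class label.
#' @return an `eval_report`: pooled confusion matrix and metrics, per-fold
#'   metrics, and the configuration descriptor.
#' @export
cross_validate <- function(x, y = NULL, classifier = "KNN-W", folds = 10L,
                           seed = 1L, hfsr = TRUE, k_top = 24L,
                           n_components = 5L, kernel = "rbf",
                           holdout = NULL, positive = POSITIVE_CLASS) {
  if (inherits(x, "feature_matrix")) { y <- x$labels; x <- x$x }
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("two classes required", call. = FALSE)
  if (is.null(holdout)) {
    if (folds < 2) stop("folds must be >= 2", call. = FALSE)
    if (min(table(y)) < folds)
      stop("each class needs at least `folds` members", call. = FALSE)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 101L))

  assign_folds <- function() {
    f <- integer(length(y))
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
    f
  }
  if (is.null(holdout)) {
    fold_id <- assign_folds()
    splits <- lapply(seq_len(folds), function(k)
      list(train = which(fold_id != k), test = which(fold_id == k)))
  } else {
    test <- unlist(lapply(levels(y), function(lv) {
      idx <- sample(which(y == lv))
      idx[seq_len(max(1L, round(holdout * length(idx))))]
    }))
    splits <- list(list(train = setdiff(seq_along(y), test), test = test))
  }

  clf <- baseline_roster(classifier)
  fold_results <- lapply(splits, function(sp) {
    xtr <- x[sp$train, , drop = FALSE]
    ytr <- droplevels(y[sp$train])
    xte <- x[sp$test, , drop = FALSE]
    if (hfsr) {
      hm <- hfsr_fit(xtr, ytr, k_top = k_top, n_components = n_components,
                     kernel = kernel)
      xtr <- hfsr_transform(hm, xtr)
      xte <- hfsr_transform(hm, xte)
      colnames(xtr) <- colnames(xte) <- paste0("PC", seq_len(ncol(xtr)))
    }
    model <- clf$fit(xtr, ytr)
    pred <- clf$predict(model, xte)
    list(cm = confusion_counts(y[sp$test], pred, positive))
  })
  cms <- do.call(rbind, lapply(fold_results, `[[`, "cm"))
  pooled <- colSums(cms)
  structure(list(
    confusion = pooled,
    metrics = report_metrics(pooled),
    per_fold = data.frame(fold = seq_len(nrow(cms)), cms,
                          t(apply(cms, 1, report_metrics))),
    config = list(classifier = classifier,
                  folds = if (is.null(holdout)) folds else NA_integer_,
                  holdout = holdout, seed = seed, hfsr = hfsr,
                  k_top = if (hfsr) k_top else NA_integer_,
                  n_components = if (hfsr) n_components else NA_integer_,
                  kernel = if (hfsr) kernel else NA_character_,
                  positive = positive, n = length(y))
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf("<eval_report> %s, %s, n=%d\n", x$config$classifier,
              if (is.null(x$config$holdout))
                sprintf("%d-fold CV", x$config$folds)
              else sprintf("%.0f%% holdout", 100 * x$config$holdout),
              x$config$n))
  cat(sprintf("  confusion (pos=%s): TP=%d FN=%d FP=%d TN=%d\n",
              x$config$positive, cm["TP"], cm["FN"], cm["FP"], cm["TN"]))
  m <- x$metrics
  cat(sprintf("  Acc=%.3f Sen=%.3f Sp=%.3f Err=%.3f\n",
              m["accuracy"], m["sensitivity"], m["specificity"],
              m["error"]))
  invisible(x)
}

#' Serialise an evaluation report
#'
#' `report_to_json` writes the full report; `report_row` returns the
#' one-line `Classifier, Acc, Sp, Sen, Err` comparison-table row.
#'
#' @param report an `eval_report`.
#' @param path JSON path.
#' @export
report_to_json <- function(report, path) {
  jsonlite::write_json(list(
    confusion = as.list(report$confusion),
    metrics = as.list(report$metrics),
    per_fold = report$per_fold,
    config = report$config
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname report_to_json
#' @export
report_row <- function(report) {
  m <- report$metrics
  data.frame(Classifier = report$config$classifier,
             Acc = m["accuracy"], Sp = m["specificity"],
             Sen = m["sensitivity"], Err = m["error"],
             row.names = NULL)
}
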