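#' Baseline classifier roster
#'
#' Resolves the comparison-table classifier names to fit/predict pairs
#' behind one interface. Members: decision tree (`DT`), linear
#' discriminant (`LD`), logistic regression (`LR`), Gaussian and
#' kernel-density naive Bayes (`NBG`, `NBK`), SVMs with linear, quadratic,
#' cubic and fine/medium Gaussian kernels (`SVM-L`, `SVM-Q`, `SVM-C`,
#' `SVM-FG`, `SVM-MG`), KNN variants (`KNN-F` fine k=1, `KNN-M` medium
#' k=10, `KNN-Cos` cosine, `KNN-C` cubic-distance, `KNN-W` distance
#' weighted), boosted trees (`Eboost`), bagged trees (`EBT`) and the
#' subspace ensembles (`ESD` discriminant, `ESKNN` KNN).
#'
#' @param name roster name (see Details).
#' @return list with elements `name`, `fit(x, y)` and
#'   `predict(model, newx)`; predictions are factors on the training
#'   levels.
#' @export
baseline_roster <- function(name) {
  knn_spec <- function(k, distance = "euclidean", weight = "uniform", p = 3)
    list(
      fit = function(x, y) knnw_fit(x, y, k = min(k, nrow(x)),
                                    weight = weight, distance = distance,
                                    p = p),
      predict = function(m, newx) knnw_predict(m, newx)
    )
  svm_spec <- function(kernel, degree = 3, gamma_mult = 1)
    list(
      fit = function(x, y) e1071::svm(x, as.factor(y), kernel = kernel,
                                      degree = degree, coef0 = 1,
                                      gamma = gamma_mult / ncol(x),
                                      scale = apply(x, 2, stats::sd) > 0),
      predict = function(m, newx) stats::predict(m, newx)
    )
  subspace_spec <- function(base_fit, base_predict, n_learners = 30L)
    list(
      fit = function(x, y) {
        d <- ncol(x)
        sub_d <- max(1L, ceiling(d / 2))
        learners <- lapply(seq_len(n_learners), function(i) {
          cols <- sample.int(d, sub_d)
          list(cols = cols, model = base_fit(x[, cols, drop = FALSE], y))
        })
        list(learners = learners, levels = levels(as.factor(y)))
      },
      predict = function(m, newx) {
        votes <- sapply(m$learners, function(l)
          as.character(base_predict(l$model, newx[, l$cols, drop = FALSE])))
        if (!is.matrix(votes)) votes <- matrix(votes, nrow = 1)
        factor(apply(votes, 1, function(v) names(which.max(table(v)))),
               levels = m$levels)
      }
    )

  spec <- switch(name,
    "DT" = list(
      fit = function(x, y) rpart::rpart(y ~ ., data.frame(y = as.factor(y), x),
                                        method = "class"),
      predict = function(m, newx)
        stats::predict(m, data.frame(newx), type = "class")),
    "LD" = list(
      fit = function(x, y) MASS::lda(x, grouping = as.factor(y)),
      predict = function(m, newx) stats::predict(m, newx)$class),
    "LR" = list(
      fit = function(x, y) {
        y <- as.factor(y)
        list(glm = suppressWarnings(
          stats::glm(y ~ ., data.frame(y = y, x), family = stats::binomial())),
          levels = levels(y))
      },
      predict = function(m, newx) {
        p <- stats::predict(m$glm, data.frame(newx), type = "response")
        factor(m$levels[1 + (p > 0.5)], levels = m$levels)
      }),
    "NBG" = list(
      fit = function(x, y) e1071::naiveBayes(x, as.factor(y)),
      predict = function(m, newx) stats::predict(m, newx)),
    "NBK" = list(fit = nbk_fit, predict = nbk_predict),
    "SVM-L" = svm_spec("linear"),
    "SVM-Q" = svm_spec("polynomial", degree = 2),
    "SVM-C" = svm_spec("polynomial", degree = 3),
    "SVM-FG" = svm_spec("radial", gamma_mult = 4),
    "SVM-MG" = svm_spec("radial", gamma_mult = 1),
    "KNN-F" = knn_spec(1L),
    "KNN-M" = knn_spec(10L),
    "KNN-Cos" = knn_spec(10L, distance = "cosine"),
    "KNN-C" = knn_spec(10L, distance = "minkowski", p = 3),
    "KNN-W" = knn_spec(10L, weight = "inverse_distance_squared"),
    "Eboost" = list(
      fit = function(x, y) xgboost::xgboost(as.matrix(x), as.factor(y),
                                            nrounds = 30, max_depth = 3,
                                            verbosity = 0, nthread = 1),
      predict = function(m, newx)
        stats::predict(m, as.matrix(newx), type = "class")),
    "EBT" = list(
      fit = function(x, y) randomForest::randomForest(
        x, as.factor(y), ntree = 100, mtry = ncol(x)), # mtry = p: bagging
      predict = function(m, newx) stats::predict(m, newx)),
    "ESD" = subspace_spec(
      function(x, y) MASS::lda(x, grouping = as.factor(y)),
      function(m, newx) stats::predict(m, newx)$class),
    "ESKNN" = subspace_spec(
      function(x, y) knnw_fit(x, y, k = 1L),
      function(m, newx) knnw_predict(m, newx)),
    stop("unknown classifier '", name, "'", call. = FALSE)
  )
  c(list(name = name), spec)
}

#' @rdname baseline_roster
#' @export
roster_names <- function() {
  c("DT", "LD", "LR", "NBG", "NBK", "SVM-L", "SVM-Q", "SVM-C", "SVM-FG",
    "SVM-MG", "KNN-F", "KNN-M", "KNN-Cos", "KNN-C", "KNN-W", "Eboost",
    "EBT", "ESD", "ESKNN")
}

# Kernel-density naive Bayes: per-class, per-feature Gaussian KDE.
nbk_fit <- function(x, y) {
  y <- as.factor(y)
  dens <- lapply(levels(y), function(l) {
    xi <- x[y == l, , drop = FALSE]
    lapply(seq_len(ncol(x)), function(j) {
      v <- xi[, j]
      if (stats::sd(v) == 0) v <- v + stats::rnorm(length(v), 0, 1e-9)
      d <- stats::density(v, n = 512)
      list(fun = stats::approxfun(d$x, pmax(d$y, 1e-12), rule = 2))
    })
  })
  names(dens) <- levels(y)
  list(dens = dens, prior = table(y) / length(y), levels = levels(y))
}

nbk_predict <- function(m, newx) {
  newx <- as.matrix(newx)
  ll <- sapply(m$levels, function(l) {
    s <- log(as.numeric(m$prior[l]))
    s + rowSums(sapply(seq_len(ncol(newx)), function(j)
      log(m$dens[[l]][[j]]$fun(newx[, j]))))
  })
  if (!is.matrix(ll)) ll <- matrix(ll, nrow = 1)
  factor(m$levels[apply(ll, 1, which.max)], levels = m$levels)
}
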