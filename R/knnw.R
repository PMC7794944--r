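#' Weighted k-nearest-neighbour classifier
#'
#' Lazy learner storing z-scored training points. Prediction sums the
#' neighbour weights per class; the default weight is the inverse squared
#' distance. Zero-distance neighbours dominate (infinite-weight rule: the
#' majority class among coincident points wins); an exact weight tie falls
#' back to the class of the single nearest neighbour.
#'
#' @param x training matrix (samples x dims).
#' @param y class labels.
#' @param k neighbour count (default 10).
#' @param weight `"inverse_distance_squared"`, `"inverse_distance"` or
#'   `"uniform"`.
#' @param distance `"euclidean"`, `"cosine"` or `"minkowski"`.
#' @param p Minkowski exponent (3 = "cubic" distance).
#' @param standardize z-score with training statistics (default TRUE).
#' @return a `knnw_model`.
#' @export
knnw_fit <- function(x, y, k = 10L, weight = c("inverse_distance_squared",
                                               "inverse_distance", "uniform"),
                     distance = c("euclidean", "cosine", "minkowski"),
                     p = 3, standardize = TRUE) {
  weight <- match.arg(weight)
  distance <- match.arg(distance)
  x <- as.matrix(x)
  y <- as.factor(y)
  if (k < 1 || k > nrow(x))
    stop("k must lie in 1..number of training samples", call. = FALSE)
  if (standardize) {
    centre <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  } else {
    centre <- rep(0, ncol(x)); scale_ <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2, centre), 2, scale_, "/")
  structure(list(x = xs, y = y, k = as.integer(k), weight = weight,
                 distance = distance, p = p, centre = centre,
                 scale = scale_),
            class = "knnw_model")
}

knn_distances <- function(model, q) {
  switch(model$distance,
    euclidean = sqrt(pmax(outer(rowSums(q^2), rowSums(model$x^2), "+") -
                            2 * q %*% t(model$x), 0)),
    minkowski = {
      d <- matrix(0, nrow(q), nrow(model$x))
      for (j in seq_len(ncol(q)))
        d <- d + abs(outer(q[, j], model$x[, j], "-"))^model$p
      d^(1 / model$p)
    },
    cosine = {
      qn <- sqrt(rowSums(q^2)); tn <- sqrt(rowSums(model$x^2))
      qn[qn == 0] <- 1; tn[tn == 0] <- 1
      1 - (q %*% t(model$x)) / outer(qn, tn)
    })
}

#' @rdname knnw_fit
#' @param model a `knnw_model`.
#' @param newx matrix of query points.
#' @return factor of predicted labels.
#' @export
knnw_predict <- function(model, newx) {
  stopifnot(inherits(model, "knnw_model"))
  newx <- as.matrix(newx)
  q <- sweep(sweep(newx, 2, model$centre), 2, model$scale, "/")
  d <- knn_distances(model, q)
  lev <- levels(model$y)
  out <- character(nrow(q))
  for (i in seq_len(nrow(q))) {
    ord <- order(d[i, ], model$y) # deterministic under distance ties
    nb <- ord[seq_len(model$k)]
    dn <- d[i, nb]
    if (any(dn < 1e-12)) { # coincident points dominate
      votes <- table(model$y[nb[dn < 1e-12]])
      out[i] <- names(votes)[which.max(votes)]
      next
    }
    w <- switch(model$weight,
                inverse_distance_squared = 1 / dn^2,
                inverse_distance = 1 / dn,
                uniform = rep(1, length(dn)))
    sums <- vapply(lev, function(l) sum(w[model$y[nb] == l]), numeric(1))
    top <- which(sums == max(sums))
    out[i] <- if (length(top) > 1) as.character(model$y[nb[1]]) else lev[top]
  }
  factor(out, levels = lev)
}
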