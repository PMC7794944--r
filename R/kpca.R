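#' Kernel principal component analysis
#'
#' Features are z-scored with training statistics, the kernel matrix is
#' double-centred and eigendecomposed, and the leading eigenvectors
#' (scaled by 1/sqrt(eigenvalue)) define the projection. Component-count
#' presets S1..S6 correspond to 5, 7, 10, 12, 15 and 17 components.
#'
#' @param x training matrix (samples x features).
#' @param kernel `"rbf"` (default), `"linear"` or `"poly"`.
#' @param gamma RBF width / polynomial scale; default `1/d` on z-scored
#'   features (i.e. 1 over feature count times unit variance).
#' @param degree polynomial degree.
#' @param n_components components retained.
#' @return a `kpca_model`.
#' @export
kpca_fit <- function(x, kernel = c("rbf", "linear", "poly"), gamma = NULL,
                     degree = 3L, n_components = 5L) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need >= 2 samples", call. = FALSE)
  if (n_components < 1) stop("n_components must be >= 1", call. = FALSE)
  if (n_components > n)
    stop("n_components cannot exceed the sample count", call. = FALSE)
  centre <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- sweep(sweep(x, 2, centre), 2, scale_, "/")
  if (is.null(gamma)) gamma <- 1 / ncol(x)

  k <- kernel_matrix(xs, xs, kernel, gamma, degree)
  ones <- matrix(1 / n, n, n)
  kc <- k - ones %*% k - k %*% ones + ones %*% k %*% ones
  eig <- eigen(kc, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  pos <- lambda > max(lambda) * 1e-12
  n_use <- min(n_components, sum(pos))
  alpha <- eig$vectors[, seq_len(n_use), drop = FALSE]
  alpha <- sweep(alpha, 2, sqrt(lambda[seq_len(n_use)]), "/")
  structure(list(kernel = kernel, gamma = gamma, degree = degree,
                 centre = centre, scale = scale_, x_train = xs,
                 k_train = k, alpha = alpha,
                 eigenvalues = lambda[seq_len(n_use)],
                 n_components = as.integer(n_components)),
            class = "kpca_model")
}

kernel_matrix <- function(a, b, kernel, gamma, degree) {
  switch(kernel,
    linear = a %*% t(b),
    poly = (gamma * a %*% t(b) + 1)^degree,
    rbf = {
      an <- rowSums(a^2); bn <- rowSums(b^2)
      d2 <- outer(an, bn, "+") - 2 * a %*% t(b)
      exp(-gamma * pmax(d2, 0))
    })
}

#' Project data through a fitted KPCA model
#'
#' Out-of-sample projection with the training standardisation and kernel
#' centring statistics; transforming the training data reproduces the
#' fit-time scores.
#'
#' @param model a [kpca_fit()] result.
#' @param x matrix to project (samples x features).
#' @return matrix with `min(n_components, rank)` columns; zero-row input
#'   gives a zero-row matrix.
#' @export
kpca_transform <- function(model, x) {
  stopifnot(inherits(model, "kpca_model"))
  x <- as.matrix(x)
  if (nrow(x) == 0) return(matrix(0, 0, ncol(model$alpha)))
  xs <- sweep(sweep(x, 2, model$centre), 2, model$scale, "/")
  n <- nrow(model$x_train)
  k <- kernel_matrix(xs, model$x_train, model$kernel, model$gamma,
                     model$degree)
  row_mean_train <- colMeans(model$k_train) # mean over training rows
  k_c <- sweep(k, 2, row_mean_train) -
    rowMeans(k) + mean(model$k_train)
  k_c %*% model$alpha
}

#' @export
print.kpca_model <- function(x, ...) {
  cat(sprintf("<kpca_model> kernel=%s gamma=%g components=%d (n=%d)\n",
              x$kernel, x$gamma, ncol(x$alpha), nrow(x$x_train)))
  invisible(x)
}

#' Component-count presets
#'
#' @param preset `"S1"`..`"S6"`.
#' @return integer component count (5, 7, 10, 12, 15, 17).
#' @export
component_preset <- function(preset) {
  presets <- c(S1 = 5L, S2 = 7L, S3 = 10L, S4 = 12L, S5 = 15L, S6 = 17L)
  if (!preset %in% names(presets))
    stop("unknown preset; use S1..S6", call. = FALSE)
  presets[[preset]]
}

#' Persist / restore a KPCA model as JSON
#'
#' @param model a `kpca_model`.
#' @param path JSON file path.
#' @export
save_kpca <- function(model, path) {
  obj <- model
  obj$x_train <- as.matrix(obj$x_train)
  jsonlite::write_json(
    lapply(unclass(obj), function(e) if (is.matrix(e)) list(dim = dim(e),
      data = as.numeric(e)) else e),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_kpca
#' @export
load_kpca <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in names(raw)) {
    e <- raw[[nm]]
    if (is.list(e) && !is.null(e$dim))
      raw[[nm]] <- matrix(e$data, e$dim[1], e$dim[2])
  }
  raw$centre <- as.numeric(raw$centre)
  raw$scale <- as.numeric(raw$scale)
  raw$eigenvalues <- as.numeric(raw$eigenvalues)
  structure(raw, class = "kpca_model")
}

#' Fit the full hybrid feature selection and reduction stage
#'
#' Rank fusion (seven rankers, mean rank, top-k selection) followed by
#' kernel PCA on the selected columns.
#'
#' @param x samples x features matrix.
#' @param y class labels.
#' @param k_top features kept after mean-rank fusion.
#' @param n_components KPCA components.
#' @param kernel KPCA kernel.
#' @return an `hfsr_model` with `ranks` (rank_table), `selected` (names)
#'   and `kpca`.
#' @export
hfsr_fit <- function(x, y, k_top = 24L, n_components = 5L, kernel = "rbf") {
  rt <- rank_table(x, y)
  sel <- select_top(rt, k_top)
  kp <- kpca_fit(x[, sel, drop = FALSE], kernel = kernel,
                 n_components = n_components)
  structure(list(ranks = rt, selected = sel, kpca = kp),
            class = "hfsr_model")
}

#' @rdname hfsr_fit
#' @param model an `hfsr_model`.
#' @export
hfsr_transform <- function(model, x) {
  kpca_transform(model$kpca, x[, model$selected, drop = FALSE])
}
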