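RANKER_METHODS <- c("TT", "KLD", "BD", "ROC", "MWT", "MRMR", "RRF")

#' Univariate / multivariate feature scores
#'
#' Raw discriminativeness scores (higher = better) for a two-class
#' problem. Methods: `TT` absolute Welch t statistic; `KLD` symmetric
#' Kullback-Leibler divergence between per-class univariate Gaussian fits;
#' `BD` univariate Gaussian Bhattacharyya distance; `ROC` |AUC - 0.5| from
#' the rank-sum estimator; `MWT` absolute z of the Mann-Whitney U
#' statistic (tie-corrected); `MRMR` greedy minimum-redundancy
#' maximum-relevance selection-order score (mutual information on 10
#' equal-frequency bins, relevance minus mean redundancy; the first
#' feature selected receives the largest score); `RRF` ReliefF weights
#' (k = 10 neighbours, every sample used).
#'
#' Zero-variance features score 0 with a warning.
#'
#' @param x numeric matrix (samples x features).
#' @param y class labels (2 levels).
#' @param method one of `"TT", "KLD", "BD", "ROC", "MWT", "MRMR", "RRF"`.
#' @return numeric score per feature.
#' @export
score_features <- function(x, y, method = RANKER_METHODS) {
  method <- match.arg(method)
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("exactly two classes required", call. = FALSE)
  if (min(table(y)) < 3) stop("need >= 3 samples per class", call. = FALSE)
  g1 <- x[y == levels(y)[1], , drop = FALSE]
  g2 <- x[y == levels(y)[2], , drop = FALSE]
  const <- apply(x, 2, function(v) stats::var(v) == 0)
  if (any(const))
    warning(sum(const), " zero-variance feature(s) scored 0", call. = FALSE)

  score <- switch(method,
    TT = {
      n1 <- nrow(g1); n2 <- nrow(g2)
      se <- sqrt(apply(g1, 2, stats::var) / n1 + apply(g2, 2, stats::var) / n2)
      abs(colMeans(g1) - colMeans(g2)) / se
    },
    KLD = {
      v1 <- pmax(apply(g1, 2, stats::var), 1e-24)
      v2 <- pmax(apply(g2, 2, stats::var), 1e-24)
      dm2 <- (colMeans(g1) - colMeans(g2))^2
      0.5 * (v1 / v2 + v2 / v1) - 1 + 0.5 * dm2 * (1 / v1 + 1 / v2)
    },
    BD = {
      v1 <- pmax(apply(g1, 2, stats::var), 1e-24)
      v2 <- pmax(apply(g2, 2, stats::var), 1e-24)
      dm2 <- (colMeans(g1) - colMeans(g2))^2
      0.25 * dm2 / (v1 + v2) + 0.5 * log((v1 + v2) / (2 * sqrt(v1 * v2)))
    },
    ROC = abs(apply(x, 2, function(v) auc_ranksum(v, y)) - 0.5),
    MWT = apply(x, 2, function(v) abs(mw_z(v, y))),
    MRMR = mrmr_scores(x, y),
    RRF = relieff_weights(x, y)
  )
  score[const] <- 0
  score[!is.finite(score)] <- 0
  unname(score)
}

# AUC for class levels(y)[2] as "positive", via the rank-sum identity.
auc_ranksum <- function(v, y) {
  r <- rank(v)
  pos <- y == levels(y)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Tie-corrected normal z of the Mann-Whitney U statistic.
mw_z <- function(v, y) {
  pos <- y == levels(y)[2]
  n1 <- sum(pos); n0 <- sum(!pos); n <- n1 + n0
  r <- rank(v)
  u <- sum(r[pos]) - n1 * (n1 + 1) / 2
  ties <- table(v)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  s2 <- n1 * n0 / 12 * (n + 1 - tie_term)
  if (s2 <= 0) return(0)
  (u - n1 * n0 / 2) / sqrt(s2)
}

# Equal-frequency discretisation into up to `bins` levels.
discretize_ef <- function(v, bins = 10L) {
  qs <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1L),
                               type = 1))
  if (length(qs) < 2) return(rep(1L, length(v)))
  as.integer(cut(v, qs, include.lowest = TRUE))
}

mutual_information <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

# Greedy MID ordering; score = F - selection position + 1.
mrmr_scores <- function(x, y, bins = 10L) {
  f <- ncol(x)
  disc <- lapply(seq_len(f), function(j) discretize_ef(x[, j], bins))
  rel <- vapply(disc, mutual_information, numeric(1), b = y)
  selected <- integer(0)
  remaining <- seq_len(f)
  red_sum <- numeric(f)
  order_out <- integer(f)
  for (step in seq_len(f)) {
    crit <- if (length(selected) == 0) rel[remaining] else
      rel[remaining] - red_sum[remaining] / length(selected)
    pick <- remaining[which.max(crit)]
    order_out[step] <- pick
    remaining <- setdiff(remaining, pick)
    if (length(remaining))
      red_sum[remaining] <- red_sum[remaining] +
        vapply(remaining, function(j) mutual_information(disc[[j]], disc[[pick]]),
               numeric(1))
    selected <- c(selected, pick)
  }
  score <- numeric(f)
  score[order_out] <- seq(f, 1)
  score
}

# ReliefF with k nearest hits/misses per instance, every instance used.
# Features are range-normalised for both the distance and the diff term.
relieff_weights <- function(x, y, k = 10L) {
  n <- nrow(x); f <- ncol(x)
  rng <- apply(x, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  xs <- sweep(x, 2, apply(x, 2, min), "-")
  xs <- sweep(xs, 2, rng, "/")
  d <- as.matrix(stats::dist(xs, method = "manhattan"))
  w <- numeric(f)
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- setdiff(same, i)
    diff_cls <- which(y != y[i])
    hits <- same[order(d[i, same])][seq_len(min(k, length(same)))]
    misses <- diff_cls[order(d[i, diff_cls])][seq_len(min(k, length(diff_cls)))]
    diff_hit <- abs(sweep(xs[hits, , drop = FALSE], 2, xs[i, ], "-"))
    diff_miss <- abs(sweep(xs[misses, , drop = FALSE], 2, xs[i, ], "-"))
    w <- w + colMeans(diff_miss) - colMeans(diff_hit)
  }
  w / n
}

#' Convert raw scores to integer ranks
#'
#' The best (largest) score receives rank F; ties share their mean
#' position, rounded half-up, so the output stays integer.
#'
#' @param scores numeric vector.
#' @return integer ranks in 1..F.
#' @export
scores_to_ranks <- function(scores) {
  r <- rank(scores, ties.method = "average")
  as.integer(floor(r + 0.5))
}

#' Per-method rank table for a feature matrix
#'
#' Runs all seven rankers and converts scores to ranks (larger = more
#' discriminative, matching the convention that selected features carry
#' large entries).
#'
#' @param x samples x features matrix (column names = feature names).
#' @param y class labels.
#' @return a `rank_table`: data frame with `feature`, one integer column
#'   per method, and `MR` (mean rank, 2 decimals).
#' @export
rank_table <- function(x, y) {
  const <- apply(x, 2, function(v) stats::var(v) == 0)
  if (any(const))
    warning(sum(const), " zero-variance feature(s) ranked last",
            call. = FALSE)
  ranks <- vapply(RANKER_METHODS,
                  function(m) scores_to_ranks(
                    suppressWarnings(score_features(x, y, m))),
                  integer(ncol(x)))
  out <- data.frame(feature = colnames(x) %||null% paste0("f", seq_len(ncol(x))),
                    ranks, check.names = FALSE, stringsAsFactors = FALSE)
  out$MR <- mean_rank(as.matrix(out[, RANKER_METHODS]))
  class(out) <- c("rank_table", "data.frame")
  out
}

`%||null%` <- function(a, b) if (is.null(a)) b else a

#' Mean rank across ranking methods
#'
#' Arithmetic mean of the per-method ranks, reported to 2 decimals.
#'
#' @param ranks matrix (features x methods) or a `rank_table`.
#' @return numeric mean rank per feature.
#' @export
mean_rank <- function(ranks) {
  if (inherits(ranks, "rank_table"))
    ranks <- as.matrix(ranks[, RANKER_METHODS])
  round(rowMeans(ranks), 2)
}

#' Select the top-k features by mean rank
#'
#' @param mr mean-rank vector (names = feature names) or a `rank_table`.
#' @param k number of features to keep (default 24).
#' @return character names (or indices when unnamed) of the selected
#'   features; ties broken by registry (input) order.
#' @export
select_top <- function(mr, k = 24L) {
  if (inherits(mr, "rank_table")) {
    nm <- mr$feature
    mr <- stats::setNames(mr$MR, nm)
  }
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  k <- min(k, length(mr))
  ord <- order(-mr, seq_along(mr)) # ties: earlier registry position wins
  sel <- ord[seq_len(k)]
  if (!is.null(names(mr))) names(mr)[sel] else sel
}

#' Export a rank table as CSV
#'
#' Columns `Feature, TT, KLD, BD, ROC, MWT, MRMR, RRF, MR`, sorted by
#' decreasing mean rank.
#'
#' @param rt a [rank_table()].
#' @param path CSV path.
#' @export
write_rank_table <- function(rt, path) {
  out <- rt[order(-rt$MR), c("feature", RANKER_METHODS, "MR")]
  names(out)[1] <- "Feature"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
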