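# two-class toy with one informative and several noise features
toy_matrix <- function(n = 20, d = 5, shift = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n * d), 2 * n, d,
              dimnames = list(NULL, paste0("f", seq_len(d))))
  y <- factor(rep(c("normal", "hypertension"), each = n),
              levels = c("normal", "hypertension"))
  x[y == "hypertension", 1] <- x[y == "hypertension", 1] + shift
  list(x = x, y = y)
}

test_that("uninformative features score near zero, separated ones top out", {
  tm <- toy_matrix(n = 30)
  roc <- score_features(tm$x, tm$y, "ROC")
  tt <- score_features(tm$x, tm$y, "TT")
  expect_gt(roc[1], max(roc[-1]))
  expect_gt(tt[1], max(tt[-1]))
  expect_lt(mean(roc[-1]), 0.2)
  # a perfectly separated feature reaches the 0.5 ROC ceiling
  tm$x[, 2] <- ifelse(tm$y == "hypertension", 10, 0) + rnorm(60, 0, 0.1)
  expect_equal(score_features(tm$x, tm$y, "ROC")[2], 0.5)
})

test_that("every ranking method prefers the informative feature", {
  tm <- toy_matrix(n = 25, shift = 4, seed = 3)
  for (m in c("TT", "KLD", "BD", "ROC", "MWT", "MRMR", "RRF")) {
    sc <- score_features(tm$x, tm$y, m)
    expect_identical(which.max(sc), 1L)
  }
})

test_that("single-class input and zero-variance features are handled", {
  tm <- toy_matrix()
  expect_error(score_features(tm$x, rep("a", nrow(tm$x)), "TT"), "two classes")
  tm$x[, 3] <- 1
  expect_warning(sc <- score_features(tm$x, tm$y, "TT"), "zero-variance")
  expect_equal(sc[3], 0)
})

test_that("ROC scores agree with exhaustive pairwise AUC on tiny sets", {
  set.seed(7)
  for (rep in 1:20) {
    n1 <- sample(3:6, 1); n0 <- sample(3:6, 1)
    v <- round(rnorm(n1 + n0), 1) # ties likely
    y <- factor(c(rep("normal", n0), rep("hypertension", n1)),
                levels = c("normal", "hypertension"))
    pos <- v[y == "hypertension"]; neg <- v[y == "normal"]
    auc <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b))) # brute-force pair counting
    got <- score_features(matrix(v, ncol = 1), y, "ROC")
    expect_equal(got, abs(auc - 0.5), tolerance = 1e-12)
  }
})

test_that("scores convert to integer ranks with mid-rank ties", {
  expect_identical(scores_to_ranks(c(0.1, 0.9, 0.5)), c(1L, 3L, 2L))
  expect_identical(scores_to_ranks(rep(1, 5)), rep(3L, 5L))
  expect_identical(scores_to_ranks(c(2, 2, 1, 3)),
                   c(3L, 3L, 1L, 4L)) # mean position 2.5 rounds half-up
  s <- c(0.2, 0.8, 0.4, 0.9)
  expect_identical(scores_to_ranks(s), scores_to_ranks(exp(s)))
})

test_that("mean rank reproduces the published worked examples", {
  # Root Sum of Squares row: ranks from TT, KLD, BD, ROC, MWT, MRMR, RRF
  expect_equal(mean_rank(matrix(c(53, 49, 52, 99, 18, 58, 72), 1)), 57.29)
  # 3rd LTP coefficient row of the wavelet-route table
  expect_equal(mean_rank(matrix(c(12, 93, 93, 83, 32, 102, 98), 1)), 73.29)
  # top rows of the EMD-route table
  expect_equal(mean_rank(matrix(c(100, 98, 98, 26, 96, 97, 55), 1)), 81.43)
  expect_equal(mean_rank(matrix(c(89, 96, 76, 73, 85, 52, 96), 1)), 81.00)
  expect_equal(mean_rank(matrix(rep(7, 7), 1)), 7)
})

test_that("rank tables conserve the rank sum", {
  tm <- toy_matrix(n = 15, d = 8, seed = 5)
  rt <- rank_table(tm$x, tm$y)
  f <- ncol(tm$x)
  for (m in c("TT", "KLD", "BD", "ROC", "MWT", "MRMR", "RRF"))
    expect_true(all(rt[[m]] %in% 1:f))
  expect_equal(mean(rt$MR), (f + 1) / 2, tolerance = 0.01)
  expect_true(all(rt$MR >= 1 & rt$MR <= f))
})

test_that("top-k selection follows mean rank with registry-order ties", {
  mr <- c(a = 10, b = 30, c = 20, d = 30)
  expect_identical(select_top(mr, 2), c("b", "d"))
  expect_identical(select_top(mr, 4), c("b", "d", "c", "a"))
  expect_error(select_top(mr, 0), "k")
})

test_that("rank fusion rejects a feature championed by a single method", {
  # adversarial table: feature 1 gets the top rank from one method but
  # sits at the median for the other six; 30 decoys hold solid ranks
  f <- 102
  set.seed(11)
  ranks <- matrix(0L, f, 7)
  for (m in 1:7) ranks[, m] <- sample.int(f)
  ranks[1, ] <- c(f, rep(floor(f / 2), 6))
  solid <- 2:31
  ranks[solid, ] <- matrix(rep(seq(f, f - 29), 7), ncol = 7)
  mr <- mean_rank(ranks)
  names(mr) <- paste0("f", seq_len(f))
  expect_false("f1" %in% select_top(mr, 24))
})

test_that("linear-kernel KPCA reproduces PCA scores up to sign", {
  set.seed(13)
  for (rep in 1:5) {
    x <- matrix(rnorm(20 * 6), 20, 6)
    km <- kpca_fit(x, kernel = "linear", n_components = 3)
    scores_k <- kpca_transform(km, x)
    xs <- scale(x)
    scores_p <- stats::prcomp(xs, center = FALSE, scale. = FALSE)$x[, 1:3]
    # kpca scores are unit-scaled; compare after column normalisation
    norm_cols <- function(m) sweep(m, 2, sqrt(colSums(m^2)), "/")
    a <- norm_cols(scores_k); b <- norm_cols(scores_p)
    for (j in 1:3) expect_lt(min(max(abs(a[, j] - b[, j])),
                                 max(abs(a[, j] + b[, j]))), 1e-6)
  }
})

test_that("rbf KPCA matches a brute-force centred-kernel eigensolve", {
  set.seed(17)
  x <- matrix(rnorm(5 * 3), 5, 3)
  gamma <- 0.3
  km <- kpca_fit(x, kernel = "rbf", gamma = gamma, n_components = 2)
  got <- kpca_transform(km, x)
  # independent dense computation on the explicitly standardised data
  xs <- scale(x)
  d2 <- as.matrix(stats::dist(xs))^2
  k <- exp(-gamma * d2)
  n <- 5; ones <- matrix(1 / n, n, n)
  kc <- k - ones %*% k - k %*% ones + ones %*% k %*% ones
  eig <- eigen(kc, symmetric = TRUE)
  expected <- kc %*% sweep(eig$vectors[, 1:2], 2, sqrt(eig$values[1:2]), "/")
  for (j in 1:2) expect_lt(min(max(abs(got[, j] - expected[, j])),
                               max(abs(got[, j] + expected[, j]))), 1e-8)
})

test_that("KPCA eigenvalues are non-negative and sorted", {
  set.seed(19)
  x <- matrix(rnorm(30 * 4), 30, 4)
  km <- kpca_fit(x, n_components = 10)
  expect_true(all(km$eigenvalues >= -1e-10))
  expect_true(all(diff(km$eigenvalues) <= 1e-10))
})

test_that("KPCA agrees with an established implementation", {
  skip_if_not_installed("kernlab")
  set.seed(23)
  x <- matrix(rnorm(25 * 4), 25, 4)
  gamma <- 0.25
  km <- kpca_fit(x, kernel = "rbf", gamma = gamma, n_components = 3)
  got <- kpca_transform(km, x)
  ref <- kernlab::rotated(kernlab::kpca(scale(x),
                                        kernel = "rbfdot",
                                        kpar = list(sigma = gamma),
                                        features = 3))
  # same subspace: compare column spans via correlations
  for (j in 1:3)
    expect_gt(max(abs(stats::cor(got[, j], ref))), 0.999)
})

test_that("transform is consistent, handles duplicates and empty input", {
  set.seed(29)
  x <- matrix(rnorm(12 * 3), 12, 3)
  x[2, ] <- x[1, ]
  km <- kpca_fit(x, n_components = 4)
  sc <- kpca_transform(km, x)
  expect_equal(sc[1, ], sc[2, ], tolerance = 1e-10)
  expect_equal(kpca_transform(km, x), sc, tolerance = 1e-8)
  expect_identical(dim(kpca_transform(km, x[0, , drop = FALSE])), c(0L, 4L))
  expect_error(kpca_fit(x, n_components = 13), "sample count")
})

test_that("component presets map S1..S6 to the published counts", {
  expect_identical(vapply(paste0("S", 1:6), component_preset, integer(1),
                          USE.NAMES = FALSE),
                   c(5L, 7L, 10L, 12L, 15L, 17L))
  expect_error(component_preset("S7"), "preset")
})

test_that("KPCA models survive a JSON round trip", {
  set.seed(31)
  x <- matrix(rnorm(10 * 3), 10, 3)
  km <- kpca_fit(x, n_components = 2)
  path <- tempfile(fileext = ".json")
  save_kpca(km, path)
  km2 <- load_kpca(path)
  expect_equal(kpca_transform(km2, x), kpca_transform(km, x),
               tolerance = 1e-10)
})

test_that("hfsr_fit selects k features and projects to the target dim", {
  tm <- toy_matrix(n = 25, d = 10, seed = 37)
  hm <- hfsr_fit(tm$x, tm$y, k_top = 4, n_components = 2)
  expect_length(hm$selected, 4L)
  expect_true("f1" %in% hm$selected) # the informative feature survives
  z <- hfsr_transform(hm, tm$x)
  expect_identical(dim(z), c(50L, 2L))
})
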