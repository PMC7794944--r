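test_that("weighted votes decide exactly as the hand computation", {
  # neighbours at distances 1, 2, 3 with labels A, B, B:
  # weights 1, 1/4, 1/9 -> A wins 1 > 0.361
  x <- matrix(c(0, 1, 2, 3), ncol = 1)
  y <- factor(c("A", "B", "B", "B"))
  m <- knnw_fit(x, y, k = 3, standardize = FALSE)
  expect_identical(as.character(knnw_predict(m, matrix(1, 1, 1))), "B")
  # query at -1: distances 1,2,3,4 -> neighbours x1(A),x2(B),x3(B)
  expect_identical(as.character(knnw_predict(m, matrix(-1, 1, 1))), "A")
})

test_that("k = 1 reduces to the nearest-neighbour rule", {
  set.seed(1)
  x <- matrix(rnorm(40), 20, 2)
  y <- factor(rep(c("A", "B"), 10))
  m1 <- knnw_fit(x, y, k = 1)
  q <- matrix(rnorm(10), 5, 2)
  d <- as.matrix(stats::dist(rbind(scale(x), scale(q,
    center = colMeans(x), scale = apply(x, 2, sd)))))[21:25, 1:20]
  expect_identical(knnw_predict(m1, q),
                   factor(y[apply(d, 1, which.min)], levels = levels(y)))
})

test_that("a query on a training point inherits its class", {
  set.seed(2)
  x <- matrix(rnorm(30), 15, 2)
  y <- factor(c(rep("A", 7), rep("B", 8)))
  m <- knnw_fit(x, y, k = 5)
  expect_identical(as.character(knnw_predict(m, x[3, , drop = FALSE])), "A")
  expect_identical(as.character(knnw_predict(m, x[12, , drop = FALSE])), "B")
})

test_that("training order does not affect predictions", {
  set.seed(3)
  x <- matrix(rnorm(60), 30, 2)
  y <- factor(rep(c("A", "B"), 15))
  q <- matrix(rnorm(20), 10, 2)
  m <- knnw_fit(x, y, k = 7)
  perm <- sample(30)
  m2 <- knnw_fit(x[perm, ], y[perm], k = 7)
  expect_identical(knnw_predict(m, q), knnw_predict(m2, q))
})

test_that("predictions match a brute-force weighted vote on fuzz sets", {
  set.seed(4)
  for (rep in 1:10) {
    x <- matrix(rnorm(40), 20, 2)
    y <- factor(sample(c("A", "B"), 20, replace = TRUE,
                       prob = c(0.5, 0.5)))
    if (length(unique(y)) < 2) next
    k <- sample(1:5, 1)
    m <- knnw_fit(x, y, k = k, standardize = FALSE)
    q <- matrix(rnorm(6), 3, 2)
    pred <- knnw_predict(m, q)
    for (i in 1:3) {
      d <- sqrt(colSums((t(x) - q[i, ])^2))
      nb <- order(d)[seq_len(k)]
      w <- 1 / d[nb]^2
      sums <- tapply(w, y[nb], sum, default = 0)
      expect_identical(as.character(pred[i]),
                       names(sums)[which.max(sums)])
    }
  }
})

test_that("k outside 1..N is rejected", {
  x <- matrix(rnorm(10), 5, 2)
  y <- factor(c("A", "A", "A", "B", "B"))
  expect_error(knnw_fit(x, y, k = 6), "k must")
  expect_error(knnw_fit(x, y, k = 0), "k must")
})

test_that("the roster resolves every comparison-table name", {
  expect_setequal(roster_names(),
                  c("DT", "LD", "LR", "NBG", "NBK", "SVM-L", "SVM-Q",
                    "SVM-C", "SVM-FG", "SVM-MG", "KNN-F", "KNN-M",
                    "KNN-Cos", "KNN-C", "KNN-W", "Eboost", "EBT", "ESD",
                    "ESKNN"))
  for (nm in roster_names()) expect_identical(baseline_roster(nm)$name, nm)
  expect_error(baseline_roster("nope"), "unknown")
})

test_that("every roster member separates two well-separated blobs", {
  blobs <- two_blobs(n = 50, d = 3, sep = 8, seed = 5)
  idx_train <- c(1:40, 51:90)
  idx_test <- setdiff(1:100, idx_train)
  for (nm in roster_names()) {
    clf <- baseline_roster(nm)
    set.seed(42)
    model <- clf$fit(blobs$x[idx_train, ], blobs$y[idx_train])
    pred <- clf$predict(model, blobs$x[idx_test, ])
    expect_identical(as.character(pred), as.character(blobs$y[idx_test]),
                     label = nm)
  }
})

test_that("cross-validation pools clean confusion counts", {
  blobs <- two_blobs(n = 30, d = 3, sep = 8, seed = 6)
  r <- cross_validate(blobs$x, blobs$y, classifier = "KNN-W", folds = 5,
                      seed = 1, hfsr = FALSE)
  expect_equal(unname(r$metrics["accuracy"]), 1)
  expect_equal(unname(r$metrics["error"]), 0)
  cm <- r$confusion
  expect_equal(sum(cm), 60)
  expect_equal(unname(cm["TP"] + cm["FN"]), 30) # total positives
  expect_equal(nrow(r$per_fold), 5L)
})

test_that("reports are deterministic in data, seed and config", {
  blobs <- two_blobs(n = 20, d = 4, sep = 2, seed = 7)
  r1 <- cross_validate(blobs$x, blobs$y, folds = 4, seed = 9, hfsr = FALSE)
  r2 <- cross_validate(blobs$x, blobs$y, folds = 4, seed = 9, hfsr = FALSE)
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$per_fold, r2$per_fold)
})

test_that("label permutation drives accuracy to chance", {
  set.seed(8)
  x <- matrix(rnorm(60 * 4), 60, 4)
  accs <- replicate(20, {
    y <- factor(sample(rep(c("normal", "hypertension"), 30)),
                levels = c("normal", "hypertension"))
    cross_validate(x, y, classifier = "KNN-W", folds = 5, seed = 1,
                   hfsr = FALSE)$metrics["accuracy"]
  })
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("in-fold selection does not leak labels on pure noise", {
  set.seed(9)
  x <- matrix(rnorm(40 * 120), 40, 120,
              dimnames = list(NULL, paste0("f", 1:120)))
  y <- factor(rep(c("normal", "hypertension"), each = 20),
              levels = c("normal", "hypertension"))
  r <- cross_validate(x, y, classifier = "KNN-W", folds = 4, seed = 2,
                      hfsr = TRUE, k_top = 24, n_components = 5)
  expect_lt(abs(unname(r$metrics["accuracy"]) - 0.5), 0.25)
})

test_that("holdout evaluation splits by the requested fraction", {
  blobs <- two_blobs(n = 40, d = 3, sep = 8, seed = 10)
  r <- cross_validate(blobs$x, blobs$y, classifier = "KNN-W", seed = 3,
                      hfsr = FALSE, holdout = 0.25)
  expect_equal(sum(r$confusion), 20) # 25% of 80
  expect_equal(unname(r$metrics["accuracy"]), 1)
})

test_that("configuration errors are caught before any fold runs", {
  blobs <- two_blobs(n = 5, d = 2, sep = 8, seed = 11)
  expect_error(cross_validate(blobs$x, blobs$y, folds = 6, hfsr = FALSE),
               "at least")
  expect_error(cross_validate(blobs$x, blobs$y, folds = 1, hfsr = FALSE),
               "folds")
  expect_error(cross_validate(blobs$x, rep("a", 10), hfsr = FALSE),
               "two classes")
})

test_that("sensitivity counts the hypertension class as positive", {
  truth <- c("hypertension", "hypertension", "normal", "normal")
  pred <- c("hypertension", "normal", "normal", "normal")
  cm <- ehds:::confusion_counts(truth, pred)
  expect_equal(unname(cm), c(1L, 1L, 0L, 2L)) # TP FN FP TN
  m <- ehds:::report_metrics(cm)
  expect_equal(unname(m["sensitivity"]), 0.5)
  expect_equal(unname(m["specificity"]), 1)
  expect_equal(unname(m["error"]), 1 - unname(m["accuracy"]))
})
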