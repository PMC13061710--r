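test_that("cross-entropy matches its closed forms", {
  expect_equal(cross_entropy(1, 1), 0, tolerance = 1e-5)
  expect_equal(cross_entropy(0.5, 1), log(2), tolerance = 1e-9)
  # smoothing makes a perfect prediction strictly positive
  expect_gt(cross_entropy(1, 1, label_smoothing = 0.1), 0)
  # smoothed target form: t = (1-s)y + s/2
  s <- 0.2; p <- 0.7; t <- (1 - s) * 1 + s / 2
  expect_equal(cross_entropy(p, 1, label_smoothing = s),
               -(t * log(p) + (1 - t) * log(1 - p)), tolerance = 1e-9)
  # class weights multiply per-sample losses
  expect_equal(cross_entropy(c(0.5, 0.5), c(0, 1), class_weights = c(2, 0)),
               log(2))
})

test_that("inverse-frequency class weights are normalized to mean 1", {
  w <- class_weights_from_labels(c(rep(0, 75), rep(1, 25)))
  expect_equal(mean(w), 1)
  expect_equal(w[2] / w[1], 3)
  expect_equal(class_weights_from_labels(rep(1, 3)), c(1, 1))
})

test_that("error map is the absolute difference to the global label", {
  p <- matrix(1, 2, 2)
  expect_equal(error_map(p, 1), matrix(0, 2, 2))
  expect_equal(error_map(matrix(0.3, 2, 2), 0), matrix(0.3, 2, 2))
  expect_equal(error_map(matrix(c(0.2, 0.9), 1, 2), 1),
               matrix(c(0.8, 0.1), 1, 2))
})

test_that("calibration loss hits its closed-form cases", {
  set.seed(1)
  u <- matrix(runif(64), 8, 8)
  expect_equal(as.numeric(ual_loss(u, 2 * u + 0.1)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(ual_loss(u, -u + 1)), 2, tolerance = 1e-12)
  # independent noise: loss near 1
  big_u <- matrix(runif(1e4), 100, 100)
  big_e <- matrix(runif(1e4), 100, 100)
  v <- as.numeric(ual_loss(big_u, big_e))
  expect_gte(v, 0.95); expect_lte(v, 1.05)
  # positive-affine invariance in pearson mode
  expect_equal(as.numeric(ual_loss(3 * u + 2, 2 * u + 0.1)), 0,
               tolerance = 1e-12)
  # zero-variance input: neutral value, flagged
  flat <- matrix(1, 8, 8)
  out <- ual_loss(flat, u)
  expect_equal(as.numeric(out), 1)
  expect_true(attr(out, "degenerate"))
  expect_error(ual_loss(u, matrix(0, 2, 2)), "shape")
})

test_that("spearman and mse variants behave sanely", {
  set.seed(2)
  u <- matrix(runif(64), 8, 8)
  expect_equal(as.numeric(ual_loss(u, u^3, metric = "spearman")), 0,
               tolerance = 1e-12)    # monotone map: perfect rank corr
  expect_equal(as.numeric(ual_loss(u, u, metric = "mse")), 0,
               tolerance = 1e-12)
  # mse is invariant to positive affine maps through the normalization
  expect_equal(as.numeric(ual_loss(5 * u + 1, u, metric = "mse")), 0,
               tolerance = 1e-12)
})

test_that("total loss is the weighted sum", {
  lb <- total_loss(1, 1, gamma = 0.1)
  expect_equal(lb$total, 1.1)
  expect_equal(total_loss(0.7, 5, gamma = 0)$total, 0.7)
  expect_equal(lb$total, lb$cel + lb$gamma * lb$ual)
})

test_that("confusion counts and metrics match direct arithmetic", {
  pred <- c(rep(1, 55), rep(0, 45))
  truth <- c(rep(1, 50), rep(0, 5), rep(1, 5), rep(0, 40))
  ct <- confusion(pred, truth)
  expect_equal(ct, list(TP = 50, TN = 40, FP = 5, FN = 5))
  expect_equal(as.numeric(accuracy(ct)), 0.9)
  expect_equal(as.numeric(precision(ct)), 10 / 11)
  expect_equal(as.numeric(recall(ct)), 10 / 11)
  expect_equal(as.numeric(f1_score(ct)), 10 / 11)
  # all correct
  ct2 <- confusion(truth, truth)
  expect_equal(vapply(list(accuracy, precision, recall, f1_score),
                      function(f) as.numeric(f(ct2)), numeric(1)),
               rep(1, 4))
  # degenerate denominator: flagged zero, not an exception
  ct3 <- confusion(rep(0, 10), rep(1, 10))
  expect_equal(as.numeric(precision(ct3)), 0)
  expect_true(attr(precision(ct3), "flagged"))
  expect_error(confusion(integer(0), integer(0)), "empty")
})

test_that("f1 is always the harmonic mean of precision and recall", {
  set.seed(3)
  for (r in 1:10) {
    pred <- rbinom(50, 1, 0.5); truth <- rbinom(50, 1, 0.4)
    ct <- confusion(pred, truth)
    p <- as.numeric(precision(ct)); rc <- as.numeric(recall(ct))
    if (p + rc > 0) {
      expect_equal(as.numeric(f1_score(ct)), 2 * p * rc / (p + rc))
    }
  }
})

test_that("AUC is the normalized rank statistic", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_roc(rep(0.5, 10), rep(0:1, 5)), 0.5)
  expect_error(auc_roc(runif(5), rep(1, 5)), "both classes")
  set.seed(4)
  for (r in 1:10) {
    sc <- rnorm(30); lb <- rbinom(30, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(auc_roc(sc, lb), auc_ref(sc, lb), tolerance = 1e-12)
  }
  # labels independent of scores: AUC near 0.5 at n = 1e4
  sc <- rnorm(1e4); lb <- rbinom(1e4, 1, 0.4)
  a <- auc_roc(sc, lb)
  expect_gte(a, 0.48); expect_lte(a, 0.52)
})
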