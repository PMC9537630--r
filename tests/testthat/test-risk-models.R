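brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + (p > n) + 0.5 * (p == n)
  wins / (length(pos) * length(neg))
}

test_that("AUC obeys its trivial contracts and the worked 4-point example", {
  expect_equal(rocAuc(rep(0.3, 10), rep(0:1, 5))$auc, 0.5)
  expect_equal(rocAuc(1:10, rep(0:1, c(5, 5)))$auc, 1.0)
  expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_error(rocAuc(1:5, rep(1, 5)), "both classes")
})

test_that("rank AUC equals the brute-force pairwise count with ties", {
  set.seed(8)
  for (r in 1:25) {
    n <- sample(6:50, 1)
    labels <- c(0, 1, stats::rbinom(n - 2, 1, 0.4))
    scores <- round(stats::runif(n), sample(1:3, 1))  # rounding makes ties
    expect_equal(rocAuc(scores, labels)$auc, brute_auc(scores, labels))
  }
})

test_that("the ROC staircase is monotone from (0,0) to (1,1)", {
  set.seed(9)
  ra <- rocAuc(stats::runif(60), stats::rbinom(60, 1, 0.3))
  expect_equal(unlist(ra$roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(ra$roc[nrow(ra$roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(ra$roc$fpr) >= 0))
  expect_true(all(diff(ra$roc$tpr) >= 0))
  expect_true(ra$ci_low <= ra$auc && ra$auc <= ra$ci_high)
})

test_that("a predictor-free outcome gives a near-chance AUC", {
  set.seed(5)
  d <- data.frame(poaf = stats::rbinom(200, 1, 0.3),
                  x1 = stats::rnorm(200), x2 = stats::rnorm(200))
  m <- fitLogistic(d, c("x1", "x2"))
  expect_lt(abs(m$auc - 0.5), 0.08)
})

test_that("a deterministic threshold predictor is flagged as separated", {
  set.seed(6)
  x <- stats::rnorm(80)
  d <- data.frame(poaf = as.integer(x > 0), x = x)
  m <- fitLogistic(d, "x")
  expect_equal(m$auc, 1.0)
  expect_true(m$separation)
})

test_that("logistic coefficients are recovered within 3 SE on a known model", {
  set.seed(7)
  n <- 2000
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
  eta <- 0.3 + 0.8 * x1 - 0.5 * x2
  d <- data.frame(poaf = stats::rbinom(n, 1, stats::plogis(eta)),
                  x1 = x1, x2 = x2)
  m <- fitLogistic(d, c("x1", "x2"))
  cf <- m$coefficients
  se <- summary(m$fit)$coefficients[, 2]
  expect_lt(abs(cf$estimate[cf$term == "x1"] - 0.8), 3 * se["x1"])
  expect_lt(abs(cf$estimate[cf$term == "x2"] + 0.5), 3 * se["x2"])
})

test_that("degenerate designs are rejected with informative errors", {
  d <- data.frame(poaf = rep(0:1, 10), x = rep(1, 20), y = stats::rnorm(20))
  expect_error(fitLogistic(d, "x"), "constant predictor")
  d2 <- data.frame(poaf = rep(0:1, 10), a = stats::rnorm(20))
  d2$b <- 2 * d2$a
  expect_error(fitLogistic(d2, c("a", "b")), "singular|collinear")
  expect_error(fitLogistic(data.frame(poaf = rep(1, 10), x = 1:10), "x"),
               "both classes")
})

test_that("splits reproduce the published counts and partition the cohort", {
  labels <- rep(0:1, c(66, 28))
  a <- makeSplits(labels, "A", seed = 2)
  expect_equal(lengths(a[c("train0", "train1", "test0", "test1")]),
               c(train0 = 19, train1 = 19, test0 = 47, test1 = 9))
  expect_length(intersect(a$train, a$test), 0)
  expect_setequal(c(a$train, a$test), 1:94)
  b <- makeSplits(labels, "B", seed = 2)
  expect_equal(lengths(b[c("test0", "test1")]), c(test0 = 9, test1 = 9))
  expect_length(intersect(b$train, b$test), 0)
  expect_identical(makeSplits(labels, "A", seed = 5),
                   makeSplits(labels, "A", seed = 5))
  expect_error(makeSplits(rep(0:1, c(66, 1)), "A", seed = 1), "too small")
})

test_that("well-separated clouds reach near-perfect cross-validated accuracy", {
  set.seed(31)
  x <- rbind(matrix(stats::rnorm(19 * 7, -1.5), ncol = 7),
             matrix(stats::rnorm(19 * 7, 1.5), ncol = 7))
  y <- rep(0:1, each = 19)
  fit <- tuneSvm(x, y, c_grid = 10^(-1:2), gamma_grid = 10^(-2:0), seed = 3)
  expect_gte(fit$cv_accuracy, 0.95)
  ## permuted labels stay near chance
  set.seed(32)
  yp <- sample(y)
  fitp <- tuneSvm(x, yp, c_grid = 10^(-1:2), gamma_grid = 10^(-2:0), seed = 3)
  expect_lt(abs(fitp$cv_accuracy - 0.5), 0.15)
})

test_that("a single grid cell is returned unchanged and k is validated", {
  set.seed(33)
  x <- matrix(stats::rnorm(40 * 3), ncol = 3)
  y <- rep(0:1, each = 20)
  fit <- tuneSvm(x, y, c_grid = 2.5, gamma_grid = 0.7, seed = 1)
  expect_equal(c(fit$C, fit$gamma), c(2.5, 0.7))
  expect_error(tuneSvm(x[1:8, ], y[c(1:4, 21:24)], k = 5, seed = 1),
               "k exceeds")
})

test_that("SVM metrics match the confusion matrix and the all-negative case", {
  set.seed(34)
  xtr <- rbind(matrix(stats::rnorm(19 * 2, -3), ncol = 2),
               matrix(stats::rnorm(19 * 2, 3), ncol = 2))
  ytr <- rep(0:1, each = 19)
  fit <- tuneSvm(xtr, ytr, c_grid = 1, gamma_grid = 0.5, seed = 1)
  ## test points at the class-0 centre are all predicted 0
  xte <- matrix(stats::rnorm(56 * 2, -3, 0.1), ncol = 2)
  yte <- rep(c(0, 1), c(47, 9))
  ev <- evaluateSvm(fit, xte, yte)
  expect_equal(ev$accuracy, 47 / 56)
  expect_equal(ev$sensitivity, 0)
  expect_equal(ev$specificity, 1)
  cm <- ev$confusion
  expect_equal(ev$accuracy, unname((cm["tp"] + cm["tn"]) / sum(cm)))
  expect_equal(ev$specificity, unname(cm["tn"] / (cm["tn"] + cm["fp"])))
  ## perfect prediction on separable test data
  ev2 <- evaluateSvm(fit, xtr, ytr)
  expect_equal(ev2$accuracy, 1)
  expect_equal(ev2$sensitivity, 1)
  expect_equal(ev2$specificity, 1)
})

test_that("the SVM protocol is deterministic given data, grids and seed", {
  feats <- simulatePWaveFeatures(66, 28, seed = 41)
  X <- feats[, c("pmax", "pmin", "pmean", "pstd", "pwd", "pptmean", "pptstd")]
  r1 <- svmProtocol(X, feats$poaf, "B", seed = 9,
                    c_grid = 10^(0:2), gamma_grid = 10^(-2:0))
  r2 <- svmProtocol(X, feats$poaf, "B", seed = 9,
                    c_grid = 10^(0:2), gamma_grid = 10^(-2:0))
  expect_equal(r1$C, r2$C)
  expect_equal(r1$gamma, r2$gamma)
  expect_equal(r1$test$accuracy, r2$test$accuracy)
  expect_identical(r1$split$train, r2$split$train)
})

test_that("adding pure-noise predictors never lowers in-sample AUC", {
  set.seed(55)
  for (r in 1:5) {
    n <- 150
    x <- stats::rnorm(n)
    d <- data.frame(poaf = stats::rbinom(n, 1, stats::plogis(x)), x = x,
                    z1 = stats::rnorm(n), z2 = stats::rnorm(n))
    a1 <- fitLogistic(d, "x")$auc
    a2 <- fitLogistic(d, c("x", "z1", "z2"))$auc
    expect_gte(a2, a1 - 1e-9)
  }
})
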