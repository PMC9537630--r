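test_that("the pooled summary t-test reproduces the published p-values", {
  battery <- list(
    age = list(69, 50.43, 10.59, 31, 55.97, 8.49, 0.012),
    gfr = list(69, 93.00, 13.81, 31, 82.02, 14.94, 0.001),
    urea = list(69, 5.59, 1.32, 31, 6.40, 1.75, 0.012),
    pmax = list(69, 167, 31, 31, 184, 37, 0.018),
    pstd = list(69, 15, 7, 31, 19, 11, 0.031),
    pwd = list(69, 62, 28, 31, 80, 35, 0.008))
  for (nm in names(battery)) {
    v <- battery[[nm]]
    p <- ttestFromSummary(v[[1]], v[[2]], v[[3]], v[[4]], v[[5]], v[[6]])$p
    expect_lt(abs(p - v[[7]]), 0.005)
  }
})

test_that("the published sex 2x2 chi-square p-value is reproduced", {
  sex <- data.frame(sex_male = c(rep(1, 43), rep(0, 26), rep(1, 16), rep(0, 15)),
                    poaf = rep(0:1, c(69, 31)))
  res <- compareGroups(sex, "sex_male", "categorical")
  expect_equal(res$test, "chi2")
  expect_lt(abs(res$p_value - 0.314), 0.005)
})

test_that("rare categorical variables fall back to Fisher's exact test", {
  ## diabetes: 3/69 vs 0/31 in the published table -> expected counts < 5
  dm <- data.frame(dm = c(rep(1, 3), rep(0, 66), rep(0, 31)),
                   poaf = rep(0:1, c(69, 31)))
  res <- compareGroups(dm, "dm", "categorical")
  expect_equal(res$test, "fisher")
  expect_lt(abs(res$p_value - 0.550), 0.005)
})

test_that("identical groups give p = 1 under Fisher's test", {
  d <- data.frame(x = rep(c(0, 1), 20), poaf = rep(0:1, each = 20))
  res <- compareGroups(d, "x", "categorical")
  expect_equal(res$p_value, 1)
})

test_that("a constant-in-both-groups variable returns NA rather than failing", {
  d <- data.frame(x = rep(0, 40), poaf = rep(0:1, each = 20))
  res <- compareGroups(d, "x", "categorical")
  expect_true(is.na(res$p_value))
})

test_that("well-separated continuous groups are detected with high power", {
  set.seed(12)
  d <- data.frame(x = c(stats::rnorm(50, 0, 1), stats::rnorm(50, 2, 1)),
                  poaf = rep(0:1, each = 50))
  res <- compareGroups(d, "x", "normal_continuous")
  expect_equal(res$test, "t")
  expect_lt(res$p_value, 0.001)
  res_w <- compareGroups(d, "x", "skewed_continuous")
  expect_equal(res_w$test, "mann_whitney")
  expect_lt(res_w$p_value, 0.001)
})

test_that("degenerate and unknown inputs are rejected", {
  d <- data.frame(x = rep(1, 20), poaf = rep(0:1, each = 10))
  expect_error(compareGroups(d, "x", "normal_continuous"), "degenerate")
  expect_error(compareGroups(d, "x", "ordinal"), "unknown variable kind")
  expect_error(ttestFromSummary(1, 0, 1, 10, 0, 1), "n >= 2")
  expect_error(ttestFromSummary(10, 0, 0, 10, 0, 0), "not both zero")
})

test_that("summary-statistic and raw-data t-tests agree to 1e-9", {
  set.seed(3)
  for (r in 1:10) {
    x <- stats::rnorm(sample(5:40, 1), mean = stats::runif(1, -2, 2))
    y <- stats::rnorm(sample(5:40, 1), sd = stats::runif(1, 0.5, 2))
    raw <- stats::t.test(x, y, var.equal = TRUE)
    summ <- ttestFromSummary(length(x), mean(x), sd(x),
                             length(y), mean(y), sd(y))
    expect_equal(summ$t, unname(raw$statistic), tolerance = 1e-9)
    expect_equal(summ$p, raw$p.value, tolerance = 1e-9)
  }
})

test_that("swapping group order negates t and preserves p", {
  s1 <- ttestFromSummary(20, 5, 2, 30, 6, 3)
  s2 <- ttestFromSummary(30, 6, 3, 20, 5, 2)
  expect_equal(s1$t, -s2$t)
  expect_equal(s1$p, s2$p)
})

test_that("type-I error of the t path is 5% under the null", {
  set.seed(99)
  nrep <- 10000; n1 <- 20; n2 <- 25
  x <- matrix(stats::rnorm(nrep * n1), nrep)
  y <- matrix(stats::rnorm(nrep * n2), nrep)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  s1 <- sqrt(rowSums((x - m1)^2) / (n1 - 1))
  s2 <- sqrt(rowSums((y - m2)^2) / (n2 - 1))
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(t), n1 + n2 - 2)
  ## spot-check the vectorised battery against the function itself
  one <- ttestFromSummary(n1, m1[1], s1[1], n2, m2[1], s2[1])
  expect_equal(one$p, p[1], tolerance = 1e-12)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
})

test_that("the cohort table runs every published variable without error", {
  cohort <- simulateCohort(cohortSpec(69, 31, seed = 14))
  tab <- cohortStatsTable(cohort)
  expect_equal(nrow(tab), nrow(clinicalReference()))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))
  expect_true(all(tab$test %in% c("t", "mann_whitney", "chi2", "fisher")))
})
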