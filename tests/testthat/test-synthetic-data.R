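test_that("same seed and parameters give bit-identical signal and truth", {
  a <- simulateEcg(beatTemplate(), 10, fs = 500, noise = noiseSpec(), seed = 7)
  b <- simulateEcg(beatTemplate(), 10, fs = 500, noise = noiseSpec(), seed = 7)
  expect_identical(samples(a$signal), samples(b$signal))
  expect_identical(beats(a$truth), beats(b$truth))
  d <- simulateEcg(beatTemplate(), 10, fs = 500, noise = noiseSpec(), seed = 8)
  expect_false(identical(samples(a$signal), samples(d$signal)))
})

test_that("degenerate duration distribution yields constant P durations", {
  rec <- simulateEcg(beatTemplate(p_duration_mean = 120, p_duration_sd = 0),
                     30, noise = noiseSpec(0, 0, 0), seed = 1)
  expect_true(all(beats(rec$truth)$duration_ms == 120))
})

test_that("P durations are truncated at the 40 ms floor", {
  rec <- simulateEcg(beatTemplate(p_duration_mean = 45, p_duration_sd = 30,
                                  p_peak_fraction = 0.5),
                     60, noise = noiseSpec(0, 0, 0), seed = 3)
  expect_true(all(beats(rec$truth)$duration_ms >= 40))
})

test_that("sample mean of simulated durations matches the template", {
  rec <- simulateEcg(beatTemplate(p_duration_mean = 140, p_duration_sd = 20),
                     duration_s = 301, noise = noiseSpec(0, 0, 0), seed = 11)
  d <- beats(rec$truth)$duration_ms
  expect_gte(length(d), 290)
  se <- 20 / sqrt(length(d))
  expect_lt(abs(mean(d) - 140), 3 * se)
})

test_that("simulated durations pass a KS test against the truncated normal", {
  ## >= 1000 beats; truncation at 40 ms is active for this mean/SD
  rec <- simulateEcg(beatTemplate(p_duration_mean = 90, p_duration_sd = 35,
                                  rr_mean = 700, rr_sd = 0,
                                  pr_interval = 160, p_peak_fraction = 0.5),
                     duration_s = 750, fs = 250,
                     noise = noiseSpec(0, 0, 0), seed = 5)
  d <- beats(rec$truth)$duration_ms
  expect_gte(length(d), 1000)
  ks <- suppressWarnings(stats::ks.test(
    d, function(q) PWaveAF:::ptruncnorm_lower(q, 90, 35, 40)))
  expect_gt(ks$p.value, 0.01)
})

test_that("truth fiducials are strictly ordered and non-overlapping", {
  rec <- simulateEcg(beatTemplate(), 60, noise = noiseSpec(), seed = 2)
  tr <- beats(rec$truth)
  expect_true(all(tr$onset_ms < tr$peak_ms))
  expect_true(all(tr$peak_ms < tr$offset_ms))
  expect_true(all(diff(tr$onset_ms) > 0))
  expect_true(all(tr$offset_ms[-nrow(tr)] < tr$onset_ms[-1]))
})

test_that("overlapping-beat configurations warn and truncate", {
  expect_warning(
    rec <- simulateEcg(beatTemplate(p_duration_mean = 200, p_duration_sd = 0,
                                    pr_interval = 280, rr_mean = 520,
                                    rr_sd = 0, t_duration = 200),
                       20, noise = noiseSpec(0, 0, 0), seed = 1),
    "truncated")
  tr <- beats(rec$truth)
  expect_true(all(tr$offset_ms[-nrow(tr)] <= tr$onset_ms[-1] + 1e-9))
})

test_that("argument errors are raised for invalid duration and rate", {
  expect_error(simulateEcg(beatTemplate(), -1, seed = 1), "duration_s")
  expect_error(simulateEcg(beatTemplate(), 10, fs = 100, seed = 1), "250")
  expect_error(beatTemplate(p_peak_fraction = 1.2), "pPeakFraction")
  expect_error(beatTemplate(p_duration_mean = -5), "positive")
})

test_that("cohort group means land within 3 SE of the specification", {
  cohort <- simulateCohort(cohortSpec(n_group0 = 69, n_group1 = 31, seed = 9))
  expect_equal(nrow(cohort), 100)
  expect_equal(sum(cohort$poaf), 31)
  a0 <- cohort$age_y[cohort$poaf == 0]
  a1 <- cohort$age_y[cohort$poaf == 1]
  expect_lt(abs(mean(a0) - 50.43), 3 * 10.59 / sqrt(69))
  expect_lt(abs(mean(a1) - 55.97), 3 * 8.49 / sqrt(31))
  expect_true(all(cohort$sex_male %in% 0:1))
})

test_that("degenerate cohort variables are exact", {
  v <- data.frame(variable = c("x", "b"), kind = c("normal", "binary"),
                  g0_mean = c(5, NA), g0_sd = c(0, NA),
                  g1_mean = c(7, NA), g1_sd = c(0, NA),
                  g0_prop = c(NA, 0), g1_prop = c(NA, 1))
  cohort <- simulateCohort(cohortSpec(10, 10, variables = v, seed = 1))
  expect_true(all(cohort$x[cohort$poaf == 0] == 5))
  expect_true(all(cohort$x[cohort$poaf == 1] == 7))
  expect_true(all(cohort$b[cohort$poaf == 0] == 0))
  expect_true(all(cohort$b[cohort$poaf == 1] == 1))
})

test_that("cohort simulation is deterministic and rejects unknown kinds", {
  s <- cohortSpec(20, 10, seed = 4)
  expect_identical(simulateCohort(s), simulateCohort(s))
  v <- data.frame(variable = "x", kind = "categorical5",
                  g0_mean = 1, g0_sd = 1, g1_mean = 1, g1_sd = 1)
  expect_error(cohortSpec(5, 5, variables = v), "unknown variable kind")
})

test_that("skewed operative variables match the specified median", {
  cohort <- simulateCohort(cohortSpec(2000, 2000, seed = 13))
  mv0 <- cohort$mech_vent_h[cohort$poaf == 0]
  mv1 <- cohort$mech_vent_h[cohort$poaf == 1]
  expect_lt(abs(stats::median(mv0) - 33) / 33, 0.10)
  expect_lt(abs(stats::median(mv1) - 52) / 52, 0.10)
  expect_gt(stats::median(mv1), stats::median(mv0))
})
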