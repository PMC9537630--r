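test_that("the seven parameters evaluate exactly on a hand-computed case", {
  f <- computePFeatures(c(100, 120, 140), peak_times_ms = c(50, 60, 70))
  expect_equal(f$pmax, 140)
  expect_equal(f$pmin, 100)
  expect_equal(f$pmean, 120)
  expect_equal(f$pstd, 20)       # sample (n-1) SD
  expect_equal(f$pwd, 40)
  expect_equal(f$pptmean, 60)
  expect_equal(f$pptstd, 10)
  expect_equal(f$n_beats, 3)
})

test_that("a degenerate record gives zero spread", {
  f <- computePFeatures(rep(120, 5), peak_times_ms = rep(60, 5))
  expect_equal(f$pstd, 0)
  expect_equal(f$pwd, 0)
  expect_equal(c(f$pmax, f$pmin, f$pmean), c(120, 120, 120))
})

test_that("feature computation rejects insufficient or ill-ordered input", {
  expect_error(computePFeatures(120, peak_times_ms = 60), "at least 2")
  expect_error(computePFeatures(c(100, 120), peak_times_ms = c(110, 60)),
               "ordering")
  fid <- make_fiducials(c(100, 120))
  fid@beats$valid <- FALSE
  expect_error(computePFeatures(fid), "at least 2")
})

test_that("features from fiducials match the sample-index arithmetic", {
  fid <- make_fiducials(c(100, 120, 140), peak_ms = c(50, 60, 70))
  f <- computePFeatures(fid)
  expect_equal(f$pwd, 40)
  expect_equal(f$pptmean, 60)
})

test_that("the feature matrix has one row per retained patient, 7 columns", {
  sets <- lapply(1:94, function(i) make_fiducials(100 + (i %% 5) * 10 + c(0, 4, 9)))
  names(sets) <- sprintf("P%03d", 1:94)
  tab <- featuresTable(sets)
  expect_equal(nrow(tab), 94)
  expect_identical(names(tab)[2:8],
                   c("pmax", "pmin", "pmean", "pstd", "pwd", "pptmean", "pptstd"))
  expect_length(attr(tab, "excluded"), 0)
})

test_that("empty input yields an empty 7-column matrix", {
  tab <- featuresTable(stats::setNames(list(), character()))
  expect_equal(nrow(tab), 0)
  expect_identical(names(tab)[2:8],
                   c("pmax", "pmin", "pmean", "pstd", "pwd", "pptmean", "pptstd"))
})

test_that("excluded patients are dropped and reported; duplicates rejected", {
  good <- make_fiducials(c(110, 120, 130))
  bad <- make_fiducials(rep(120, 10), valid = c(rep(FALSE, 8), TRUE, TRUE))
  bad <- qcFilter(bad)
  sets <- list(A = good, B = bad)
  tab <- featuresTable(sets)
  expect_equal(tab$patient_id, "A")
  expect_identical(attr(tab, "excluded"), "B")
  expect_error(featuresTable(list(A = good, A = good)), "duplicate")
})

test_that("pwd identically equals pmax - pmin and group means are linear", {
  feats <- simulatePWaveFeatures(40, 20, seed = 17)
  expect_identical(feats$pwd, feats$pmax - feats$pmin)
  for (g in 0:1) {
    sub <- feats[feats$poaf == g, ]
    expect_equal(mean(sub$pwd), mean(sub$pmax) - mean(sub$pmin),
                 tolerance = 1e-12)
  }
  expect_true(all(feats$pmin <= feats$pmean & feats$pmean <= feats$pmax))
  expect_true(all(feats$pptmean < feats$pmean))
})

test_that("feature-level cohorts recover the published group means", {
  feats <- simulatePWaveFeatures(60, 60, seed = 23)
  ref <- pwaveReference()
  for (g in 0:1) {
    sub <- feats[feats$poaf == g, ]
    m <- ref[[if (g == 0) "g0_mean" else "g1_mean"]]
    s <- ref[[if (g == 0) "g0_sd" else "g1_sd"]]
    for (k in c("pmean", "pptmean")) {
      i <- match(k, ref$feature)
      expect_lt(abs(mean(sub[[k]]) - m[i]), 3 * s[i] / sqrt(nrow(sub)))
    }
  }
})
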