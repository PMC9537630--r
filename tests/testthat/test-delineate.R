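test_that("every beat of a clean record is found within 10 ms of truth", {
  f <- fx_clean()
  tr <- beats(f$rec$truth)
  expect_equal(nrow(f$qrs), nrow(tr))
  r_ms <- f$qrs$r_peak_idx / 500 * 1000
  expect_true(all(abs(r_ms - tr$r_peak_ms) <= 10))
})

test_that("a flat record yields an empty annotation with a warning", {
  flat <- ecgSignal(rep(0, 5000), 500)
  expect_warning(q <- detectQrs(flat), "no QRS")
  expect_equal(nrow(q), 0)
})

test_that("QRS sensitivity stays above 99% at SNR 20 dB", {
  base <- simulateEcg(beatTemplate(), 120, noise = noiseSpec(0, 0, 0),
                      seed = 21)
  sd20 <- whiteSdForSnr(base$signal, 20)
  rec <- simulateEcg(beatTemplate(), 120, noise = noiseSpec(0, 0, sd20),
                     seed = 21)
  pre <- preprocessEcg(rec$signal)
  qrs <- detectQrs(pre)
  tr <- beats(rec$truth)
  r_ms <- qrs$r_peak_idx / 500 * 1000
  hits <- sum(vapply(tr$r_peak_ms,
                     function(t) any(abs(r_ms - t) <= 50), logical(1)))
  expect_gte(hits / nrow(tr), 0.99)
  expect_lte(nrow(qrs), nrow(tr) + ceiling(0.01 * nrow(tr)))
})

test_that("clean-record onset and offset land within a sample or two of truth", {
  f <- fx_clean()
  e <- delineation_errors(f$rec, f$pre, f$qrs, f$fid)
  expect_gte(mean(e$valid), 0.95)
  expect_gte(mean(abs(e$onset[e$valid]) <= 2), 0.95)   # +/- 1 sample at 500 Hz
  expect_gte(mean(abs(e$offset[e$valid]) <= 2), 0.95)
  expect_lte(mean(abs(e$duration[e$valid])), 4)
})

test_that("beats with no atrial deflection are marked invalid", {
  rec <- simulateEcg(beatTemplate(p_amplitude = 0.0001), 20,
                     noise = noiseSpec(0, 0, 0), seed = 2)
  pre <- preprocessEcg(rec$signal)
  fid <- locatePWaves(pre, detectQrs(pre))
  expect_true(all(!beats(fid)$valid))
})

test_that("duration error degrades monotonically with white-noise level", {
  mae <- vapply(c(0, 0.01, 0.04), function(sd) {
    rec <- simulateEcg(beatTemplate(), 90, noise = noiseSpec(0, 0, sd),
                       seed = 30)
    pre <- preprocessEcg(rec$signal)
    qrs <- detectQrs(pre)
    fid <- locatePWaves(pre, qrs)
    e <- delineation_errors(rec, pre, qrs, fid)
    mean(abs(e$duration[e$valid]))
  }, numeric(1))
  expect_true(all(diff(mae) >= 0))
})

test_that("fiducial ordering holds for every valid delineated beat", {
  f <- fx_clean()
  v <- validBeats(f$fid)
  expect_true(all(v$onset_idx < v$peak_idx))
  expect_true(all(v$peak_idx < v$offset_idx))
  expect_true(all(v$offset_idx < f$qrs$qrs_onset_idx[v$beat]))
})

test_that("QC passes clean beats through unchanged", {
  f <- fx_clean()
  out <- qcFilter(f$fid, f$pre)
  expect_equal(nrow(beats(out)), sum(beats(f$fid)$valid))
  expect_false(patientExcluded(out))
  expect_equal(out@qc$valid_fraction, mean(beats(f$fid)$valid))
})

test_that("QC drops out-of-range durations and flags noisy patients", {
  fid <- make_fiducials(c(120, 130, 500, 125, 30))   # one too long, one too short
  out <- qcFilter(fid)
  expect_equal(nrow(beats(out)), 3)
  expect_false(500 %in% ((beats(out)$offset_idx - beats(out)$onset_idx) * 2))
  ## a record with most beats invalid is excluded at the default threshold
  bad <- make_fiducials(rep(120, 10), valid = c(rep(FALSE, 6), rep(TRUE, 4)))
  out2 <- qcFilter(bad)
  expect_true(patientExcluded(out2))
  expect_equal(out2@qc$valid_fraction, 0.4)
})

test_that("search windows that leave the record mark beats invalid, not fail", {
  rec <- simulateEcg(beatTemplate(), 8, noise = noiseSpec(0, 0, 0), seed = 4)
  pre <- preprocessEcg(rec$signal)
  qrs <- detectQrs(pre)
  ## force a huge window so early beats cannot be searched
  fid <- locatePWaves(pre, qrs, search_window_ms = 20000)
  expect_s4_class(fid, "PWaveFiducials")
  expect_true(any(!beats(fid)$valid))
})
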