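## Shared fixtures, generated once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fx_cache))
    assign(name, force(expr), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

## a clean 2-minute record with default template, preprocessed, plus QRS and
## P-wave fiducials
fx_clean <- function() fx("clean", {
  rec <- simulateEcg(beatTemplate(), duration_s = 120, fs = 500,
                     noise = noiseSpec(0, 0, 0), seed = 42)
  pre <- preprocessEcg(rec$signal)
  qrs <- detectQrs(pre)
  fid <- locatePWaves(pre, qrs)
  list(rec = rec, pre = pre, qrs = qrs, fid = fid)
})

## pair detected beats with ground-truth beats via nearest R peak (ms)
match_truth <- function(truth, qrs, fs) {
  r_ms <- qrs$r_peak_idx / fs * 1000
  tr <- beats(truth)
  vapply(r_ms, function(t) which.min(abs(tr$r_peak_ms - t)), integer(1))
}

## per-beat delineation errors (ms) for a delineated record
delineation_errors <- function(rec, pre, qrs, fid) {
  fs <- samplingRate(pre)
  tr <- beats(rec$truth)
  m <- match_truth(rec$truth, qrs, fs)
  b <- beats(fid)
  ok <- b$valid
  list(
    valid = ok,
    onset = b$onset_idx / fs * 1000 - tr$onset_ms[m],
    offset = b$offset_idx / fs * 1000 - tr$offset_ms[m],
    duration = (b$offset_idx - b$onset_idx) / fs * 1000 - tr$duration_ms[m])
}

## hand-built fiducial object: durations/peaks specified in ms at a given fs
make_fiducials <- function(durations_ms, peak_ms = durations_ms * 0.5,
                           fs = 500, spacing_ms = 1000, valid = TRUE) {
  onset <- seq_along(durations_ms) * spacing_ms
  to_idx <- function(ms) as.integer(round(ms * fs / 1000))
  b <- data.frame(beat = seq_along(durations_ms),
                  onset_idx = to_idx(onset),
                  peak_idx = to_idx(onset + peak_ms),
                  offset_idx = to_idx(onset + durations_ms),
                  iso_mv = 0, valid = rep_len(valid, length(durations_ms)))
  new("PWaveFiducials", beats = b, fs = fs)
}
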