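#' QRS detection by derivative energy with an adaptive threshold
#'
#' A Pan–Tompkins-style detector: the signal is band-passed to the QRS band
#' (5–22 Hz), differentiated, squared and integrated over a 120 ms moving
#' window; peaks of this envelope above an adaptive threshold, separated by a
#' refractory period, mark beats.  The R peak is refined to the signal
#' extremum near each envelope peak, and the QRS onset is found by walking
#' left from the R peak to the isoelectric junction.
#'
#' @param sig a preprocessed [EcgSignal-class].
#' @param refractory_ms minimum inter-beat interval, ms (default 200).
#' @param min_amp minimum plausible R-peak amplitude, mV; a record whose
#'   envelope never exceeds the corresponding energy returns an empty
#'   annotation with a warning (flat-signal contract).
#' @param threshold_frac envelope threshold as a fraction of the robust
#'   envelope peak level (default 0.3).
#' @return A data.frame of class \code{"qrsAnnotation"} with columns
#'   \code{r_peak_idx} and \code{qrs_onset_idx} (0-based sample indices),
#'   strictly increasing.
#' @examples
#' rec <- simulateEcg(beatTemplate(), 30, noise = noiseSpec(0, 0, 0), seed = 1)
#' qrs <- detectQrs(preprocessEcg(rec$signal))
#' nrow(qrs)
#' @export
detectQrs <- function(sig, refractory_ms = 200, min_amp = 0.05,
                      threshold_frac = 0.3) {
  stopifnot(is(sig, "EcgSignal"))
  fs <- sig@fs
  x <- sig@samples
  nyq <- fs / 2

  bp <- signal::butter(2, c(5, 22) / nyq, type = "pass")
  xb <- filtfilt_reflect(bp, x, fs)
  d <- c(0, diff(xb)) * fs
  e <- d^2
  wi <- max(3L, as.integer(round(0.120 * fs)))
  if (wi %% 2L == 0L) wi <- wi + 1L
  cs <- cumsum(c(0, e))
  half <- (wi - 1L) %/% 2L
  n <- length(e)
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  env <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)

  ## energy floor for a min_amp QRS-like deflection
  floor_e <- (min_amp * 2 * pi * 5)^2 * 0.05
  ref_level <- stats::quantile(env, 0.98, names = FALSE)
  if (!is.finite(ref_level) || ref_level < floor_e) {
    warning("no QRS-like activity found; returning empty annotation",
            call. = FALSE)
    return(structure(data.frame(r_peak_idx = integer(), qrs_onset_idx = integer()),
                     class = c("qrsAnnotation", "data.frame")))
  }
  thr <- threshold_frac * ref_level

  above <- env > thr
  edges <- diff(c(FALSE, above, FALSE))
  starts <- which(edges == 1L)
  ends <- which(edges == -1L) - 1L
  peaks <- mapply(function(s, e) s - 1L + which.max(env[s:e]), starts, ends)

  ## refractory: keep the larger envelope peak of any pair closer than the
  ## refractory period
  refr <- round(refractory_ms / 1000 * fs)
  if (length(peaks) > 1L) {
    keep <- rep(TRUE, length(peaks))
    last <- 1L
    for (k in 2L:length(peaks)) {
      if (peaks[k] - peaks[last] < refr) {
        if (env[peaks[k]] > env[peaks[last]]) { keep[last] <- FALSE; last <- k }
        else keep[k] <- FALSE
      } else last <- k
    }
    peaks <- peaks[keep]
  }

  ## refine R peak: extremum of the signal within +/- 80 ms
  r80 <- as.integer(round(0.08 * fs))
  r_idx <- vapply(as.integer(peaks), function(p) {
    a <- max(1L, p - r80); b <- min(length(x), p + r80)
    a - 1L + which.max(abs(x[a:b]))
  }, integer(1))
  r_idx <- sort(unique(r_idx))

  ## QRS onset: walk left from R while the signal keeps descending toward the
  ## baseline; stop at the isoelectric junction
  onset_idx <- vapply(r_idx, function(r) {
    lim <- max(2L, r - round(0.12 * fs))
    amp <- abs(x[r])
    i <- r
    while (i > lim) {
      below <- abs(x[i - 1L]) <= 0.05 * amp
      rising <- abs(x[i - 1L]) >= abs(x[i]) && abs(x[i]) <= 0.2 * amp
      if (below || rising) break
      i <- i - 1L
    }
    i
  }, integer(1))

  structure(data.frame(r_peak_idx = as.integer(r_idx - 1L),
                       qrs_onset_idx = as.integer(onset_idx - 1L)),
            class = c("qrsAnnotation", "data.frame"))
}
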