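## Synthetic single-lead ECG with exact P-wave ground truth.
##
## Each beat is a sum of smooth lobes: the P wave is two half raised-cosine
## lobes (rise over p_peak_fraction of the width, fall over the rest) so the
## wave leaves and rejoins the isoelectric line tangentially — the same
## geometry the delineator's isoelectric-intersection rule measures.  QRS and
## T are symmetric raised-cosine lobes.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Asymmetric raised-cosine P lobe evaluated at times t (ms)
p_lobe <- function(t, onset, peak, offset, amp) {
  y <- numeric(length(t))
  ris <- t >= onset & t <= peak
  fal <- t > peak & t <= offset
  if (peak > onset)
    y[ris] <- amp / 2 * (1 - cos(pi * (t[ris] - onset) / (peak - onset)))
  if (offset > peak)
    y[fal] <- amp / 2 * (1 + cos(pi * (t[fal] - peak) / (offset - peak)))
  y
}

cos_lobe <- function(t, center, width, amp) {
  y <- numeric(length(t))
  inl <- abs(t - center) <= width / 2
  y[inl] <- amp / 2 * (1 + cos(2 * pi * (t[inl] - center) / width))
  y
}

#' Simulate a single-lead ECG record with known P-wave fiducials
#'
#' Generates beats from a [BeatTemplateParams-class] template: RR intervals
#' are Normal(rr_mean, rr_sd) truncated at 300 ms; each beat's P-wave
#' duration is Normal(p_duration_mean, p_duration_sd) truncated at 40 ms.
#' The P offset sits at a fixed PR segment
#' (\code{pr_interval - p_duration_mean}) before QRS onset, so duration
#' variability moves the onset, as atrial conduction delay does.  Noise
#' (baseline wander, powerline, white) is added per \code{noise}.  The exact
#' per-beat onset/peak/offset times are returned as a [SimTruth-class].
#'
#' If a P wave would collide with the previous T wave (template durations
#' exceeding the RR interval) the beat is truncated at the T offset and a
#' warning is issued once per record.
#'
#' @param params a [BeatTemplateParams-class].
#' @param duration_s record length, seconds.
#' @param fs sampling rate, Hz (>= 250).
#' @param noise a [NoiseSpec-class]; \code{noiseSpec(0, 0, 0)} for a clean
#'   record.
#' @param seed integer seed; identical arguments give bit-identical output.
#' @param label record label stored in the signal.
#' @return A list with elements \code{signal} ([EcgSignal-class]) and
#'   \code{truth} ([SimTruth-class]).
#' @examples
#' rec <- simulateEcg(beatTemplate(), duration_s = 30, fs = 500,
#'                    noise = noiseSpec(0, 0, 0), seed = 1)
#' rec$signal
#' head(beats(rec$truth))
#' @export
simulateEcg <- function(params, duration_s, fs = 500,
                        noise = noiseSpec(), seed = 1, label = "synthetic") {
  stopifnot(is(params, "BeatTemplateParams"), is(noise, "NoiseSpec"))
  validObject(params); validObject(noise)
  stopifnot_scalar_pos(duration_s, "duration_s")
  stopifnot_scalar_pos(fs, "fs")
  if (fs < 250)
    stop("'fs' must be at least 250 Hz for millisecond-scale P-wave work",
         call. = FALSE)

  dur_ms <- duration_s * 1000
  pr_seg <- params@prInterval - params@pDurationMean
  if (pr_seg < 20) {
    warning("PR segment (pr_interval - p_duration_mean) below 20 ms; ",
            "P waves will abut the QRS", call. = FALSE)
    pr_seg <- max(pr_seg, 0)
  }

  with_seed(seed, {
    ## beat schedule
    r1 <- max(600, params@prInterval + 500)
    n_max <- ceiling(dur_ms / max(params@rrMean - 4 * params@rrSd, 300)) + 2L
    rr <- rtruncnorm_lower(n_max, params@rrMean, params@rrSd, 300)
    r_times <- r1 + c(0, cumsum(rr))
    r_times <- r_times[r_times < dur_ms - (params@qrsDuration / 2 +
                                           params@tDuration + 150)]
    n_beats <- length(r_times)
    if (n_beats < 1L)
      stop("record too short to hold a single beat", call. = FALSE)

    d <- rtruncnorm_lower(n_beats, params@pDurationMean, params@pDurationSd, 40)
    qrs_on <- r_times - params@qrsDuration / 2
    p_off <- qrs_on - pr_seg
    p_on <- p_off - d

    ## previous beat's T-wave extent (ST segment 100 ms)
    t_cent <- r_times + params@qrsDuration / 2 + 100 + params@tDuration / 2
    t_off <- t_cent + params@tDuration / 2
    truncated <- FALSE
    if (n_beats > 1L) {
      lim <- c(-Inf, t_off[-n_beats]) + 2
      clash <- p_on < lim
      if (any(clash)) {
        truncated <- TRUE
        p_on[clash] <- lim[clash]
        d[clash] <- p_off[clash] - p_on[clash]
      }
    }
    if (any(p_on < 0)) {
      keep <- p_on >= 0
      r_times <- r_times[keep]; d <- d[keep]; qrs_on <- qrs_on[keep]
      p_off <- p_off[keep]; p_on <- p_on[keep]; t_cent <- t_cent[keep]
      n_beats <- length(r_times)
    }
    if (truncated)
      warning("beat overlap: some P waves truncated at the preceding T offset",
              call. = FALSE)
    p_pk <- p_on + params@pPeakFraction * d

    ## synthesis on the sample grid (times in ms)
    n <- round(dur_ms * fs / 1000)
    t_ms <- (seq_len(n) - 1L) / fs * 1000
    x <- numeric(n)
    for (k in seq_len(n_beats)) {
      lo <- max(1L, floor(p_on[k] * fs / 1000) - 1L)
      hi <- min(n, ceiling((t_cent[k] + params@tDuration / 2) * fs / 1000) + 2L)
      idx <- lo:hi
      tt <- t_ms[idx]
      x[idx] <- x[idx] +
        p_lobe(tt, p_on[k], p_pk[k], p_off[k], params@pAmplitude) +
        cos_lobe(tt, r_times[k], params@qrsDuration, params@qrsAmplitude) +
        cos_lobe(tt, t_cent[k], params@tDuration, params@tAmplitude)
    }

    ## additive noise
    t_s <- t_ms / 1000
    if (noise@baselineAmp > 0)
      x <- x + noise@baselineAmp *
        sin(2 * pi * noise@baselineFreq * t_s + stats::runif(1, 0, 2 * pi))
    if (noise@powerlineAmp > 0)
      x <- x + noise@powerlineAmp *
        sin(2 * pi * noise@powerlineFreq * t_s + stats::runif(1, 0, 2 * pi))
    if (noise@whiteSd > 0)
      x <- x + stats::rnorm(n, 0, noise@whiteSd)

    truth <- new("SimTruth",
                 beats = data.frame(beat = seq_len(n_beats),
                                    onset_ms = p_on, peak_ms = p_pk,
                                    offset_ms = p_off, r_peak_ms = r_times,
                                    qrs_onset_ms = qrs_on, duration_ms = d),
                 pDurationMean = params@pDurationMean,
                 pDurationSd = params@pDurationSd)
    list(signal = ecgSignal(x, fs, label = label), truth = truth)
  })
}

#' White-noise level for a target signal-to-noise ratio
#'
#' Returns the white-noise standard deviation that yields the requested SNR
#' (in dB) relative to the root-mean-square of a signal.
#'
#' @param sig an [EcgSignal-class] or numeric vector.
#' @param snr_db target SNR in decibels.
#' @return Noise standard deviation in the signal's units (mV).
#' @examples
#' rec <- simulateEcg(beatTemplate(), 10, noise = noiseSpec(0, 0, 0), seed = 1)
#' whiteSdForSnr(rec$signal, 20)
#' @export
whiteSdForSnr <- function(sig, snr_db) {
  x <- if (is(sig, "EcgSignal")) sig@samples else as.numeric(sig)
  sqrt(mean(x^2)) / 10^(snr_db / 20)
}
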