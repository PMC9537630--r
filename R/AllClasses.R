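#' @import methods
NULL

#' Single-lead ECG signal
#'
#' An \code{EcgSignal} holds a uniformly sampled single-lead voltage series in
#' millivolts together with its sampling rate.  The \code{proc} slot records
#' the conditioning already applied (filter cutoffs, smoothing window), so that
#' downstream delineation can account for it.
#'
#' @slot samples numeric vector of voltages, mV.
#' @slot fs sampling rate, Hz.
#' @slot t0 time offset of the first sample, seconds.
#' @slot label free-text record label.
#' @slot proc named list of processing provenance (e.g. \code{smooth_ms}).
#'
#' @seealso [ecgSignal()], [simulateEcg()], [bandpassDenoise()]
#' @export
setClass("EcgSignal",
  representation(samples = "numeric", fs = "numeric", t0 = "numeric",
                 label = "character", proc = "list"),
  prototype(t0 = 0, label = "", proc = list()))

setValidity("EcgSignal", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(object@samples) < 2L)
    msg <- c(msg, "signal must contain at least 2 samples")
  if (!all(is.finite(object@samples)))
    msg <- c(msg, "all samples must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an EcgSignal
#'
#' @param samples numeric voltage series, mV.
#' @param fs sampling rate, Hz.
#' @param t0 time of the first sample, seconds.
#' @param label record label.
#' @param proc processing provenance list.
#' @return An [EcgSignal-class] object.
#' @examples
#' sig <- ecgSignal(sin(2 * pi * 1 * seq(0, 2, by = 1/250)), fs = 250)
#' samplingRate(sig)
#' @export
ecgSignal <- function(samples, fs, t0 = 0, label = "", proc = list()) {
  new("EcgSignal", samples = as.numeric(samples), fs = as.numeric(fs),
      t0 = as.numeric(t0), label = as.character(label), proc = proc)
}

#' Parametric beat template for ECG simulation
#'
#' Describes one subject's average beat: raised-cosine P, QRS and T lobes with
#' per-beat P-wave duration drawn from a truncated normal distribution.  The
#' PR interval is measured from mean P onset to QRS onset, so the PR segment
#' (P offset to QRS onset) equals \code{pr_interval - p_duration_mean}.
#'
#' @slot pDurationMean,pDurationSd per-beat P duration distribution, ms.
#' @slot pAmplitude P amplitude above the isoelectric line, mV.
#' @slot pPeakFraction position of the first P peak within the wave, in (0,1).
#' @slot prInterval P onset to QRS onset at the mean P duration, ms.
#' @slot qrsDuration,qrsAmplitude QRS lobe width (ms) and height (mV).
#' @slot tDuration,tAmplitude T lobe width (ms) and height (mV).
#' @slot rrMean,rrSd RR-interval distribution, ms.
#' @seealso [beatTemplate()], [simulateEcg()]
#' @export
setClass("BeatTemplateParams",
  representation(pDurationMean = "numeric", pDurationSd = "numeric",
                 pAmplitude = "numeric", pPeakFraction = "numeric",
                 prInterval = "numeric", qrsDuration = "numeric",
                 qrsAmplitude = "numeric", tDuration = "numeric",
                 tAmplitude = "numeric", rrMean = "numeric", rrSd = "numeric"))

setValidity("BeatTemplateParams", function(object) {
  msg <- character()
  pos <- c(pDurationMean = object@pDurationMean, prInterval = object@prInterval,
           qrsDuration = object@qrsDuration, tDuration = object@tDuration,
           rrMean = object@rrMean)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad))
    msg <- c(msg, paste0("durations must be positive: ", paste(bad, collapse = ", ")))
  if (object@pDurationSd < 0 || object@rrSd < 0)
    msg <- c(msg, "standard deviations must be >= 0")
  if (object@pPeakFraction <= 0 || object@pPeakFraction >= 1)
    msg <- c(msg, "'pPeakFraction' must lie strictly in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a beat template
#'
#' Defaults give a sinus beat at 60 bpm with a 130 ms, 0.2 mV P wave peaking
#' at 54\% of its width — the no-POAF group centre of the bundled printed
#' P-wave table.
#'
#' @param p_duration_mean,p_duration_sd P-wave duration distribution, ms.
#' @param p_amplitude P amplitude, mV.
#' @param p_peak_fraction first-peak position within the P wave, in (0,1).
#' @param pr_interval mean P onset to QRS onset, ms.
#' @param qrs_duration,qrs_amplitude QRS width (ms) and height (mV).
#' @param t_duration,t_amplitude T width (ms) and height (mV).
#' @param rr_mean,rr_sd RR interval distribution, ms.
#' @return A [BeatTemplateParams-class] object.
#' @export
beatTemplate <- function(p_duration_mean = 130, p_duration_sd = 15,
                         p_amplitude = 0.2, p_peak_fraction = 0.54,
                         pr_interval = 200, qrs_duration = 90,
                         qrs_amplitude = 1.0, t_duration = 160,
                         t_amplitude = 0.3, rr_mean = 1000, rr_sd = 40) {
  new("BeatTemplateParams",
      pDurationMean = p_duration_mean, pDurationSd = p_duration_sd,
      pAmplitude = p_amplitude, pPeakFraction = p_peak_fraction,
      prInterval = pr_interval, qrsDuration = qrs_duration,
      qrsAmplitude = qrs_amplitude, tDuration = t_duration,
      tAmplitude = t_amplitude, rrMean = rr_mean, rrSd = rr_sd)
}

#' Additive ECG noise specification
#'
#' Three independent components: a slow sinusoidal baseline wander, a
#' powerline sinusoid and white Gaussian noise.  All amplitudes may be zero.
#'
#' @slot baselineAmp,baselineFreq wander amplitude (mV) and frequency (Hz, < 0.5).
#' @slot powerlineAmp,powerlineFreq mains amplitude (mV) and frequency (Hz).
#' @slot whiteSd white-noise standard deviation, mV.
#' @seealso [noiseSpec()]
#' @export
setClass("NoiseSpec",
  representation(baselineAmp = "numeric", baselineFreq = "numeric",
                 powerlineAmp = "numeric", powerlineFreq = "numeric",
                 whiteSd = "numeric"))

setValidity("NoiseSpec", function(object) {
  msg <- character()
  if (object@baselineAmp < 0 || object@powerlineAmp < 0 || object@whiteSd < 0)
    msg <- c(msg, "noise amplitudes must be >= 0")
  if (object@baselineFreq <= 0 || object@baselineFreq >= 0.5)
    msg <- c(msg, "'baselineFreq' must lie in (0, 0.5) Hz")
  if (object@powerlineFreq <= 0)
    msg <- c(msg, "'powerlineFreq' must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a noise specification
#'
#' The default is a quiet ambulatory recording; \code{noiseSpec(0, 0, 0)}
#' gives a noise-free signal.
#'
#' @param baseline_amp,baseline_freq wander amplitude (mV) and frequency (Hz).
#' @param powerline_amp,powerline_freq mains amplitude (mV) and frequency (Hz).
#' @param white_sd white-noise SD, mV.
#' @return A [NoiseSpec-class] object.
#' @export
noiseSpec <- function(baseline_amp = 0.05, powerline_amp = 0.02,
                      white_sd = 0.01, baseline_freq = 0.3,
                      powerline_freq = 50) {
  new("NoiseSpec", baselineAmp = baseline_amp, baselineFreq = baseline_freq,
      powerlineAmp = powerline_amp, powerlineFreq = powerline_freq,
      whiteSd = white_sd)
}

#' Ground-truth fiducials of a simulated record
#'
#' @slot beats data.frame with one row per beat: \code{beat}, \code{onset_ms},
#'   \code{peak_ms}, \code{offset_ms}, \code{r_peak_ms}, \code{qrs_onset_ms},
#'   \code{duration_ms} (all ms from record start).
#' @slot pDurationMean,pDurationSd the generating per-beat P-duration
#'   distribution, ms.
#' @seealso [simulateEcg()]
#' @export
setClass("SimTruth",
  representation(beats = "data.frame", pDurationMean = "numeric",
                 pDurationSd = "numeric"))

setValidity("SimTruth", function(object) {
  b <- object@beats
  need <- c("beat", "onset_ms", "peak_ms", "offset_ms", "r_peak_ms",
            "qrs_onset_ms", "duration_ms")
  if (!all(need %in% names(b)))
    return(paste("'beats' must contain columns:", paste(need, collapse = ", ")))
  if (nrow(b)) {
    if (any(b$onset_ms >= b$peak_ms) || any(b$peak_ms >= b$offset_ms))
      return("each beat must satisfy onset < peak < offset")
    if (is.unsorted(b$onset_ms, strictly = TRUE))
      return("beats must be strictly ordered in time")
  }
  TRUE
})

#' Per-beat P-wave fiducials from delineation
#'
#' Sample indices are 0-based so that \code{idx / fs} is the time from record
#' start; exported tables report milliseconds.
#'
#' @slot beats data.frame with columns \code{beat}, \code{onset_idx},
#'   \code{peak_idx}, \code{offset_idx}, \code{iso_mv}, \code{valid}.
#' @slot fs sampling rate, Hz.
#' @slot qc named list filled by [qcFilter()]: \code{valid_fraction},
#'   \code{patient_excluded}, \code{n_dropped}.
#' @seealso [locatePWaves()], [qcFilter()], [computePFeatures()]
#' @export
setClass("PWaveFiducials",
  representation(beats = "data.frame", fs = "numeric", qc = "list"),
  prototype(qc = list()))

setValidity("PWaveFiducials", function(object) {
  b <- object@beats
  need <- c("beat", "onset_idx", "peak_idx", "offset_idx", "iso_mv", "valid")
  if (!all(need %in% names(b)))
    return(paste("'beats' must contain columns:", paste(need, collapse = ", ")))
  if (length(object@fs) != 1L || object@fs <= 0)
    return("'fs' must be a single positive number")
  v <- b[b$valid, , drop = FALSE]
  if (nrow(v)) {
    if (any(v$onset_idx >= v$peak_idx) || any(v$peak_idx >= v$offset_idx))
      return("valid beats must satisfy onset_idx < peak_idx < offset_idx")
  }
  TRUE
})

## ---- accessors -------------------------------------------------------------

#' @describeIn ecgSignal Number of samples in the record.
#' @param x an \code{EcgSignal}.
#' @export
setMethod("length", "EcgSignal", function(x) length(x@samples))

#' Accessors for PWaveAF objects
#'
#' @param object an object of one of the package's S4 classes.
#' @return \code{samples()} the voltage vector; \code{samplingRate()} the
#'   sampling rate in Hz; \code{recordDuration()} the record length in
#'   seconds; \code{beats()} the per-beat data.frame of a [SimTruth-class] or
#'   [PWaveFiducials-class]; \code{validBeats()} only the beats that passed
#'   delineation; \code{patientExcluded()} the QC exclusion flag.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setMethod("samples", "EcgSignal", function(object) object@samples)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "EcgSignal", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "PWaveFiducials", function(object) object@fs)

#' @rdname accessors
#' @export
setGeneric("recordDuration", function(object) standardGeneric("recordDuration"))
#' @rdname accessors
#' @export
setMethod("recordDuration", "EcgSignal",
          function(object) length(object@samples) / object@fs)

#' @rdname accessors
#' @export
setGeneric("beats", function(object) standardGeneric("beats"))
#' @rdname accessors
#' @export
setMethod("beats", "SimTruth", function(object) object@beats)
#' @rdname accessors
#' @export
setMethod("beats", "PWaveFiducials", function(object) object@beats)

#' @rdname accessors
#' @export
setGeneric("validBeats", function(object) standardGeneric("validBeats"))
#' @rdname accessors
#' @export
setMethod("validBeats", "PWaveFiducials",
          function(object) object@beats[object@beats$valid, , drop = FALSE])

#' @rdname accessors
#' @export
setGeneric("patientExcluded", function(object) standardGeneric("patientExcluded"))
#' @rdname accessors
#' @export
setMethod("patientExcluded", "PWaveFiducials", function(object) {
  isTRUE(object@qc$patient_excluded)
})

## ---- show ------------------------------------------------------------------

setMethod("show", "EcgSignal", function(object) {
  cat(sprintf("EcgSignal%s: %d samples @ %g Hz (%.1f s)\n",
              if (nzchar(object@label)) paste0(" '", object@label, "'") else "",
              length(object@samples), object@fs,
              length(object@samples) / object@fs))
  if (length(object@proc))
    cat("  processing:", paste(names(object@proc), unlist(lapply(object@proc, format)),
                               sep = "=", collapse = ", "), "\n")
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d beats, generating P duration %g +/- %g ms\n",
              nrow(object@beats), object@pDurationMean, object@pDurationSd))
})

setMethod("show", "PWaveFiducials", function(object) {
  b <- object@beats
  cat(sprintf("PWaveFiducials: %d beats (%d valid) @ %g Hz\n",
              nrow(b), sum(b$valid), object@fs))
  if (length(object@qc))
    cat(sprintf("  QC: valid fraction %.2f, patient %s\n",
                object@qc$valid_fraction,
                if (isTRUE(object@qc$patient_excluded)) "EXCLUDED" else "retained"))
})

setMethod("show", "BeatTemplateParams", function(object) {
  cat(sprintf(paste0("BeatTemplateParams: P %g +/- %g ms x %g mV (peak at %g),",
                     " PR %g ms, QRS %g ms, T %g ms, RR %g +/- %g ms\n"),
              object@pDurationMean, object@pDurationSd, object@pAmplitude,
              object@pPeakFraction, object@prInterval, object@qrsDuration,
              object@tDuration, object@rrMean, object@rrSd))
})

setMethod("show", "NoiseSpec", function(object) {
  cat(sprintf("NoiseSpec: wander %g mV @ %g Hz, mains %g mV @ %g Hz, white sd %g mV\n",
              object@baselineAmp, object@baselineFreq, object@powerlineAmp,
              object@powerlineFreq, object@whiteSd))
})

#' Plot an ECG record
#'
#' @param x an [EcgSignal-class].
#' @param from,to time window to draw, seconds.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, \code{x}.
#' @export
setMethod("plot", signature(x = "EcgSignal", y = "missing"),
  function(x, from = 0, to = min(10, recordDuration(x)), ...) {
    t <- x@t0 + seq_along(x@samples) / x@fs
    keep <- t >= from & t <= to
    graphics::plot(t[keep], x@samples[keep], type = "l",
                   xlab = "time (s)", ylab = "amplitude (mV)",
                   main = x@label, ...)
    invisible(x)
  })
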