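#' Filter specification for ECG conditioning
#'
#' @param lowpass_hz low-pass cutoff, Hz (default 40, the upper edge of the
#'   P-wave band in ambulatory recordings).
#' @param highpass_hz high-pass cutoff, Hz (default 0.5, below which baseline
#'   wander lives).
#' @param smooth_ms moving-average window, ms (default 20; 0 disables).
#' @param order Butterworth order for each filter (default 4).
#' @return A list of class \code{"filterSpec"}.
#' @seealso [bandpassDenoise()], [smoothEcg()], [preprocessEcg()]
#' @export
filterSpec <- function(lowpass_hz = 40, highpass_hz = 0.5, smooth_ms = 20,
                       order = 4) {
  if (highpass_hz <= 0 || lowpass_hz <= highpass_hz)
    stop("need 0 < highpass_hz < lowpass_hz", call. = FALSE)
  if (smooth_ms < 0) stop("'smooth_ms' must be >= 0", call. = FALSE)
  structure(list(lowpass_hz = lowpass_hz, highpass_hz = highpass_hz,
                 smooth_ms = smooth_ms, order = order), class = "filterSpec")
}

## zero-phase Butterworth with reflect padding (signal::filtfilt alone leaves
## edge transients; reflection keeps the boundary smooth)
filtfilt_reflect <- function(b, x, fs) {
  npad <- min(length(x) - 1L, max(3L * fs, 64L))
  xp <- c(2 * x[1] - rev(x[seq_len(npad) + 1L]),
          x,
          2 * x[length(x)] - rev(x[length(x) - seq_len(npad)]))
  y <- signal::filtfilt(b, xp)
  y[npad + seq_along(x)]
}

#' Zero-phase band-pass denoising
#'
#' Applies the conditioning chain used throughout the package: a low-pass
#' Butterworth filter followed by a high-pass Butterworth filter, each run
#' forward and backward (zero phase, so no filter delay is introduced), with
#' reflect padding at the record boundaries.  Passband tones are preserved in
#' amplitude and phase; baseline wander and high-frequency noise are
#' attenuated.
#'
#' @param sig an [EcgSignal-class].
#' @param spec a [filterSpec()] (cutoffs must be below Nyquist).
#' @return An [EcgSignal-class] of identical length and sampling rate.
#' @examples
#' rec <- simulateEcg(beatTemplate(), 10, seed = 1)
#' clean <- bandpassDenoise(rec$signal, filterSpec())
#' @export
bandpassDenoise <- function(sig, spec = filterSpec()) {
  stopifnot(is(sig, "EcgSignal"), inherits(spec, "filterSpec"))
  fs <- sig@fs
  nyq <- fs / 2
  if (spec$lowpass_hz >= nyq)
    stop(sprintf("lowpass cutoff %g Hz is at or above Nyquist (%g Hz)",
                 spec$lowpass_hz, nyq), call. = FALSE)
  if (length(sig@samples) <= max(3L * spec$order + 1L, 32L))
    stop("signal shorter than the filter warm-up", call. = FALSE)
  lp <- signal::butter(spec$order, spec$lowpass_hz / nyq, type = "low")
  hp <- signal::butter(spec$order, spec$highpass_hz / nyq, type = "high")
  y <- filtfilt_reflect(lp, sig@samples, fs)
  y <- filtfilt_reflect(hp, y, fs)
  proc <- sig@proc
  proc$lowpass_hz <- spec$lowpass_hz
  proc$highpass_hz <- spec$highpass_hz
  ecgSignal(y, fs, t0 = sig@t0, label = sig@label, proc = proc)
}

#' Moving-average smoothing
#'
#' Centred moving average with reflect padding; the window is rounded to an
#' odd number of samples so the filter stays symmetric (zero phase).  A
#' window of 0 ms returns the input unchanged.  The applied window is
#' recorded in the signal's \code{proc} slot, which [locatePWaves()] uses to
#' keep its isoelectric-crossing estimate unbiased.
#'
#' @param sig an [EcgSignal-class].
#' @param window_ms window length, ms.
#' @return An [EcgSignal-class] of identical length.
#' @export
smoothEcg <- function(sig, window_ms = 20) {
  stopifnot(is(sig, "EcgSignal"))
  if (window_ms < 0) stop("'window_ms' must be >= 0", call. = FALSE)
  if (window_ms == 0) return(sig)
  w <- round(window_ms * sig@fs / 1000)
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  if (w >= length(sig@samples))
    stop("smoothing window longer than the record", call. = FALSE)
  if (w == 1L) return(sig)
  half <- (w - 1L) %/% 2L
  x <- sig@samples
  xp <- c(rev(x[seq_len(half) + 1L]), x, rev(x[length(x) - seq_len(half)]))
  cs <- cumsum(c(0, xp))
  y <- (cs[(w + 1L):(length(xp) + 1L)] - cs[seq_len(length(xp) - w + 1L)]) / w
  proc <- sig@proc
  proc$smooth_ms <- w / sig@fs * 1000
  ecgSignal(y, sig@fs, t0 = sig@t0, label = sig@label, proc = proc)
}

#' Full conditioning chain
#'
#' Band-pass (low-pass then high-pass, zero phase) followed by smoothing, in
#' that order.
#'
#' @inheritParams bandpassDenoise
#' @return A conditioned [EcgSignal-class].
#' @export
preprocessEcg <- function(sig, spec = filterSpec()) {
  smoothEcg(bandpassDenoise(sig, spec), spec$smooth_ms)
}
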