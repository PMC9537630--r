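## P-wave delineation at the isoelectric-line intersection.
##
## The measurement rule: the P onset is the point where the wave leaves the
## isoelectric line and the offset the point where it rejoins it.  A smooth
## atrial deflection leaves the baseline tangentially, so the raw crossing of
## a tolerance band sits inside the true wave; reading the crossing off
## directly would bias every duration short.  The crossing therefore only
## initialises the edge, which is then refined by a flank fit: each side of
## a smooth unimodal P wave is modelled as a half raised-cosine between the
## isoelectric line and the peak, the model is passed through the same
## moving-average window the signal received (recorded in the signal's
## provenance), and the edge position minimising the least-squares misfit
## over the flank is taken.  This uses every flank sample instead of one
## threshold crossing, which is what keeps the edge stable under noise.

## Half-cosine flank fit.  dev: polarity-corrected deviation over the search
## window; p_loc: peak sample (window-relative); cross: band-crossing sample
## initialising the edge; side: -1 onset, +1 offset; w_samp: moving-average
## width in samples (0/1 = none).  Returns a fractional window-relative edge
## position, or NA.
fit_edge <- function(dev, p_loc, amp, side, cross, w_samp) {
  n <- length(dev)
  cand <- cross + seq(-10, 10, by = 0.25)
  cand <- if (side < 0) cand[cand >= 1 & cand <= p_loc - 3]
          else cand[cand <= n & cand >= p_loc + 3]
  if (length(cand) < 2L) return(NA_real_)

  ## SSE region: flank samples from just outside the outermost candidate up
  ## to where the deviation reaches 80% of the peak (the peak cap itself is
  ## distorted by smoothing and by peak-sample quantisation)
  if (side < 0) {
    t_hi <- p_loc
    while (t_hi > max(1L, floor(min(cand))) && dev[t_hi] > 0.8 * amp)
      t_hi <- t_hi - 1L
    ts <- seq(max(1L, floor(min(cand)) - 1L), t_hi)
  } else {
    t_lo <- p_loc
    while (t_lo < min(n, ceiling(max(cand))) && dev[t_lo] > 0.8 * amp)
      t_lo <- t_lo + 1L
    ts <- seq(t_lo, min(n, ceiling(max(cand)) + 1L))
  }
  if (length(ts) < 5L) return(NA_real_)

  w <- as.integer(round(w_samp))
  if (w > 1L && w %% 2L == 0L) w <- w + 1L
  h <- if (w > 1L) (w - 1L) %/% 2L else 0L
  ts_ext <- (min(ts) - h):(max(ts) + h)

  ## template matrix: rows = candidate edges, cols = extended samples; the
  ## flank runs from the candidate edge (0) to the peak (1) on either side
  ref <- p_loc
  G <- matrix(0, length(cand), length(ts_ext))
  for (i in seq_along(cand)) {
    ui <- pmin(pmax((ts_ext - cand[i]) / (ref - cand[i]), 0), 1)
    G[i, ] <- (1 - cos(pi * ui)) / 2
  }
  if (h > 0L) {
    ## centred moving average along columns; result aligns with ts exactly
    cs <- cbind(0, t(apply(G, 1L, cumsum)))
    G <- (cs[, (2L * h + 2L):(ncol(cs))] - cs[, 1L:(ncol(cs) - 2L * h - 1L)]) / w
  }
  m <- dev[ts]
  ## first differences approximately whiten the moving-average-correlated
  ## noise, so the LS fit stays close to maximum likelihood under smoothing
  if (w > 1L && ncol(G) > 2L) {
    G <- G[, -1L, drop = FALSE] - G[, -ncol(G), drop = FALSE]
    m <- diff(m)
  }
  num <- G %*% m
  den <- rowSums(G * G)
  cc <- pmax(as.numeric(num) / pmax(den, 1e-12), 0)
  sse <- sum(m * m) - 2 * cc * as.numeric(num) + cc^2 * den
  cand[which.min(sse)]
}

local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  which(y[2:(n - 1L)] >= y[1:(n - 2L)] & y[2:(n - 1L)] > y[3:n]) + 1L
}

#' Locate P-wave onset, first peak and offset for each beat
#'
#' Within a search window ending shortly before each QRS onset, the
#' isoelectric level is estimated as the median of the PR segment, the first
#' dominant local extremum of the (polarity-corrected) deviation is taken as
#' the P peak, and the onset and offset are found by walking outward from the
#' peak to the crossings of a tolerance band around the isoelectric level,
#' then refining each crossing to the true isoelectric intersection with a
#' tangency fit that accounts for any moving-average smoothing recorded in
#' the signal's provenance.  Beats whose window leaves the record, whose
#' deviation never exceeds \code{min_amp}, or where a crossing cannot be
#' found are marked \code{valid = FALSE}.
#'
#' P-wave polarity is detected once per record as the sign of the median
#' dominant deflection across beats.
#'
#' @param sig a preprocessed [EcgSignal-class].
#' @param qrs a \code{"qrsAnnotation"} from [detectQrs()].
#' @param search_window_ms length of the pre-QRS search window, ms.
#' @param pre_qrs_gap_ms gap between the window end and QRS onset, ms.
#' @param tol_frac tolerance band for the outward walk, as a fraction of the
#'   P amplitude above the isoelectric level.
#' @param min_amp minimum P amplitude, mV.
#' @return A [PWaveFiducials-class] with one row per QRS beat.
#' @examples
#' rec <- simulateEcg(beatTemplate(), 30, noise = noiseSpec(0, 0, 0), seed = 1)
#' pre <- preprocessEcg(rec$signal)
#' fid <- locatePWaves(pre, detectQrs(pre))
#' head(validBeats(fid))
#' @export
locatePWaves <- function(sig, qrs, search_window_ms = 350,
                         pre_qrs_gap_ms = 40, tol_frac = 0.10,
                         min_amp = 0.05) {
  stopifnot(is(sig, "EcgSignal"), inherits(qrs, "qrsAnnotation"))
  if (!nrow(qrs)) stop("'qrs' annotation is empty", call. = FALSE)
  fs <- sig@fs
  x <- sig@samples
  n <- length(x)
  w_samp <- (sig@proc$smooth_ms %||% 0) * fs / 1000
  win <- round(search_window_ms / 1000 * fs)
  gap <- round(pre_qrs_gap_ms / 1000 * fs)

  onset1 <- qrs$qrs_onset_idx + 1L   # 1-based QRS onsets
  r1 <- qrs$r_peak_idx + 1L
  nb <- length(onset1)

  one_beat <- function(k, pol) {
    o <- onset1[k]
    hi <- o - gap                 # window end (exclusive of PR gap)
    lo <- hi - win + 1L
    if (k > 1L) lo <- max(lo, r1[k - 1L] + round(0.42 * fs))
    if (lo < 1L || hi - lo < round(0.08 * fs))
      return(NULL)
    iso <- stats::median(x[(o - gap):(o - 1L)])
    seg <- x[lo:hi]
    dev <- pol * (seg - iso)
    pks <- local_maxima(dev)
    if (!length(pks)) return(NULL)
    a_max <- max(dev[pks])
    if (a_max < min_amp) return(NULL)
    cand <- pks[dev[pks] >= 0.6 * a_max]
    p_loc <- cand[1L]             # first dominant extremum in time
    amp <- dev[p_loc]

    edge <- function(direction) {
      idx <- p_loc
      lim <- if (direction < 0) 1L else length(dev)
      cross <- NA_integer_
      while (idx != lim) {
        idx <- idx + direction
        if (dev[idx] <= tol_frac * amp) { cross <- idx; break }
        if (dev[idx] > amp * 1.05 && abs(idx - p_loc) > 2L) break
      }
      if (is.na(cross)) return(NA_real_)
      t0 <- fit_edge(dev, p_loc, amp, direction, cross, w_samp)
      if (is.na(t0)) t0 <- cross
      t0
    }
    on_f <- edge(-1)
    off_f <- edge(+1)
    if (is.na(on_f) || is.na(off_f)) return(NULL)
    onset_i <- lo - 1L + round(on_f)   # 1-based absolute
    offset_i <- lo - 1L + round(off_f)
    peak_i <- lo - 1L + p_loc
    if (!(onset_i < peak_i && peak_i < offset_i)) return(NULL)
    if (offset_i >= o) return(NULL)
    c(onset_i, peak_i, offset_i, iso)
  }

  ## polarity pass: dominant deflection sign per beat, majority vote
  pol_votes <- vapply(seq_len(nb), function(k) {
    o <- onset1[k]
    hi <- o - gap; lo <- hi - win + 1L
    if (lo < 1L || hi <= lo) return(NA_real_)
    iso <- stats::median(x[(o - gap):(o - 1L)])
    seg <- x[lo:hi] - iso
    up <- max(seg); dn <- -min(seg)
    if (max(up, dn) < min_amp) return(NA_real_)
    if (up >= dn) 1 else -1
  }, numeric(1))
  pol <- if (all(is.na(pol_votes))) 1 else sign(stats::median(pol_votes, na.rm = TRUE))
  if (pol == 0) pol <- 1

  rows <- lapply(seq_len(nb), function(k) {
    r <- one_beat(k, pol)
    if (is.null(r))
      data.frame(beat = k, onset_idx = NA_integer_, peak_idx = NA_integer_,
                 offset_idx = NA_integer_, iso_mv = NA_real_, valid = FALSE)
    else
      data.frame(beat = k, onset_idx = as.integer(r[1] - 1L),
                 peak_idx = as.integer(r[2] - 1L),
                 offset_idx = as.integer(r[3] - 1L),
                 iso_mv = r[4], valid = TRUE)
  })
  new("PWaveFiducials", beats = do.call(rbind, rows), fs = fs)
}

#' Rule-based quality control of delineated beats
#'
#' Stands in for manual verification of the positioning results: beats whose
#' measured duration falls outside \code{[min_duration_ms, max_duration_ms]}
#' or whose P amplitude (peak above the isoelectric level) is below
#' \code{amp_floor} are invalidated, and a patient-level exclusion flag is
#' raised when the fraction of beats surviving falls below
#' \code{min_valid_fraction}.
#'
#' @param fid a [PWaveFiducials-class]; QC needs the signal to re-check
#'   amplitudes, passed as \code{sig} (optional — amplitude rule skipped when
#'   absent).
#' @param sig the [EcgSignal-class] the fiducials were measured on (optional).
#' @param min_duration_ms,max_duration_ms admissible P duration range, ms.
#' @param amp_floor minimum P amplitude, mV.
#' @param min_valid_fraction patient retention threshold (default 0.5).
#' @return A [PWaveFiducials-class] containing only the surviving beats, with
#'   the \code{qc} slot filled (\code{valid_fraction}, \code{patient_excluded},
#'   \code{n_dropped}).  Inspect with [patientExcluded()].
#' @export
qcFilter <- function(fid, sig = NULL, min_duration_ms = 40,
                     max_duration_ms = 400, amp_floor = 0.05,
                     min_valid_fraction = 0.5) {
  stopifnot(is(fid, "PWaveFiducials"))
  b <- fid@beats
  n_all <- nrow(b)
  keep <- b$valid
  dur <- (b$offset_idx - b$onset_idx) / fid@fs * 1000
  keep <- keep & !is.na(dur) & dur >= min_duration_ms & dur <= max_duration_ms
  if (!is.null(sig)) {
    stopifnot(is(sig, "EcgSignal"))
    amp <- abs(sig@samples[b$peak_idx + 1L] - b$iso_mv)
    keep <- keep & !is.na(amp) & amp >= amp_floor
  }
  keep[is.na(keep)] <- FALSE
  frac <- if (n_all) sum(keep) / n_all else 0
  new("PWaveFiducials",
      beats = b[keep, , drop = FALSE],
      fs = fid@fs,
      qc = list(valid_fraction = frac,
                patient_excluded = frac < min_valid_fraction,
                n_dropped = n_all - sum(keep)))
}
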