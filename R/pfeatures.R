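#' Seven per-patient P-wave parameters
#'
#' From the valid delineated beats, per-beat durations
#' \eqn{d_i = (offset - onset)/fs} and onset-to-peak times
#' \eqn{q_i = (peak - onset)/fs} give, in milliseconds:
#' \describe{
#'   \item{pmax, pmin}{widest and narrowest P wave.}
#'   \item{pmean, pstd}{mean and sample (n−1) standard deviation of the
#'     durations.}
#'   \item{pwd}{P-wave dispersion, \code{pmax - pmin} (exactly, by
#'     construction).}
#'   \item{pptmean, pptstd}{mean and sample SD of the onset-to-peak times.}
#' }
#'
#' @param fid a [PWaveFiducials-class] (only \code{valid} beats are used), or
#'   a numeric vector of durations in ms (then \code{peak_times_ms} supplies
#'   the onset-to-peak times).
#' @param peak_times_ms onset-to-peak times in ms when \code{fid} is a plain
#'   duration vector; defaults to \code{NULL}.
#' @return A one-row data.frame with columns \code{pmax}, \code{pmin},
#'   \code{pmean}, \code{pstd}, \code{pwd}, \code{pptmean}, \code{pptstd}
#'   (all ms) and \code{n_beats}.
#' @examples
#' computePFeatures(c(100, 120, 140), peak_times_ms = c(50, 60, 70))
#' @export
computePFeatures <- function(fid, peak_times_ms = NULL) {
  if (is(fid, "PWaveFiducials")) {
    v <- validBeats(fid)
    d <- (v$offset_idx - v$onset_idx) / fid@fs * 1000
    q <- (v$peak_idx - v$onset_idx) / fid@fs * 1000
  } else {
    d <- as.numeric(fid)
    q <- as.numeric(peak_times_ms)
    if (length(q) != length(d))
      stop("durations and peak times must have equal length", call. = FALSE)
  }
  if (length(d) < 2L)
    stop("at least 2 valid beats are required to compute P-wave features",
         call. = FALSE)
  if (any(d <= 0) || any(q <= 0) || any(q >= d))
    stop("invalid fiducial ordering: need 0 < peak time < duration per beat",
         call. = FALSE)
  pmax_ <- max(d); pmin_ <- min(d)
  data.frame(pmax = pmax_, pmin = pmin_, pmean = mean(d), pstd = sample_sd(d),
             pwd = pmax_ - pmin_, pptmean = mean(q), pptstd = sample_sd(q),
             n_beats = length(d))
}

#' Per-patient feature matrix
#'
#' Assembles one row of P-wave features per patient in the fixed column
#' order \code{pmax, pmin, pmean, pstd, pwd, pptmean, pptstd}.  Patients
#' flagged by [qcFilter()] (or with fewer than 2 valid beats) are excluded
#' from the matrix and reported in the \code{"excluded"} attribute.
#'
#' @param fiducial_sets named list of [PWaveFiducials-class], one per
#'   patient; names are patient identifiers (must be unique).
#' @return A data.frame with \code{patient_id}, the seven feature columns
#'   (ms) and \code{n_beats}; excluded patient ids in
#'   \code{attr(, "excluded")}.
#' @export
featuresTable <- function(fiducial_sets) {
  ids <- names(fiducial_sets)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("'fiducial_sets' must be a named list of PWaveFiducials",
         call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate patient identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  cols <- c("pmax", "pmin", "pmean", "pstd", "pwd", "pptmean", "pptstd")
  rows <- list(); excluded <- character()
  for (id in ids) {
    fid <- fiducial_sets[[id]]
    if (patientExcluded(fid) || sum(fid@beats$valid) < 2L) {
      excluded <- c(excluded, id)
      next
    }
    f <- computePFeatures(fid)
    rows[[id]] <- cbind(data.frame(patient_id = id), f)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(patient_id = character()),
          stats::setNames(as.data.frame(matrix(numeric(), 0, 7)), cols),
          data.frame(n_beats = integer()))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
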