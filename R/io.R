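#' Read and write ECG records (two-column CSV or WFDB format 16)
#'
#' The CSV dialect is a two-column file with header
#' \code{time_s,amplitude_mV}; sampling must be uniform (tolerated jitter
#' 1 ppm of the sampling interval).  WFDB support covers single-signal
#' format-16 records: a \code{.hea} text header plus a little-endian 16-bit
#' \code{.dat} file, with amplitudes stored at a fixed ADC gain per mV.
#'
#' @param path for CSV, the file path; for WFDB, the record path without
#'   extension (\code{.hea}/\code{.dat} are appended).
#' @param format \code{"csv"} or \code{"wfdb"}.
#' @param sig an [EcgSignal-class] (writers).
#' @param gain WFDB ADC gain, units per mV (default 1000).
#' @return \code{readEcg()} returns an [EcgSignal-class]; the writers return
#'   the path invisibly.
#' @examples
#' rec <- simulateEcg(beatTemplate(), 5, noise = noiseSpec(0, 0, 0), seed = 1)
#' f <- tempfile(fileext = ".csv")
#' writeEcg(rec$signal, f, format = "csv")
#' back <- readEcg(f, format = "csv")
#' max(abs(samples(back) - samples(rec$signal)))
#' @name ecgIO
NULL

#' @rdname ecgIO
#' @export
readEcg <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    hdr <- gsub('"', "", strsplit(readLines(path, n = 1L), ",")[[1]])
    if (!identical(trimws(hdr), c("time_s", "amplitude_mV")))
      stop("malformed ECG CSV: expected header 'time_s,amplitude_mV'",
           call. = FALSE)
    d <- utils::read.csv(path)
    if (nrow(d) < 2L) stop("ECG CSV holds fewer than 2 samples", call. = FALSE)
    dt <- diff(d$time_s)
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
      stop("non-uniform sampling in ECG CSV (jitter above 1 ppm)",
           call. = FALSE)
    ecgSignal(d$amplitude_mV, fs = 1 / stats::median(dt), t0 = d$time_s[1],
              label = basename(path))
  } else {
    hea <- paste0(path, ".hea")
    if (!file.exists(hea)) stop("WFDB header not found: ", hea, call. = FALSE)
    lines <- readLines(hea)
    rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (length(rec) < 4L)
      stop("malformed WFDB header: need 'name nsig fs nsamp'", call. = FALSE)
    nsig <- as.integer(rec[2]); fs <- as.numeric(rec[3])
    nsamp <- as.integer(rec[4])
    if (nsig != 1L)
      stop("only single-signal WFDB records are supported", call. = FALSE)
    sigline <- strsplit(trimws(lines[2]), "\\s+")[[1]]
    if (sigline[2] != "16")
      stop("only WFDB format 16 is supported", call. = FALSE)
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", sigline[3])))
    dat <- file.path(dirname(hea), sigline[1])
    raw <- readBin(dat, "integer", n = nsamp, size = 2L, signed = TRUE,
                   endian = "little")
    if (length(raw) != nsamp)
      stop("WFDB .dat truncated: expected ", nsamp, " samples", call. = FALSE)
    ecgSignal(raw / gain, fs = fs, label = basename(path))
  }
}

#' @rdname ecgIO
#' @export
writeEcg <- function(sig, path, format = c("csv", "wfdb"), gain = 1000) {
  stopifnot(is(sig, "EcgSignal"))
  format <- match.arg(format)
  if (format == "csv") {
    t <- sig@t0 + (seq_along(sig@samples) - 1L) / sig@fs
    utils::write.csv(data.frame(time_s = t, amplitude_mV = sig@samples),
                     path, row.names = FALSE)
  } else {
    rec <- basename(path)
    q <- as.integer(round(pmin(pmax(sig@samples * gain, -32768), 32767)))
    writeLines(c(sprintf("%s 1 %g %d", rec, sig@fs, length(q)),
                 sprintf("%s.dat 16 %g/mV 16 0 %d 0 0 ECG", rec, gain, q[1])),
               paste0(path, ".hea"))
    writeBin(q, paste0(path, ".dat"), size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read and write fiducial annotation tables
#'
#' Annotations travel as CSV with columns \code{beat}, \code{onset_ms},
#' \code{peak_ms}, \code{offset_ms}, \code{valid} (times in ms from record
#' start).
#'
#' @param fid a [PWaveFiducials-class] or [SimTruth-class].
#' @param path CSV path.
#' @return \code{readFiducials()} returns the annotation data.frame.
#' @name annotationIO
NULL

#' @rdname annotationIO
#' @export
writeFiducials <- function(fid, path) {
  if (is(fid, "PWaveFiducials")) {
    b <- fid@beats
    out <- data.frame(beat = b$beat,
                      onset_ms = b$onset_idx / fid@fs * 1000,
                      peak_ms = b$peak_idx / fid@fs * 1000,
                      offset_ms = b$offset_idx / fid@fs * 1000,
                      valid = b$valid)
  } else if (is(fid, "SimTruth")) {
    b <- fid@beats
    out <- data.frame(beat = b$beat, onset_ms = b$onset_ms,
                      peak_ms = b$peak_ms, offset_ms = b$offset_ms,
                      valid = TRUE)
  } else stop("unsupported annotation object", call. = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname annotationIO
#' @export
readFiducials <- function(path) {
  d <- utils::read.csv(path)
  need <- c("beat", "onset_ms", "peak_ms", "offset_ms", "valid")
  if (!all(need %in% names(d)))
    stop("annotation CSV must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  d
}

#' Read and write patient tables
#'
#' Clinical cohorts and feature matrices are plain CSV with a
#' \code{patient_id} column.
#'
#' @param x a data.frame.
#' @param path CSV path.
#' @return \code{readCohort()} returns the data.frame.
#' @name cohortIO
NULL

#' @rdname cohortIO
#' @export
writeCohort <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohortIO
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(d))
    stop("cohort CSV must contain a 'patient_id' column", call. = FALSE)
  if (anyDuplicated(d$patient_id))
    stop("duplicate patient_id in cohort CSV", call. = FALSE)
  d
}
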