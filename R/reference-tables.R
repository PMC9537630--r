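#' Reference summary tables bundled with the package
#'
#' Three small plain-text tables ship with the package and parameterise the
#' synthetic cohort generator and the summary-statistic checks:
#' \describe{
#'   \item{\code{clinicalReference()}}{per-variable group summaries of the
#'     surgical cohort (no-POAF n = 69, POAF n = 31): mean/SD for normal
#'     continuous variables, counts for binary ones, median and quartiles for
#'     skewed operative times, plus the published two-sided p-value.}
#'   \item{\code{pwaveReference()}}{group mean/SD of the seven per-patient
#'     P-wave parameters (Pmax, Pmin, Pmean, Pstd, PWd, Pptmean, Pptstd).}
#'   \item{\code{studyFlowReference()}}{study bookkeeping counts: patients
#'     monitored, excluded for paroxysmal AF, POAF detected by long-term
#'     monitoring, POAF episodes missed by routine care, and the machine
#'     learning cohort sizes per class.}
#' }
#'
#' @return A data.frame (\code{studyFlowReference()} returns a named numeric
#'   vector).
#' @examples
#' pwaveReference()
#' studyFlowReference()["n_monitored"]
#' @name referenceTables
NULL

ref_path <- function(file) {
  system.file("extdata", file, package = "PWaveAF", mustWork = TRUE)
}

#' @rdname referenceTables
#' @export
clinicalReference <- function() {
  utils::read.csv(ref_path("clinical_reference.csv"), stringsAsFactors = FALSE)
}

#' @rdname referenceTables
#' @export
pwaveReference <- function() {
  utils::read.csv(ref_path("pwave_reference.csv"), stringsAsFactors = FALSE)
}

#' @rdname referenceTables
#' @export
studyFlowReference <- function() {
  x <- utils::read.csv(ref_path("study_flow_reference.csv"),
                       stringsAsFactors = FALSE)
  stats::setNames(as.numeric(x$value), x$quantity)
}

#' POAF detection-rate bookkeeping
#'
#' Computes the study-flow quantities from raw counts: how many monitored
#' patients enter the analysis after exclusions, and the POAF detection rate
#' (as a percentage of included patients) under continuous long-term
#' monitoring versus routine postoperative care.  Routine care misses the
#' episodes captured only by the wearable monitor, so its numerator is
#' \code{n_poaf_long_term - n_poaf_missed_routine}.
#'
#' @param n_monitored patients fitted with the long-term monitor.
#' @param n_excluded patients excluded (paroxysmal AF found preoperatively).
#' @param n_poaf_long_term POAF cases detected by long-term monitoring.
#' @param n_poaf_missed_routine of those, cases routine care did not catch.
#' @return Named list: \code{n_included}, \code{rate_long_term_pct},
#'   \code{rate_routine_pct}.
#' @examples
#' flow <- studyFlowReference()
#' detectionRates(flow["n_monitored"], flow["n_excluded_paroxysmal_af"],
#'                flow["n_poaf_long_term"], flow["n_poaf_missed_routine"])
#' @export
detectionRates <- function(n_monitored, n_excluded, n_poaf_long_term,
                           n_poaf_missed_routine) {
  n_monitored <- as.numeric(n_monitored)
  n_excluded <- as.numeric(n_excluded)
  n_lt <- as.numeric(n_poaf_long_term)
  n_missed <- as.numeric(n_poaf_missed_routine)
  if (n_excluded > n_monitored)
    stop("more exclusions than monitored patients", call. = FALSE)
  n_included <- n_monitored - n_excluded
  if (n_lt > n_included || n_missed > n_lt)
    stop("inconsistent POAF counts", call. = FALSE)
  list(n_included = n_included,
       rate_long_term_pct = 100 * n_lt / n_included,
       rate_routine_pct = 100 * (n_lt - n_missed) / n_included)
}
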