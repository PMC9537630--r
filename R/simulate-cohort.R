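#' Specification of a two-group synthetic clinical cohort
#'
#' Wraps a per-variable distribution table: continuous variables are drawn
#' Normal(mean, SD) per group, binary flags Bernoulli(p) per group, and
#' skewed operative times log-normal with the group median and interquartile
#' range matched.  The default table is [clinicalReference()], whose binary
#' counts are converted to proportions using the reference group sizes
#' (no-POAF 69, POAF 31).
#'
#' @param n_group0,n_group1 group sizes (no-POAF, POAF); both >= 1.
#' @param variables per-variable spec data.frame (see
#'   [clinicalReference()] for the column layout).
#' @param seed integer seed stored in the spec.
#' @param ref_n0,ref_n1 group sizes the binary counts refer to.
#' @return A list of class \code{"cohortSpec"}.
#' @seealso [simulateCohort()]
#' @export
cohortSpec <- function(n_group0 = 69, n_group1 = 31, variables = NULL,
                       seed = 1, ref_n0 = 69, ref_n1 = 31) {
  if (n_group0 < 1 || n_group1 < 1)
    stop("group sizes must be >= 1", call. = FALSE)
  v <- variables %||% clinicalReference()
  if (!all(c("variable", "kind") %in% names(v)))
    stop("'variables' needs at least 'variable' and 'kind' columns",
         call. = FALSE)
  bad <- setdiff(unique(v$kind), c("normal", "binary", "skewed"))
  if (length(bad))
    stop("unknown variable kind: ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(v$g0_prop) && !is.null(v$g0_count)) {
    v$g0_prop <- v$g0_count / ref_n0
    v$g1_prop <- v$g1_count / ref_n1
  }
  isb <- v$kind == "binary"
  if (any(isb & (is.na(v$g0_prop) | v$g0_prop < 0 | v$g0_prop > 1 |
                 is.na(v$g1_prop) | v$g1_prop < 0 | v$g1_prop > 1)))
    stop("binary proportions must lie in [0, 1]", call. = FALSE)
  isn <- v$kind == "normal"
  if (any(isn & (is.na(v$g0_sd) | v$g0_sd < 0 | is.na(v$g1_sd) | v$g1_sd < 0)))
    stop("normal-variable SDs must be >= 0", call. = FALSE)
  structure(list(n_group0 = n_group0, n_group1 = n_group1,
                 variables = v, seed = as.integer(seed)),
            class = "cohortSpec")
}

## log-normal parameters matching a median and IQR
lnorm_from_quartiles <- function(med, q1, q3) {
  sdlog <- if (q3 > q1) (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)) else 0
  list(meanlog = log(med), sdlog = sdlog)
}

#' Simulate a two-group clinical covariate table
#'
#' Draws one row per patient with the POAF label assigned by group
#' (no-POAF patients first).  Deterministic under the seed stored in the
#' spec.  Variables are drawn independently of one another — the reference
#' table publishes only marginal summaries, so no joint structure is
#' emulated (documented limitation).
#'
#' @param spec a [cohortSpec()].
#' @return A data.frame with \code{patient_id}, \code{poaf} (0/1) and one
#'   column per specified variable.
#' @examples
#' cohort <- simulateCohort(cohortSpec(seed = 7))
#' tapply(cohort$age_y, cohort$poaf, mean)
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  n0 <- spec$n_group0; n1 <- spec$n_group1
  v <- spec$variables
  with_seed(spec$seed, {
    out <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n0 + n1)),
      poaf = rep(c(0L, 1L), c(n0, n1)))
    for (i in seq_len(nrow(v))) {
      kind <- v$kind[i]
      col <- switch(kind,
        normal = c(stats::rnorm(n0, v$g0_mean[i], v$g0_sd[i]),
                   stats::rnorm(n1, v$g1_mean[i], v$g1_sd[i])),
        binary = c(stats::rbinom(n0, 1L, v$g0_prop[i]),
                   stats::rbinom(n1, 1L, v$g1_prop[i])),
        skewed = {
          p0 <- lnorm_from_quartiles(v$g0_median[i], v$g0_q1[i], v$g0_q3[i])
          p1 <- lnorm_from_quartiles(v$g1_median[i], v$g1_q1[i], v$g1_q3[i])
          c(stats::rlnorm(n0, p0$meanlog, p0$sdlog),
            stats::rlnorm(n1, p1$meanlog, p1$sdlog))
        },
        stop("unknown variable kind: ", kind, call. = FALSE))
      out[[v$variable[i]]] <- col
    }
    out
  })
}

#' Simulate per-patient P-wave features with the published group structure
#'
#' Emulates the feature matrix without synthesising signal: each patient's
#' per-beat P-duration distribution is drawn from the group's published
#' between-patient structure — the patient mean from
#' Normal(group Pmean mean, Pmean SD), the patient's beat-to-beat SD from
#' Normal(group Pstd mean, Pstd SD) truncated at \code{sigma_floor} — then
#' \code{n_beats} beat durations are drawn (truncated at 40 ms) and the
#' seven features computed with [computePFeatures()].  Onset-to-peak times
#' are the group's Pptmean/Pmean fraction of each duration, so the ordering
#' invariants (pmin <= pmean <= pmax, pwd = pmax - pmin, pptmean < pmean)
#' hold by construction.
#'
#' @param n_group0,n_group1 patients per group (no-POAF, POAF).
#' @param ref group feature summary table, defaulting to [pwaveReference()].
#' @param n_beats beats measured per patient (default 60).
#' @param seed integer seed.
#' @param sigma_floor lower truncation of the per-patient beat SD, ms.
#' @return A data.frame with \code{patient_id}, \code{poaf}, the seven
#'   feature columns and \code{n_beats}; the generating per-patient
#'   \code{mu} and \code{sigma} are attached as attribute
#'   \code{"generating"}.
#' @examples
#' feats <- simulatePWaveFeatures(66, 28, seed = 3)
#' colMeans(feats[feats$poaf == 0, c("pmax", "pmin", "pwd")])
#' @export
simulatePWaveFeatures <- function(n_group0 = 66, n_group1 = 28,
                                  ref = pwaveReference(), n_beats = 60,
                                  seed = 1, sigma_floor = 2) {
  n <- n_group0 + n_group1
  tpl <- patientTemplates(n_group0, n_group1, ref,
                          seed = child_seed(seed, 21),
                          sigma_floor = sigma_floor)
  with_seed(child_seed(seed, 22), {
    rows <- lapply(seq_len(n), function(i) {
      d <- rtruncnorm_lower(n_beats, tpl$mu[i], tpl$sigma[i], 40)
      computePFeatures(d, peak_times_ms = tpl$frac[i] * d)
    })
    out <- cbind(data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                            poaf = tpl$poaf),
                 do.call(rbind, rows))
    rownames(out) <- NULL
    attr(out, "generating") <- data.frame(patient_id = out$patient_id,
                                          mu = tpl$mu, sigma = tpl$sigma)
    out
  })
}

#' Simulate a full study: clinical covariates plus P-wave features
#'
#' Combines [simulateCohort()] and [simulatePWaveFeatures()] for the same
#' patients (clinical covariates and ECG features are drawn independently
#' within group — only group membership links them).
#'
#' @inheritParams simulatePWaveFeatures
#' @param variables clinical variable spec, defaulting to
#'   [clinicalReference()].
#' @return A merged data.frame, one row per patient.
#' @export
simulateStudy <- function(n_group0 = 66, n_group1 = 28, variables = NULL,
                          ref = pwaveReference(), n_beats = 60, seed = 1) {
  clin <- simulateCohort(cohortSpec(n_group0, n_group1, variables,
                                    seed = child_seed(seed, 1)))
  feat <- simulatePWaveFeatures(n_group0, n_group1, ref, n_beats,
                                seed = child_seed(seed, 2))
  stopifnot(identical(clin$poaf, feat$poaf))
  cbind(clin, feat[, setdiff(names(feat), c("patient_id", "poaf"))])
}
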