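#' Multivariable logistic POAF model with ROC/AUC
#'
#' Maximum-likelihood logistic regression of a binary outcome on a predictor
#' set, returning Wald 95\% confidence intervals for the coefficients,
#' per-patient predicted probabilities and the ROC/AUC (with DeLong CI) of
#' those probabilities.  The two models of interest are the clinical model
#' (sex, age, left-atrial diameter, GFR, mechanical ventilation time) and
#' the clinical+ECG model adding Pmax, Pstd and PWd; mechanical ventilation
#' time is recorded postoperatively, so using it to "predict" POAF leaks
#' temporal information — a warning is attached to the result.
#'
#' @param data patient-level data.frame.
#' @param predictors character vector of predictor column names.
#' @param outcome name of the 0/1 outcome column (default \code{"poaf"}).
#' @param conf_level confidence level for coefficient and AUC intervals.
#' @return A list of class \code{"logisticModelResult"}: \code{fit} (the
#'   \code{glm}), \code{coefficients} (estimate, CI, p), \code{prob}
#'   (fitted probabilities), \code{auc}, \code{auc_ci_low},
#'   \code{auc_ci_high}, \code{roc}, \code{separation} flag, and
#'   \code{notes}.
#' @examples
#' study <- simulateStudy(seed = 4)
#' m1 <- fitLogistic(study, c("sex_male", "age_y", "la_mm", "gfr",
#'                            "mech_vent_h"))
#' m1$auc
#' @export
fitLogistic <- function(data, predictors, outcome = "poaf",
                        conf_level = 0.95) {
  miss <- setdiff(c(predictors, outcome), names(data))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  y <- data[[outcome]]
  if (!all(y %in% 0:1) || length(unique(y)) < 2L)
    stop("outcome must be binary with both classes present", call. = FALSE)
  X <- data[, predictors, drop = FALSE]
  const <- vapply(X, function(v) stats::var(as.numeric(v)) == 0, logical(1))
  if (any(const))
    stop("constant predictor(s): ", paste(predictors[const], collapse = ", "),
         call. = FALSE)
  qr_rank <- qr(cbind(1, as.matrix(X)))$rank
  if (qr_rank < length(predictors) + 1L)
    stop("singular design: collinear predictors among ",
         paste(predictors, collapse = ", "), call. = FALSE)

  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(predictors, collapse = " + ")))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  p <- stats::fitted(fit)
  if (!sep && (max(p[y == 1]) > 1 - 1e-8 || min(p) < 1e-8) &&
      min(p[y == 1]) > max(p[y == 0]))
    sep <- TRUE

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  cf <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(cf), estimate = cf[, 1],
                      ci_low = cf[, 1] - z * cf[, 2],
                      ci_high = cf[, 1] + z * cf[, 2],
                      p_value = cf[, 4], row.names = NULL)
  ra <- rocAuc(p, y, conf_level = conf_level)
  notes <- character()
  if ("mech_vent_h" %in% predictors)
    notes <- c(notes, paste("mech_vent_h is a postoperative variable:",
                            "temporal leakage when used for prediction"))
  if (sep) notes <- c(notes, "(quasi-)separation detected")
  structure(list(fit = fit, coefficients = coefs, prob = p,
                 auc = ra$auc, auc_ci_low = ra$ci_low,
                 auc_ci_high = ra$ci_high, roc = ra$roc,
                 separation = sep, notes = notes),
            class = "logisticModelResult")
}

#' @export
print.logisticModelResult <- function(x, ...) {
  cat("Logistic model:", deparse(stats::formula(x$fit)), "\n")
  cat(sprintf("AUC %.3f (%.0f%% CI %.3f-%.3f)%s\n", x$auc,
              100 * 0.95, x$auc_ci_low, x$auc_ci_high,
              if (x$separation) " [separation]" else ""))
  print(x$coefficients, digits = 3)
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}
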