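#' AUC by the Mann–Whitney rank identity, with DeLong confidence interval
#'
#' The area under the ROC curve equals the probability that a randomly
#' chosen positive case receives a higher score than a randomly chosen
#' negative case, with ties counted one half.  It is computed here from
#' mid-ranks, \eqn{AUC = (R_1 - n_1(n_1+1)/2) / (n_1 n_0)} where \eqn{R_1}
#' is the rank sum of the positives.  The 95\% confidence interval uses
#' DeLong's variance estimate via [pROC::ci.auc()].
#'
#' @param scores numeric predicted scores or probabilities.
#' @param labels 0/1 outcome labels (1 = positive class); both classes must
#'   be present.
#' @param conf_level confidence level for the DeLong interval.
#' @return A list: \code{auc}, \code{ci_low}, \code{ci_high}, and the ROC
#'   staircase as a data.frame \code{roc} with columns \code{fpr},
#'   \code{tpr}.
#' @examples
#' rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc   # 0.75
#' @export
rocAuc <- function(scores, labels, conf_level = 0.95) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' must have equal length", call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute an AUC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ci <- tryCatch(suppressWarnings({
    ro <- pROC::roc(labels, scores, quiet = TRUE, direction = "<",
                    levels = c(0, 1))
    as.numeric(pROC::ci.auc(ro, conf.level = conf_level, method = "delong"))
  }), error = function(e) c(NA_real_, NA_real_, NA_real_))

  ## ROC staircase over unique thresholds
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab == 1); fp <- cumsum(lab == 0)
  last <- !duplicated(sc, fromLast = TRUE)   # one point per threshold
  roc_df <- data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))

  list(auc = auc, ci_low = ci[1], ci_high = ci[3], roc = roc_df)
}
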