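#' Two-group comparison with test dispatch by variable kind
#'
#' Reproduces the cohort-table machinery: normally distributed continuous
#' variables are compared with the pooled-variance two-sample t-test and
#' summarised as mean ± SD; skewed continuous variables with the
#' Mann–Whitney U test and summarised as median (Q1, Q3); categorical
#' variables with Pearson's chi-square test without continuity correction,
#' falling back to Fisher's exact test when any expected cell count is
#' below 5.  All tests are two-tailed.
#'
#' @param data a patient-level data.frame containing \code{variable} and the
#'   grouping column.
#' @param variable name of the column to compare.
#' @param kind one of \code{"normal_continuous"}, \code{"skewed_continuous"},
#'   \code{"categorical"}.
#' @param group name of the 0/1 grouping column (default \code{"poaf"}).
#' @return A one-row data.frame: \code{variable}, \code{test} (one of
#'   \code{"t"}, \code{"mann_whitney"}, \code{"chi2"}, \code{"fisher"}),
#'   \code{group0}, \code{group1} (display summaries), \code{statistic},
#'   \code{p_value}.
#' @examples
#' cohort <- simulateCohort(cohortSpec(seed = 2))
#' compareGroups(cohort, "age_y", "normal_continuous")
#' compareGroups(cohort, "sex_male", "categorical")
#' @export
compareGroups <- function(data, variable, kind, group = "poaf") {
  stopifnot(variable %in% names(data), group %in% names(data))
  g <- data[[group]]
  x0 <- data[[variable]][g == 0]
  x1 <- data[[variable]][g == 1]
  if (!length(x0) || !length(x1))
    stop("both groups must be non-empty", call. = FALSE)

  if (kind == "normal_continuous") {
    if (stats::sd(c(x0, x1)) == 0)
      stop("degenerate variance: all values identical in both groups",
           call. = FALSE)
    tt <- stats::t.test(x0, x1, var.equal = TRUE)
    res <- data.frame(
      variable = variable, test = "t",
      group0 = sprintf("%.2f ± %.2f", mean(x0), stats::sd(x0)),
      group1 = sprintf("%.2f ± %.2f", mean(x1), stats::sd(x1)),
      statistic = unname(tt$statistic), p_value = tt$p.value)
  } else if (kind == "skewed_continuous") {
    if (stats::sd(c(x0, x1)) == 0)
      stop("degenerate variance: all values identical in both groups",
           call. = FALSE)
    wt <- suppressWarnings(stats::wilcox.test(x0, x1))
    qs <- function(x) sprintf("%.1f (%.1f, %.1f)", stats::median(x),
                              stats::quantile(x, 0.25), stats::quantile(x, 0.75))
    res <- data.frame(variable = variable, test = "mann_whitney",
                      group0 = qs(x0), group1 = qs(x1),
                      statistic = unname(wt$statistic), p_value = wt$p.value)
  } else if (kind == "categorical") {
    tab <- table(factor(c(x0, x1), levels = sort(unique(c(x0, x1)))),
                 rep(0:1, c(length(x0), length(x1))))
    pc <- function(x) sprintf("%d (%.1f%%)", sum(x == 1), 100 * mean(x == 1))
    if (nrow(tab) < 2L) {
      ## variable constant in both groups: no association is testable
      res <- data.frame(variable = variable, test = "fisher",
                        group0 = pc(x0), group1 = pc(x1),
                        statistic = NA_real_, p_value = NA_real_)
    } else {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        ft <- stats::fisher.test(tab)
        res <- data.frame(variable = variable, test = "fisher",
                          group0 = pc(x0), group1 = pc(x1),
                          statistic = NA_real_, p_value = ft$p.value)
      } else {
        ct <- stats::chisq.test(tab, correct = FALSE)
        res <- data.frame(variable = variable, test = "chi2",
                          group0 = pc(x0), group1 = pc(x1),
                          statistic = unname(ct$statistic), p_value = ct$p.value)
      }
    }
  } else {
    stop("unknown variable kind: ", kind, call. = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Pooled two-sample t-test from summary statistics
#'
#' Computes the Student (pooled-variance) two-sample t statistic from group
#' sizes, means and standard deviations.  When raw data have exactly these
#' summaries, the result is identical to \code{t.test(..., var.equal = TRUE)}
#' on the raw data — this is the oracle used to check published p-values
#' against published n / mean / SD triplets.
#'
#' @param n1,mean1,sd1 first group size, mean and SD.
#' @param n2,mean2,sd2 second group size, mean and SD.
#' @return A list with \code{t}, \code{df} and two-sided \code{p}.
#' @examples
#' ## age comparison from the bundled cohort table
#' ttestFromSummary(69, 50.43, 10.59, 31, 55.97, 8.49)$p
#' @export
ttestFromSummary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2 || n2 < 2)
    stop("both groups need n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0 || (sd1 == 0 && sd2 == 0))
    stop("SDs must be >= 0 and not both zero", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Cohort comparison table
#'
#' Runs [compareGroups()] over every variable of a spec table (kind column:
#' \code{normal} -> pooled t, \code{skewed} -> Mann–Whitney,
#' \code{binary} -> chi-square/Fisher), producing a publication-style
#' summary table.
#'
#' @param data patient-level data.frame.
#' @param variables spec data.frame with \code{variable} and \code{kind}
#'   columns; defaults to the subset of [clinicalReference()] present in
#'   \code{table}.
#' @param group grouping column name.
#' @return A data.frame with one row per variable.
#' @export
cohortStatsTable <- function(data, variables = NULL, group = "poaf") {
  v <- variables %||% clinicalReference()
  v <- v[v$variable %in% names(data), , drop = FALSE]
  kinds <- c(normal = "normal_continuous", skewed = "skewed_continuous",
             binary = "categorical")
  out <- lapply(seq_len(nrow(v)), function(i)
    compareGroups(data, v$variable[i], kinds[[v$kind[i]]], group = group))
  do.call(rbind, out)
}
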