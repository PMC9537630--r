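## RBF-SVM protocol: class-balanced training split, z-score standardisation
## fit on the training set only, stratified fivefold cross-validated grid
## search over (C, gamma), then confusion-matrix metrics on train and test.

default_c_grid <- function() 10^seq(-2, 3, by = 1 / 6)
default_gamma_grid <- function() 10^seq(-3, 2, by = 1 / 6)

## deterministic stratified k-fold assignment
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

scale_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}
scale_apply <- function(X, s) sweep(sweep(X, 2, s$center), 2, s$scale, "/")

svm_fit <- function(X, y, C, gamma) {
  e1071::svm(x = X, y = factor(y, levels = c(0, 1)), type = "C-classification",
             kernel = "radial", cost = C, gamma = gamma, scale = FALSE)
}

#' Tune an RBF support-vector machine by cross-validated grid search
#'
#' Standardises the training features (z-score; parameters kept for reuse at
#' test time), then maximises stratified k-fold cross-validation accuracy
#' over a (C, gamma) grid.  Ties are broken toward the smallest C, then the
#' smallest gamma — the least complex model among the equally accurate.
#' Deterministic under \code{seed}.
#'
#' @param x numeric feature matrix (rows = patients).
#' @param y 0/1 labels.
#' @param c_grid,gamma_grid hyperparameter grids (defaults: log-spaced,
#'   6 points per decade, C in 10^\[-2, 3\], gamma in 10^\[-3, 2\]).
#' @param k number of cross-validation folds (default 5); must not exceed
#'   the per-class training count.
#' @param seed integer seed controlling fold assignment.
#' @return A list of class \code{"svmTuneResult"}: \code{C}, \code{gamma},
#'   \code{cv_accuracy}, the full \code{grid} of CV accuracies, the fitted
#'   \code{model} (trained on all of \code{x} at the tuned parameters) and
#'   the standardisation \code{scaling}.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(38 * 2, -1), ncol = 2),
#'            matrix(rnorm(38 * 2, 1), ncol = 2))
#' y <- rep(0:1, each = 38)
#' fit <- tuneSvm(x, y, c_grid = c(1, 10), gamma_grid = c(0.1, 1), seed = 1)
#' fit$cv_accuracy
#' @export
tuneSvm <- function(x, y, c_grid = default_c_grid(),
                    gamma_grid = default_gamma_grid(), k = 5, seed = 1) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (min(table(y)) < k)
    stop("k exceeds the per-class training count", call. = FALSE)
  sc <- scale_fit(x)
  xs <- scale_apply(x, sc)
  with_seed(seed, {
    fold <- stratified_folds(y, k)
    grid <- expand.grid(C = sort(c_grid), gamma = sort(gamma_grid))
    acc <- vapply(seq_len(nrow(grid)), function(i) {
      hits <- 0L
      for (f in seq_len(k)) {
        tr <- fold != f
        m <- svm_fit(xs[tr, , drop = FALSE], y[tr], grid$C[i], grid$gamma[i])
        pr <- stats::predict(m, xs[!tr, , drop = FALSE])
        hits <- hits + sum(as.integer(as.character(pr)) == y[!tr])
      }
      hits / length(y)
    }, numeric(1))
    grid$cv_accuracy <- acc
    ## ties toward smaller C then smaller gamma: grid is sorted that way
    ord <- order(-grid$cv_accuracy, grid$C, grid$gamma)
    best <- grid[ord[1L], ]
    model <- svm_fit(xs, y, best$C, best$gamma)
    structure(list(C = best$C, gamma = best$gamma,
                   cv_accuracy = best$cv_accuracy, grid = grid,
                   model = model, scaling = sc),
              class = "svmTuneResult")
  })
}

#' Confusion-matrix metrics of a tuned SVM on a test set
#'
#' Predicts with the tuned model (applying the training-set
#' standardisation) and reports accuracy, sensitivity and specificity with
#' POAF (class 1) as the positive class: Ac = (TP+TN)/N, Sen = TP/(TP+FN),
#' Spe = TN/(TN+FP).
#'
#' @param tuned an \code{"svmTuneResult"} from [tuneSvm()].
#' @param x test feature matrix.
#' @param y test 0/1 labels.
#' @return A list of class \code{"svmEval"}: \code{accuracy},
#'   \code{sensitivity}, \code{specificity} and the \code{confusion}
#'   matrix (counts: tp, fp, tn, fn).
#' @export
evaluateSvm <- function(tuned, x, y) {
  stopifnot(inherits(tuned, "svmTuneResult"))
  x <- as.matrix(x)
  y <- as.integer(y)
  if (!nrow(x)) stop("test set is empty", call. = FALSE)
  pr <- stats::predict(tuned$model, scale_apply(x, tuned$scaling))
  pred <- as.integer(as.character(pr))
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  structure(list(
    accuracy = (tp + tn) / length(y),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn)),
    class = "svmEval")
}

#' Run the full SVM protocol on a feature matrix
#'
#' Splits the cohort with [makeSplits()], tunes on the class-balanced
#' training set with [tuneSvm()] and evaluates on train and test with
#' [evaluateSvm()].
#'
#' @param x feature matrix (rows = patients, e.g. the 7 P-wave parameters).
#' @param labels 0/1 POAF labels.
#' @param scheme evaluation scheme, \code{"A"} (all remaining patients as
#'   test) or \code{"B"} (class-balanced test).
#' @param seed integer seed (drives both the split and fold assignment).
#' @param ... passed to [tuneSvm()] (\code{c_grid}, \code{gamma_grid},
#'   \code{k}).
#' @return A list of class \code{"svmResult"}: \code{scheme}, \code{split},
#'   \code{C}, \code{gamma}, \code{train_accuracy}, \code{test} (the test
#'   \code{"svmEval"}), and \code{tuned}.
#' @examples
#' feats <- simulatePWaveFeatures(66, 28, seed = 5)
#' res <- svmProtocol(feats[, c("pmax", "pmin", "pmean", "pstd", "pwd",
#'                              "pptmean", "pptstd")],
#'                    feats$poaf, scheme = "A", seed = 5,
#'                    c_grid = 10^(-1:2), gamma_grid = 10^(-2:0))
#' res$test$accuracy
#' @export
svmProtocol <- function(x, labels, scheme = c("A", "B"), seed = 1, ...) {
  scheme <- match.arg(scheme)
  x <- as.matrix(x)
  sp <- makeSplits(labels, scheme = scheme, seed = child_seed(seed, 11))
  tuned <- tuneSvm(x[sp$train, , drop = FALSE], labels[sp$train],
                   seed = child_seed(seed, 12), ...)
  train_eval <- evaluateSvm(tuned, x[sp$train, , drop = FALSE],
                            labels[sp$train])
  test_eval <- evaluateSvm(tuned, x[sp$test, , drop = FALSE],
                           labels[sp$test])
  structure(list(scheme = scheme, split = sp, C = tuned$C,
                 gamma = tuned$gamma, train_accuracy = train_eval$accuracy,
                 train = train_eval, test = test_eval, tuned = tuned),
            class = "svmResult")
}

#' @export
print.svmResult <- function(x, ...) {
  cat(sprintf("SVM scheme %s: C = %.3g, gamma = %.3g\n", x$scheme, x$C,
              x$gamma))
  cat(sprintf("  train Ac %.2f | test Ac %.2f Sen %.2f Spe %.2f\n",
              x$train_accuracy, x$test$accuracy, x$test$sensitivity,
              x$test$specificity))
  invisible(x)
}
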