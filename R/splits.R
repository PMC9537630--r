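#' Class-balanced 7:3 train/test splits (schemes A and B)
#'
#' The minority class (POAF, label 1) is split 7:3 with
#' \code{floor(0.7 * n1)} patients in the training set and the remainder in
#' the test set.  To avoid over-learning the majority class, the same number
#' of class-0 patients is drawn for training.  The two evaluation schemes
#' differ in the test set only: scheme A tests on every remaining patient
#' (all leftover class 0 plus the class-1 test cases); scheme B tests on a
#' class-balanced subsample — as many random leftover class-0 patients as
#' there are class-1 test cases.  With class sizes (66, 28) this yields
#' train 19+19, scheme-A test 47+9 and scheme-B test 9+9.
#'
#' @param labels 0/1 vector of class labels.
#' @param scheme \code{"A"} or \code{"B"}.
#' @param seed integer seed; the split is deterministic given
#'   \code{(labels, scheme, seed)}.
#' @param train_fraction fraction of class 1 used for training (default 0.7).
#' @return A list of class \code{"splitScheme"}: \code{scheme},
#'   \code{train} and \code{test} integer index vectors, and the per-class
#'   index sets \code{train0}, \code{train1}, \code{test0}, \code{test1}.
#' @examples
#' sp <- makeSplits(rep(0:1, c(66, 28)), scheme = "A", seed = 1)
#' lengths(sp[c("train0", "train1", "test0", "test1")])
#' @export
makeSplits <- function(labels, scheme = c("A", "B"), seed = 1,
                       train_fraction = 0.7) {
  scheme <- match.arg(scheme)
  labels <- as.integer(labels)
  i0 <- which(labels == 0); i1 <- which(labels == 1)
  n0 <- length(i0); n1 <- length(i1)
  n1_train <- floor(train_fraction * n1)
  n1_test <- n1 - n1_train
  if (n1_train < 1 || n1_test < 1)
    stop("class 1 too small to split at this ratio", call. = FALSE)
  if (n0 < n1_train + n1_test)
    stop("class 0 too small: need at least as many cases as class-1 train ",
         "plus test", call. = FALSE)
  with_seed(seed, {
    train1 <- sort(sample(i1, n1_train))
    test1 <- setdiff(i1, train1)
    train0 <- sort(sample(i0, n1_train))
    rest0 <- setdiff(i0, train0)
    test0 <- if (scheme == "A") rest0 else sort(sample(rest0, n1_test))
    structure(list(scheme = scheme, seed = as.integer(seed),
                   train = c(train0, train1), test = c(test0, test1),
                   train0 = train0, train1 = train1,
                   test0 = test0, test1 = test1),
              class = "splitScheme")
  })
}
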