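#' Classification result
#'
#' Container for sound-level SVM classification: the scheme
#' (`cross_validation` or `cross_classification`), the per-fold held-out
#' accuracies (a single accuracy for cross-classification), their mean, and
#' the kernel descriptor.
#'
#' @name classification_result
NULL

new_classification_result <- function(scheme, fold_accuracy, kernel, seed) {
  stopifnot(all(fold_accuracy >= 0 & fold_accuracy <= 1))
  structure(list(scheme = scheme, fold_accuracy = fold_accuracy,
                 mean_accuracy = mean(fold_accuracy),
                 n_folds = length(fold_accuracy), kernel = kernel,
                 seed = seed),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result %s: mean accuracy %.3f over %d fold(s), kernel %s>\n",
              x$scheme, x$mean_accuracy, x$n_folds, x$kernel))
  invisible(x)
}

#' @export
tidy.classification_result <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, fold = seq_len(x$n_folds),
                 accuracy = x$fold_accuracy)
}

#' @export
glance.classification_result <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, mean_accuracy = x$mean_accuracy,
                 n_folds = x$n_folds, kernel = x$kernel)
}

#' Broom-style tidiers
#'
#' `tidy()` returns per-fold rows; `glance()` a one-row summary.
#' @param x Object to tidy.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Stratified k-fold SVM classification of sounds
#'
#' Trains a support-vector machine (default third-order polynomial kernel) to
#' discriminate voice from nonvoice feature vectors with stratified k-fold
#' cross-validation: folds preserve the class balance within one sample and
#' every row is tested exactly once.
#'
#' @param features Numeric matrix or data frame (rows = sounds); non-numeric
#'   columns are dropped.
#' @param labels Factor or character vector with two classes.
#' @param n_folds Number of folds (default 5).
#' @param kernel `"polynomial"` (degree 3) or `"linear"`.
#' @param seed Integer seed for the fold assignment.
#' @return A `classification_result` with scheme `"cross_validation"`.
#' @export
classify_sounds_cv <- function(features, labels, n_folds = 5,
                               kernel = c("polynomial", "linear"), seed = 1) {
  kernel <- match.arg(kernel)
  X <- as.matrix(as.data.frame(features)[vapply(as.data.frame(features),
                                                is.numeric, TRUE)])
  y <- factor(labels)
  if (nlevels(y) != 2) stop("need exactly 2 classes")
  if (min(table(y)) < 2) stop("need >= 2 samples per class")
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  acc <- vapply(seq_len(n_folds), function(k) {
    tr <- fold != k
    fit <- svm_fit(X[tr, , drop = FALSE], y[tr], kernel)
    mean(predict(fit, X[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  out <- new_classification_result("cross_validation", acc,
                                   kernel_desc(kernel), seed)
  out$folds <- fold
  out
}

#' Train-on-one-set, test-on-another SVM classification
#'
#' Fits the SVM once on all training rows (e.g. original-sound features) and
#' reports the accuracy on the full test set (e.g. one acoustic-equivalent
#' class), mirroring the cross-classification scheme.
#'
#' @param train_features,test_features Feature matrices with identical column
#'   ordering.
#' @param train_labels,test_labels Two-class labels.
#' @inheritParams classify_sounds_cv
#' @return A `classification_result` with scheme `"cross_classification"`.
#' @export
classify_sounds_cross <- function(train_features, train_labels,
                                  test_features, test_labels,
                                  kernel = c("polynomial", "linear"),
                                  seed = 1) {
  kernel <- match.arg(kernel)
  keep_num <- function(d) as.matrix(as.data.frame(d)[vapply(as.data.frame(d),
                                                            is.numeric, TRUE)])
  Xtr <- keep_num(train_features)
  Xte <- keep_num(test_features)
  if (ncol(Xtr) != ncol(Xte))
    stop("train and test feature dimensionality differ")
  ytr <- factor(train_labels)
  yte <- factor(test_labels, levels = levels(ytr))
  set.seed(seed)
  fit <- svm_fit(Xtr, ytr, kernel)
  acc <- mean(predict(fit, Xte) == yte)
  new_classification_result("cross_classification", acc, kernel_desc(kernel),
                            seed)
}

svm_fit <- function(X, y, kernel) {
  ## constant columns break e1071's internal scaling; scale only the rest
  scale_cols <- apply(X, 2, function(v) sd(v) > 0)
  e1071::svm(X, y, kernel = kernel,
             degree = if (kernel == "polynomial") 3 else 3,
             cost = 1, scale = scale_cols)
}

kernel_desc <- function(kernel) {
  if (kernel == "polynomial") "polynomial (degree 3)" else "linear"
}
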