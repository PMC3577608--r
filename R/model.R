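# PCA + one-against-rest linear SVM, leave-one-out cross-validation, and the
# label-permutation null.
#
# Design notes that matter for correctness:
# * PCA is refit inside every LOOCV fold on the training subjects only; the
#   held-out subject never touches the transform (no leakage).
# * The retained dimension defaults to n_train - 1, the maximal rank of the
#   centered training matrix: lossless for a linear SVM acting in the span of
#   the training data, and it keeps back-projection exact.
# * Features are centered by the PCA mean only; no variance scaling (all
#   features live on the common correlation scale [-1, 1]).
# * The SVM is an L1-loss soft-margin linear machine solved by deterministic
#   dual coordinate descent; the bias is an augmented constant feature.
# * Ties in the one-against-rest argmax go to the earlier class in the fixed
#   order (patient, sibling, control).

#' Fit a PCA transform on training features
#'
#' @param x n x p numeric matrix (subjects x features).
#' @param d number of components to retain; default `min(n - 1, p)`.
#' @return list of class `pca_transform` with `mean` (length p), `loadings`
#'   (p x d, orthonormal columns, each column's largest-magnitude entry made
#'   positive so the decomposition is deterministic), `sdev` (component
#'   standard deviations) and `d`.
#' @export
fit_pca <- function(x, d = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) stop("need at least 2 training samples")
  d_max <- min(n - 1L, p)
  if (is.null(d)) d <- d_max
  if (d < 1L || d > d_max) {
    stop("d must be in 1..min(n_train - 1, p) = ", d_max, "; got ", d)
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc, nu = 0, nv = d)
  load <- sv$v
  # fix signs: largest-|.| element of each column positive
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  structure(list(mean = mu, loadings = load,
                 sdev = sv$d[seq_len(d)] / sqrt(n - 1), d = d),
            class = "pca_transform")
}

#' Project features through a PCA transform
#'
#' @param pca a `pca_transform`.
#' @param x matrix (rows = samples) or single feature vector.
#' @return projected coordinates, n x d matrix.
#' @export
pca_project <- function(pca, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(pca$mean)) stop("feature dimension mismatch")
  sweep(x, 2L, pca$mean) %*% pca$loadings
}

#' Train one-against-rest linear SVMs
#'
#' One binary soft-margin linear SVM per class (that class positive, the rest
#' negative), trained by dual coordinate descent.
#'
#' @param z n x d numeric matrix of (typically PCA-projected) features.
#' @param labels factor with the fixed class levels; every class must be
#'   present.
#' @param cost_c soft-margin cost C (default 1; the original analysis does
#'   not report a value).
#' @param tol,max_epochs solver controls.
#' @return list of class `ovr_svm` with `weights` (k x d), `biases` (k),
#'   `class_order`, `cost_c`.
#' @export
train_ovr <- function(z, labels, cost_c = 1, tol = 1e-3, max_epochs = 5000L) {
  z <- as.matrix(z)
  labels <- droplevels(as.factor(labels))
  classes <- levels(labels)
  if (any(table(labels) == 0L) || length(classes) < 2L) {
    stop("every class must be present in the training set")
  }
  k <- length(classes)
  W <- matrix(0, nrow = k, ncol = ncol(z),
              dimnames = list(classes, NULL))
  b <- numeric(k)
  for (c in seq_len(k)) {
    y <- ifelse(labels == classes[c], 1, -1)
    wb <- svm_cd_train(z, y, cost_c, tol, max_epochs)
    W[c, ] <- wb[-length(wb)]
    b[c] <- wb[length(wb)]
  }
  structure(list(weights = W, biases = b, class_order = classes,
                 cost_c = cost_c), class = "ovr_svm")
}

#' Decision values of a one-against-rest model
#'
#' @param model an `ovr_svm`.
#' @param z matrix of samples in the model's feature space.
#' @return n x k matrix of decision values.
#' @export
ovr_decision <- function(model, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != ncol(model$weights)) stop("feature dimension mismatch")
  d <- z %*% t(model$weights)
  sweep(d, 2L, model$biases, "+")
}

#' Predict class labels with a trained PCA + one-against-rest model
#'
#' Projects raw features through the PCA transform, evaluates all k decision
#' functions, and returns the class with the highest value; ties break to the
#' earlier class in the class order.
#'
#' @param object list with elements `pca` and `svm` (as produced inside
#'   [loocv()]), or pass `pca = NULL` in `object` to use `x` as-is.
#' @param x feature matrix or vector in the original edge space.
#' @param ... unused.
#' @return factor of predicted labels.
#' @export
predict_ovr <- function(object, x, ...) {
  z <- if (is.null(object$pca)) {
    if (is.null(dim(x))) matrix(x, nrow = 1L) else x
  } else {
    pca_project(object$pca, x)
  }
  dv <- ovr_decision(object$svm, z)
  idx <- apply(dv, 1L, which.max)  # which.max: first maximum = earlier class
  factor(object$svm$class_order[idx], levels = object$svm$class_order)
}

# per-fold PCA projections for LOOCV; labels play no role, so these can be
# shared across label permutations (PCA is unsupervised: refitting it with
# permuted labels gives the identical transform)
loocv_fold_projections <- function(x, d = NULL, keep_transforms = TRUE) {
  n <- nrow(x)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    pca <- fit_pca(x[-i, , drop = FALSE], d)
    folds[[i]] <- list(
      Ztr = pca_project(pca, x[-i, , drop = FALSE]),
      zte = as.numeric(pca_project(pca, x[i, , drop = FALSE])),
      pca = if (keep_transforms) pca
    )
  }
  folds
}

#' Leave-one-out cross-validation of the PCA + one-against-rest classifier
#'
#' Each subject is held out once; PCA and all k SVMs are refit on the
#' remaining subjects only, and the held-out subject is predicted. Per-fold
#' weight vectors (and transforms) are kept for the signature analysis.
#'
#' @param cohort a `labeled_cohort` (or any list with `features` and
#'   `labels`).
#' @param d retained PCA dimension; `NULL` (default) = `n_train - 1`.
#' @param cost_c SVM cost C.
#' @param keep_transforms keep each fold's PCA loadings (needed for weight
#'   back-projection; switch off to save memory on very large feature
#'   spaces).
#' @return list of class `cv_result`: `predicted`, `accuracy`, `confusion`
#'   (row-normalized percentages, rows = true class), `folds` (per fold:
#'   `pca`, `svm`), `d`, `cost_c`.
#' @export
loocv <- function(cohort, d = NULL, cost_c = 1, keep_transforms = TRUE) {
  x <- cohort$features
  labels <- as_class_factor(cohort$labels)
  n <- nrow(x)
  if (any(table(labels) < 2L)) {
    stop("every class needs >= 2 subjects for LOOCV (a fold would lose a class)")
  }
  folds_proj <- loocv_fold_projections(x, d, keep_transforms)
  predicted <- factor(rep(NA_character_, n), levels = levels(labels))
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    fp <- folds_proj[[i]]
    svm <- train_ovr(fp$Ztr, labels[-i], cost_c)
    dv <- ovr_decision(svm, fp$zte)
    predicted[i] <- svm$class_order[which.max(dv[1L, ])]
    folds[[i]] <- list(pca = fp$pca, svm = svm)
  }
  structure(list(predicted = predicted,
                 truth = labels,
                 accuracy = mean(predicted == labels),
                 confusion = confusion_percent(labels, predicted),
                 folds = folds, d = d, cost_c = cost_c,
                 fold_projections = folds_proj),
            class = "cv_result")
}

confusion_percent <- function(truth, predicted) {
  tab <- table(truth = truth, predicted = predicted)
  100 * sweep(unclass(tab), 1L, pmax(rowSums(tab), 1L), "/")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("LOOCV over", length(x$predicted), "subjects: accuracy",
      sprintf("%.1f%%", 100 * x$accuracy), "\n")
  print(round(x$confusion, 1))
  invisible(x)
}

#' Label-permutation test of LOOCV accuracy
#'
#' Repeats the full leave-one-out analysis with uniformly permuted subject
#' labels. The fold-wise PCA projections are computed once and reused: PCA
#' ignores labels, so refitting it under each permutation would reproduce the
#' identical transform. The p-value uses the add-one estimator
#' `(# null >= observed + 1) / (n_perm + 1)`, which can never be 0.
#'
#' @param cohort a `labeled_cohort`.
#' @param d,cost_c as in [loocv()].
#' @param n_perm number of permutations (default 1000, as in the original
#'   analysis).
#' @param seed master seed; permutation i draws its labels from a stream
#'   derived from `(seed, i)` so runs are reproducible.
#' @param observed optionally a precomputed `cv_result` for the true labels
#'   (saves one LOOCV pass).
#' @return list of class `perm_result`: `observed_accuracy`,
#'   `null_accuracies` (length `n_perm`), `p_value`, `n_perm`.
#' @export
permutation_test <- function(cohort, d = NULL, cost_c = 1, n_perm = 1000L,
                             seed = 1L, observed = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  x <- cohort$features
  labels <- as_class_factor(cohort$labels)
  n <- nrow(x)
  if (is.null(observed)) observed <- loocv(cohort, d, cost_c,
                                           keep_transforms = FALSE)
  folds <- if (!is.null(observed$fold_projections)) observed$fold_projections
           else loocv_fold_projections(x, d, keep_transforms = FALSE)
  cpp_folds <- lapply(folds, function(f) list(Ztr = f$Ztr, zte = f$zte))
  k <- nlevels(labels)
  int_labels <- as.integer(labels)
  perm_seeds <- withr_seed(seed, sample.int(.Machine$integer.max - 1L, n_perm))
  null_acc <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    perm <- withr_seed(perm_seeds[p], sample.int(n))
    yp <- int_labels[perm]
    pred <- ovr_loocv_predict_cpp(cpp_folds, yp, k, cost_c)
    null_acc[p] <- mean(pred == yp)
  }
  p_value <- (sum(null_acc >= observed$accuracy) + 1) / (n_perm + 1)
  structure(list(observed_accuracy = observed$accuracy,
                 null_accuracies = null_acc,
                 p_value = p_value, n_perm = n_perm, seed = seed),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("permutation test: observed accuracy %.1f%%, null mean %.1f%%, p = %.4g (%d permutations)\n",
              100 * x$observed_accuracy, 100 * mean(x$null_accuracies),
              x$p_value, x$n_perm))
  invisible(x)
}
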