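# PCA, one-against-rest SVM, LOOCV, permutation null

test_that("fit_pca matches the eigendecomposition oracle", {
  set.seed(5)
  x <- matrix(rnorm(10 * 50), 10)
  pca <- fit_pca(x)
  # component variances = eigenvalues of the brute-force covariance
  ev <- eigen(stats::cov(x), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pca$sdev^2, ev[seq_len(pca$d)], tolerance = 1e-8)
  expect_equal(crossprod(pca$loadings), diag(pca$d), tolerance = 1e-8,
               ignore_attr = TRUE)
  # full-rank retention reconstructs the centered data exactly
  z <- pca_project(pca, x)
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(z %*% t(pca$loadings), xc, tolerance = 1e-8, ignore_attr = TRUE)
  # rank-1 data: first loading parallel to the line
  dirv <- rnorm(20); dirv <- dirv / sqrt(sum(dirv^2))
  pos <- seq(-3, 3, length.out = 7)
  line <- outer(pos, dirv)
  p1 <- fit_pca(line, d = 1)
  expect_equal(abs(sum(p1$loadings[, 1] * dirv)), 1, tolerance = 1e-10)
  expect_equal(as.numeric(abs(pca_project(p1, line))), abs(pos), tolerance = 1e-10)
  expect_error(fit_pca(x, d = 10), "min")
})

test_that("the linear SVM solves the hard-margin problem at large C", {
  # 1-dim, 4 points, support points at -1 and 1: w = 2/gap = 1, b = 0
  X <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y <- c(-1, -1, 1, 1)
  wb <- connsig:::svm_cd_train(X, y, 1e6, 1e-10, 500000L)
  expect_equal(wb[1], 1, tolerance = 1e-4)
  expect_equal(wb[2], 0, tolerance = 1e-4)
  # off-center support points (-1, 3): w = 2/4, b = -w * 1
  wb2 <- connsig:::svm_cd_train(matrix(c(-3, -1, 3, 5), ncol = 1), y,
                                1e6, 1e-10, 500000L)
  expect_equal(wb2[1], 0.5, tolerance = 1e-4)
  expect_equal(wb2[2], -0.5, tolerance = 1e-4)
})

test_that("one-against-rest training separates separable clouds", {
  lc <- onehot_cohort(n_per_class = 10L, noise = 0.05)
  svm <- train_ovr(lc$features, lc$labels, cost_c = 100)
  expect_equal(nrow(svm$weights), 3L)
  pred <- predict_ovr(list(pca = NULL, svm = svm), lc$features)
  expect_equal(as.character(pred), as.character(lc$labels))
  # duplicating every training point leaves the decision functions unchanged
  svm2 <- train_ovr(rbind(lc$features, lc$features),
                    factor(rep(lc$labels, 2), levels = class_order),
                    cost_c = 100, tol = 1e-10, max_epochs = 200000L)
  svm1 <- train_ovr(lc$features, lc$labels, cost_c = 100,
                    tol = 1e-10, max_epochs = 200000L)
  expect_equal(svm1$weights, svm2$weights, tolerance = 1e-6)
  expect_error(train_ovr(lc$features[1:10, ], lc$labels[1:10]), "class")
})

test_that("prediction takes the argmax with ties to the earlier class", {
  svm <- structure(list(weights = matrix(0, 3, 2,
                                         dimnames = list(class_order, NULL)),
                        biases = c(1, 1, 0), class_order = class_order,
                        cost_c = 1), class = "ovr_svm")
  # patient and sibling tie at decision value 1: earlier class order wins
  pred <- predict_ovr(list(pca = NULL, svm = svm), matrix(rnorm(4), 2))
  expect_equal(as.character(pred), c("patient", "patient"))
})

test_that("decision values agree between PCA space and back-projected weights", {
  set.seed(11)
  x <- matrix(rnorm(15 * 40), 15)
  pca <- fit_pca(x, d = 8)
  w <- rnorm(8); b <- 0.3
  w_edge <- backproject(pca, w)
  for (r in 1:100) {
    xi <- rnorm(40)
    expect_equal(sum(w * pca_project(pca, xi)) + b,
                 sum(w_edge * (xi - pca$mean)) + b, tolerance = 1e-8)
  }
})

test_that("LOOCV is leak-free and scores degenerate cohorts correctly", {
  lc <- onehot_cohort(n_per_class = 4L, noise = 0.02)
  cv <- loocv(lc)
  expect_equal(cv$accuracy, 1)
  expect_equal(unname(rowSums(cv$confusion)), rep(100, 3), tolerance = 1e-9)
  expect_length(cv$folds, 12L)

  # no test-set leakage: replacing the held-out subject's features must not
  # change that fold's transform or weights
  lc2 <- lc
  lc2$features[1, ] <- 100 * rnorm(ncol(lc2$features))
  cv2 <- loocv(lc2)
  expect_equal(cv$folds[[1]]$pca$loadings, cv2$folds[[1]]$pca$loadings)
  expect_equal(cv$folds[[1]]$svm$weights, cv2$folds[[1]]$svm$weights)

  # all-identical features can never beat the best class prior
  flat <- structure(list(features = matrix(1, 12, 5),
                         labels = factor(rep(class_order, each = 4),
                                         levels = class_order)),
                    class = "labeled_cohort")
  cv_flat <- loocv(flat, d = 1)
  expect_lte(cv_flat$accuracy, 4 / 12)

  # a class with a single subject cannot be cross-validated
  bad <- structure(list(features = matrix(rnorm(20), 4),
                        labels = factor(c("patient", "patient", "sibling",
                                          "control"), levels = class_order)),
                   class = "labeled_cohort")
  expect_error(loocv(bad), ">= 2 subjects")
})

test_that("R and compiled LOOCV paths agree prediction-for-prediction", {
  coh <- small_cohort(n = 6L, R = 12L, T = 60L, delta = 0.4, seed = 21L)
  lc <- plain_features(coh)
  cv <- loocv(lc)
  folds <- lapply(cv$fold_projections, function(f) list(Ztr = f$Ztr, zte = f$zte))
  pred_cpp <- connsig:::ovr_loocv_predict_cpp(folds, as.integer(lc$labels), 3L, 1)
  expect_equal(as.integer(cv$predicted), as.integer(pred_cpp))
})

test_that("permutation p-values follow the add-one estimator", {
  lc <- onehot_cohort(n_per_class = 4L, noise = 0.02)
  pm <- permutation_test(lc, n_perm = 19L, seed = 2L)
  # separable toy: observed accuracy 1 beats every null -> p = 1/(n_perm + 1)
  expect_equal(pm$observed_accuracy, 1)
  expect_equal(pm$p_value, 1 / 20)
  expect_length(pm$null_accuracies, 19L)
  expect_true(all(pm$null_accuracies >= 0 & pm$null_accuracies <= 1))
  # reproducible under the same master seed, different under another
  pm2 <- permutation_test(lc, n_perm = 19L, seed = 2L)
  expect_identical(pm$null_accuracies, pm2$null_accuracies)
  expect_error(permutation_test(lc, n_perm = 0L), "n_perm")
})

test_that("LOOCV accuracy increases with planted effect size", {
  # Spearman trend over delta_r in {0, 0.2, 0.4, 0.6}, 10 replicates each
  deltas <- c(0, 0.2, 0.4, 0.6)
  grid <- expand.grid(rep = 1:10, delta = deltas)
  acc <- mapply(function(rep, delta) {
    coh <- small_cohort(n = 10L, R = 15L, T = 80L, delta = delta,
                        seed = 3000L + 17L * rep + round(100 * delta),
                        global_signal_sd = 0, n_motion_regressors = 0L)
    loocv(plain_features(coh), keep_transforms = FALSE)$accuracy
  }, grid$rep, grid$delta)
  trend <- stats::cor(grid$delta, acc, method = "spearman")
  expect_gt(trend, 0)
  means <- tapply(acc, grid$delta, mean)
  expect_gt(means[["0.6"]], means[["0"]])
})
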