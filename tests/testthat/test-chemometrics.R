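test_that("threshold labelling treats 140 mg/dL as class 0", {
  expect_identical(labelByThreshold(c(139, 140, 141)), c(0L, 0L, 1L))
  g <- c(90, 155, 130, 181)
  expect_identical(labelByThreshold(g), as.integer(g > 140))
  expect_error(labelByThreshold(0), "> 0")
})

test_that("the first NIPALS weight is the normalised covariance direction", {
  set.seed(101)
  X <- matrix(rnorm(60), 12, 5)
  y <- rnorm(12)
  m <- fitPLS(X, y, 1)
  w_ref <- crossprod(sweep(X, 2, colMeans(X)), y - mean(y))
  w_ref <- drop(w_ref / sqrt(sum(w_ref^2)))
  expect_equal(drop(m@weights), w_ref)
})

test_that("full-rank PLS reproduces the least-squares fit", {
  set.seed(7)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  m <- fitPLS(X, y, 3)
  pls_pred <- predictPosterior(m, X)$raw
  ols_pred <- unname(fitted(lm(y ~ X)))
  expect_equal(pls_pred, ols_pred, tolerance = 1e-8)
})

test_that("PLS predictions agree with an independent implementation", {
  set.seed(33)
  X <- matrix(rnorm(200), 20, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- as.numeric(X[, 1] + 0.5 * X[, 3] + rnorm(20, 0, 0.2) > 0)
  m <- fitPLS(X, y, 3)
  ref <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = FALSE)
  ref_pred <- drop(predict(ref, X)$predict[, 1, 3])
  expect_equal(unname(predictPosterior(m, X)$raw), unname(ref_pred),
               tolerance = 1e-8)
})

test_that("duplicating every sample leaves the regression vector unchanged", {
  set.seed(5)
  X <- matrix(rnorm(48), 12, 4)
  y <- rep(c(0, 1), 6)
  b1 <- fitPLS(X, y, 2)@regression_vector
  b2 <- fitPLS(rbind(X, X), c(y, y), 2)@regression_vector
  expect_equal(b1, b2)
})

test_that("score vectors are mutually orthogonal and rank is enforced", {
  set.seed(13)
  X <- matrix(rnorm(200), 20, 10)
  y <- rnorm(20)
  m <- fitPLS(X, y, 5)
  Xc <- sweep(X, 2, m@x_mean)
  # reconstruct scores sequentially from weights/loadings
  scores <- matrix(0, 20, 5)
  for (a in 1:5) {
    scores[, a] <- Xc %*% m@weights[, a]
    Xc <- Xc - tcrossprod(scores[, a], m@loadings[, a])
  }
  G <- crossprod(scores)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
  # rank-deficient X: more components than rank must error
  Xr <- cbind(X[, 1], X[, 1], X[, 2])
  expect_error(fitPLS(Xr, y, 3), "rank")
  expect_error(fitPLS(X, rep(1, 20), 2), "constant")
})

test_that("posteriors are clipped predictions with ties going to class 1", {
  sep <- separable_xy()
  m <- fitPLS(sep$X, sep$y, 2)
  pr <- predictPosterior(m, sep$X)
  expect_true(all(pr$class == sep$y))
  expect_true(all(pr$posterior >= 0 & pr$posterior <= 1))
  # clipping and the tie rule, via a handcrafted model
  m2 <- new("PLSDAModel", x_mean = 0, y_mean = 0.5,
            weights = matrix(1), loadings = matrix(1), y_loadings = 1,
            regression_vector = 1, n_latent = 1L, decision_threshold = 0.5)
  pr2 <- predictPosterior(m2, matrix(c(1.2, -0.9, 0), 3, 1))
  expect_equal(pr2$posterior, c(1, 0, 0.5))
  expect_identical(pr2$class, c(1L, 0L, 1L))
  expect_error(predictPosterior(m, sep$X[, 1:3]), "feature count")
})

test_that("posterior-to-glucose mapping spans the Clarke grid linearly", {
  expect_identical(posteriorToGlucose(0), 95)
  expect_identical(posteriorToGlucose(1), 185)
  expect_identical(posteriorToGlucose(0.5), 140)
  expect_equal(posteriorToGlucose(0.25), 117.5)
  expect_error(posteriorToGlucose(1.2), "\\[0, 1\\]")
})

test_that("Q2 selection finds strong structure and respects rank limits", {
  sep <- separable_xy(n = 24, p = 6)
  rep <- q2LOO(sep$X, sep$y)
  expect_gt(max(rep$q2_per_lv), 0.9)
  expect_true(all(rep$q2_per_lv <= 1))
  expect_identical(rep$chosen_lv,
                   as.integer(names(which.max(rep$q2_per_lv))))
  # rank-limited: 4 samples support at most 3 components
  small <- list(X = matrix(rnorm(32), 4, 8), y = c(0, 1, 0, 1))
  expect_warning(rep2 <- q2LOO(small$X, small$y, 1:5), "-Inf")
  expect_true(all(is.infinite(rep2$q2_per_lv[4:5])))
})

test_that("k-fold accuracy is perfect on separable data and deterministic", {
  sep <- separable_xy(n = 30, p = 5)
  cv <- kfoldAccuracy(sep$X, sep$y, k = 5, n_latent = 2, seed = 4)
  expect_equal(cv$mean_accuracy, 1)
  expect_equal(cv$pooled_accuracy, 1)
  expect_true(all(cv$fold_accuracies >= 0 & cv$fold_accuracies <= 1))
  cv2 <- kfoldAccuracy(sep$X, sep$y, k = 5, n_latent = 2, seed = 4)
  expect_identical(cv, cv2)
  expect_error(kfoldAccuracy(sep$X, sep$y, k = 1), "k must be")
})

test_that("stratified folds keep both classes in every training part", {
  y <- c(rep(0L, 40), rep(1L, 15))
  X <- matrix(rnorm(55 * 4), 55, 4)
  X[, 1] <- X[, 1] + y
  cv <- kfoldAccuracy(X, y, k = 5, n_latent = 2, seed = 2)
  expect_length(cv$fold_accuracies, 5)
  for (f in 1:5)
    expect_identical(sort(unique(y[cv$folds != f])), c(0L, 1L))
})

test_that("the experiment report is reproducible and internally consistent", {
  ds <- generateDataset(40, noise = noiseParams("fixed", seed = 31))
  r1 <- runExperiment(ds, seed = 31)
  r2 <- runExperiment(ds, seed = 31)
  expect_identical(r1, r2)
  expect_identical(r1$chosen_lv,
                   as.integer(names(which.max(r1$q2_per_lv))))
  scored <- !is.na(r1$posterior)
  expect_equal(r1$predicted_glucose[scored],
               posteriorToGlucose(r1$posterior[scored]))
  expect_identical(sum(r1$zone_counts), sum(scored))
})
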