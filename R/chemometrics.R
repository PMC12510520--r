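#' Binary hyperglycaemia label
#'
#' 1 if glucose exceeds the threshold, else 0. The default 140 mg/dL is the
#' American Diabetes Association postprandial hyperglycaemia cut-off; a value
#' exactly at the threshold is labelled 0 (the threshold rule is stated as
#' strictly "above").
#'
#' @param glucose glucose concentration(s) in mg/dL, > 0.
#' @param threshold decision threshold in mg/dL.
#' @return integer vector of 0/1 labels.
#' @examples
#' labelByThreshold(c(139, 140, 141))
#' @export
labelByThreshold <- function(glucose, threshold = 140) {
  if (any(!is.finite(glucose)) || any(glucose <= 0))
    stop("glucose must be > 0")
  as.integer(glucose > threshold)
}

#' Fit a PLS-DA model by NIPALS
#'
#' Univariate-response NIPALS partial least squares on column-centred data.
#' Per component: weight \eqn{w \propto X^\top y} (unit norm), scores
#' \eqn{t = Xw}, X-loading \eqn{p = X^\top t / t^\top t}, response loading
#' \eqn{q = y^\top t / t^\top t}, then deflation \eqn{X \leftarrow X - tp^\top},
#' \eqn{y \leftarrow y - qt}. The regression vector is
#' \eqn{b = W (P^\top W)^{-1} q}, so predictions are
#' \eqn{\hat y = (x - \bar x) b + \bar y}. Components whose score norm
#' collapses stop the extraction early with a warning.
#'
#' @param X numeric matrix, samples x features.
#' @param y numeric response (0/1 class membership for PLS-DA).
#' @param n_latent number of latent variables, >= 1 and at most the rank of
#'   the centred X.
#' @param decision_threshold posterior threshold for class 1.
#' @return a [PLSDAModel-class].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 10, 4)
#' y <- as.numeric(X[, 1] > 0)
#' fitPLS(X, y, n_latent = 2)
#' @export
fitPLS <- function(X, y, n_latent, decision_threshold = 0.5) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least two samples")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (sd(y) == 0) stop("response is constant")
  n_latent <- as.integer(n_latent)
  if (n_latent < 1L) stop("n_latent must be >= 1")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  r <- qr(Xc)$rank
  if (n_latent > r)
    stop("n_latent (", n_latent, ") exceeds the rank of centred X (", r, ")")
  yc <- y - y_mean
  W <- P <- matrix(0, p, n_latent)
  q <- numeric(n_latent)
  tol <- 1e-12 * max(abs(Xc))
  A <- 0L
  for (a in seq_len(n_latent)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < tol) {
      warning("degenerate deflation at component ", a, "; stopping early")
      break
    }
    w <- w / nw
    t_a <- drop(Xc %*% w)
    tt <- sum(t_a^2)
    if (tt < tol^2) {
      warning("score norm collapsed at component ", a, "; stopping early")
      break
    }
    p_a <- drop(crossprod(Xc, t_a)) / tt
    q_a <- sum(yc * t_a) / tt
    Xc <- Xc - tcrossprod(t_a, p_a)
    yc <- yc - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; q[a] <- q_a
    A <- a
  }
  if (A == 0L) stop("no latent variable could be extracted")
  W <- W[, seq_len(A), drop = FALSE]
  P <- P[, seq_len(A), drop = FALSE]
  q <- q[seq_len(A)]
  b <- drop(W %*% solve(crossprod(P, W), q))
  new("PLSDAModel", x_mean = x_mean, y_mean = y_mean, weights = W,
      loadings = P, y_loadings = q, regression_vector = b,
      n_latent = A, decision_threshold = decision_threshold)
}

#' Class posterior from a PLS-DA model
#'
#' The raw PLS prediction of the 0/1 response, clipped to [0, 1], serves as
#' the class-1 posterior probability. Class 1 is assigned when the posterior
#' is at or above the decision threshold (ties go to class 1).
#'
#' @param model a [PLSDAModel-class].
#' @param X samples x features matrix (or a single feature vector).
#' @param n_latent optionally predict with the first \code{n_latent}
#'   components only (default: all fitted components).
#' @return data.frame with columns \code{raw}, \code{posterior}, \code{class}.
#' @export
predictPosterior <- function(model, X, n_latent = model@n_latent) {
  stopifnot(is(model, "PLSDAModel"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != length(model@x_mean))
    stop("feature count mismatch: model has ", length(model@x_mean),
         ", data has ", ncol(X))
  n_latent <- as.integer(n_latent)
  if (n_latent < 1L || n_latent > model@n_latent)
    stop("n_latent must be between 1 and the fitted component count")
  b <- if (n_latent == model@n_latent) model@regression_vector else {
    W <- model@weights[, seq_len(n_latent), drop = FALSE]
    P <- model@loadings[, seq_len(n_latent), drop = FALSE]
    drop(W %*% solve(crossprod(P, W), model@y_loadings[seq_len(n_latent)]))
  }
  raw <- drop(sweep(X, 2, model@x_mean) %*% b) + model@y_mean
  post <- pmin(pmax(raw, 0), 1)
  data.frame(raw = raw, posterior = post,
             class = as.integer(post >= model@decision_threshold))
}

#' Map a class posterior to a glucose concentration
#'
#' Linear map of the posterior onto the span of the Clarke error grid used
#' for display, \code{lo + p * (hi - lo)}. With the default 95--185 mg/dL
#' span, a posterior of 0.5 maps to exactly 140 mg/dL, the class threshold.
#'
#' @param p posterior probability in [0, 1].
#' @param lo,hi glucose concentrations mapped to p = 0 and p = 1, mg/dL.
#' @return glucose concentration(s) in mg/dL.
#' @examples
#' posteriorToGlucose(c(0, 0.5, 1))  # 95 140 185
#' @export
posteriorToGlucose <- function(p, lo = 95, hi = 185) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("posterior must lie in [0, 1]")
  lo + p * (hi - lo)
}

#' Leave-one-out Q2 latent-variable selection
#'
#' For each candidate component count, computes the predictive explained
#' variance \eqn{Q^2 = 1 - \mathrm{PRESS}/\mathrm{TSS}} under leave-one-out
#' cross-validation, with \eqn{\mathrm{PRESS} = \sum_i (y_i - \hat y_{-i})^2}
#' and \eqn{\mathrm{TSS} = \sum_i (y_i - \bar y_{-i})^2} using the
#' training-fold mean (strict out-of-sample convention). The selected count
#' maximises Q2; ties go to the smallest count (parsimony). Candidates
#' exceeding the rank of any training fold are scored \code{-Inf} and skipped
#' with a warning.
#'
#' @param X samples x features matrix, n >= 3.
#' @param y numeric 0/1 response.
#' @param lv_candidates candidate component counts (default 1--5).
#' @return list with \code{q2_per_lv} (named over the candidates),
#'   \code{chosen_lv}, \code{press}, \code{tss}.
#' @export
q2LOO <- function(X, y, lv_candidates = 1:5) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("need at least three samples for leave-one-out Q2")
  lv_candidates <- sort(unique(as.integer(lv_candidates)))
  max_lv <- max(lv_candidates)
  max_feasible <- min(vapply(seq_len(n), function(i)
    qr(sweep(X[-i, , drop = FALSE], 2,
             colMeans(X[-i, , drop = FALSE])))$rank, integer(1)))
  if (max_lv > max_feasible) {
    warning("candidates above the training-fold rank (", max_feasible,
            ") scored as -Inf")
  }
  fit_lv <- min(max_lv, max_feasible)
  pred <- matrix(NA_real_, n, fit_lv)
  tss_i <- numeric(n)
  for (i in seq_len(n)) {
    m <- fitPLS(X[-i, , drop = FALSE], y[-i], fit_lv)
    for (a in seq_len(min(fit_lv, m@n_latent)))
      pred[i, a] <- predictPosterior(m, X[i, , drop = FALSE], n_latent = a)$raw
    tss_i[i] <- (y[i] - mean(y[-i]))^2
  }
  tss <- sum(tss_i)
  q2 <- vapply(lv_candidates, function(a) {
    if (a > fit_lv || anyNA(pred[, a])) return(-Inf)
    1 - sum((y - pred[, a])^2) / tss
  }, numeric(1))
  names(q2) <- lv_candidates
  chosen <- lv_candidates[which.max(q2)]
  list(q2_per_lv = q2, chosen_lv = chosen,
       press = vapply(lv_candidates, function(a)
         if (a > fit_lv) NA_real_ else sum((y - pred[, a])^2), numeric(1)),
       tss = tss)
}

# stratified fold assignment: shuffle each class, deal round-robin
.stratifiedFolds <- function(y, k, seed) {
  set.seed(as.integer(seed))
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Stratified k-fold cross-validated classification accuracy
#'
#' Seeded, class-stratified folds; per fold, a PLS-DA model is fitted on the
#' remaining data and the held-out samples are classified at the posterior
#' threshold. Folds whose training part lacks a class are skipped with a
#' warning. Both the fold-averaged and the pooled-prediction accuracy are
#' returned (they differ when fold sizes differ).
#'
#' @param X samples x features matrix.
#' @param y integer 0/1 labels.
#' @param k number of folds, >= 2.
#' @param n_latent latent-variable count for every fold model.
#' @param seed integer seed for the fold shuffle.
#' @return list with \code{fold_accuracies}, \code{mean_accuracy},
#'   \code{pooled_accuracy}, \code{posterior} and \code{predicted} (pooled
#'   out-of-fold posteriors and classes, in sample order), \code{folds},
#'   \code{n_latent}, \code{seed}.
#' @export
kfoldAccuracy <- function(X, y, k = 5L, n_latent = 5L, seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  if (k < 2L) stop("k must be >= 2")
  folds <- .stratifiedFolds(y, k, seed)
  acc <- numeric(0)
  posterior <- rep(NA_real_, length(y))
  predicted <- rep(NA_integer_, length(y))
  for (f in seq_len(k)) {
    test <- which(folds == f)
    if (length(test) == 0L) next
    train <- which(folds != f)
    if (length(unique(y[train])) < 2L) {
      warning("fold ", f, " skipped: a class is absent from the training part")
      next
    }
    lv <- min(n_latent, qr(sweep(X[train, , drop = FALSE], 2,
                                 colMeans(X[train, , drop = FALSE])))$rank)
    m <- fitPLS(X[train, , drop = FALSE], y[train], lv)
    pr <- predictPosterior(m, X[test, , drop = FALSE])
    posterior[test] <- pr$posterior
    predicted[test] <- pr$class
    acc <- c(acc, mean(pr$class == y[test]))
  }
  if (length(acc) == 0L) stop("no fold could be evaluated")
  scored <- !is.na(predicted)
  list(fold_accuracies = acc, mean_accuracy = mean(acc),
       pooled_accuracy = mean(predicted[scored] == y[scored]),
       posterior = posterior, predicted = predicted, folds = folds,
       n_latent = as.integer(n_latent), seed = as.integer(seed))
}
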