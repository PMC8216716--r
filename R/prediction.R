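# Out-of-sample prediction of performance and age from coupling estimates:
# leave-one-out multiple regression, leave-one-out quadratic discriminant
# analysis, and an exact binomial test against the no-information rate.

#' Leave-one-out cross-validated multiple regression
#'
#' For every subject, an ordinary least-squares regression of the target on
#' the features is fitted to the remaining subjects and used to predict the
#' held-out one.
#'
#' @param features numeric matrix, subjects x features (no missing cells)
#' @param target numeric vector
#' @return object of class `cv_result`: `predictions`, `rmse` (over held-out
#'   predictions), `r2` (squared Pearson correlation of predicted vs
#'   observed) and `r2_ss` (`1 - SSE/SST`, can be negative out of sample)
#' @export
loocv_regression <- function(features, target) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (any(!is.finite(X)) || any(!is.finite(target))) stop("missing cells")
  if (length(target) != n) stop("length mismatch")
  if (n < ncol(X) + 2) stop("too few subjects for the number of features")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- cbind(1, X[-i, , drop = FALSE])
    yi <- target[-i]
    qr_fit <- qr(Xi)
    if (qr_fit$rank < ncol(Xi)) {
      warning("rank-deficient training design in fold ", i,
              "; using a ridge fallback")
      XtX <- crossprod(Xi)
      lam <- 1e-6 * mean(diag(XtX))
      b <- solve(XtX + diag(lam, ncol(Xi)), crossprod(Xi, yi))
    } else {
      b <- qr.coef(qr_fit, yi)
    }
    preds[i] <- drop(c(1, X[i, ]) %*% b)
  }
  rmse <- sqrt(mean((preds - target)^2))
  structure(list(predictions = preds, observed = target, rmse = rmse,
                 r2 = cor(preds, target)^2,
                 r2_ss = 1 - sum((preds - target)^2) /
                   sum((target - mean(target))^2)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("LOOCV regression: RMSE = %.3f, R2 (squared correlation) = %.2f\n",
              x$rmse, x$r2))
  invisible(x)
}

# class-conditional Gaussian discriminant with class-specific shrinkage-
# regularized covariances
qda_train <- function(X, y, shrink = 1e-6) {
  classes <- levels(y)
  p <- ncol(X)
  models <- lapply(classes, function(k) {
    Xk <- X[y == k, , drop = FALSE]
    mu <- colMeans(Xk)
    S <- stats::cov(Xk)
    S <- S + diag(shrink * sum(diag(S)) / p, p)
    cS <- tryCatch(chol(S), error = function(e)
      stop("singular covariance for class '", k, "' even after shrinkage"))
    list(mu = mu, chol = cS, logdet = 2 * sum(log(diag(cS))),
         prior = mean(y == k))
  })
  names(models) <- classes
  models
}

qda_discriminants <- function(models, x) {
  vapply(models, function(m) {
    z <- forwardsolve(t(m$chol), x - m$mu)
    -0.5 * m$logdet - 0.5 * sum(z^2) + log(m$prior)
  }, numeric(1))
}

#' Leave-one-out quadratic discriminant classification of age group
#'
#' Per fold, class-conditional Gaussians with class-specific
#' shrinkage-regularized covariances and priors equal to the training class
#' frequencies; the held-out subject is assigned to the class with the
#' largest discriminant
#' `-log|S_k|/2 - (x - mu_k)' S_k^{-1} (x - mu_k)/2 + log pi_k`.
#'
#' @param features subjects x features matrix
#' @param group class labels (factor or character)
#' @param shrink ridge added to each class covariance, as a fraction of
#'   `tr(S_k)/p` (default 1e-6)
#' @return object of class `confusion`: `counts` (true x predicted),
#'   `normalized` (rows sum to 1), `accuracy`, `ci95` (exact binomial),
#'   `nir` and `p_vs_nir` (one-sided exact binomial test)
#' @export
qda_loocv <- function(features, group, shrink = 1e-6) {
  X <- as.matrix(features)
  y <- factor(group)
  if (any(table(y) < 2)) stop("every class needs at least two subjects")
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    models <- qda_train(X[-i, , drop = FALSE], droplevels(y[-i]), shrink)
    d <- qda_discriminants(models, X[i, ])
    pred[i] <- names(d)[which.max(d)]
  }
  pred <- factor(pred, levels = levels(y))
  counts <- table(true = y, predicted = pred)
  correct <- sum(diag(counts))
  accuracy <- correct / n
  ci <- binom.test(correct, n)$conf.int
  nir <- max(table(y)) / n
  structure(
    list(counts = counts,
         normalized = sweep(counts, 1, rowSums(counts), "/"),
         accuracy = accuracy, ci95 = c(ci[1], ci[2]),
         nir = nir, p_vs_nir = nir_test(correct, n, nir),
         predictions = pred),
    class = "confusion"
  )
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("LOO QDA: accuracy %.0f%% (95%% CI [%.2f %.2f]), NIR %.2f, p vs NIR = %.3g\n",
              100 * x$accuracy, x$ci95[1], x$ci95[2], x$nir, x$p_vs_nir))
  cat("Confusion matrix (row-normalized):\n")
  print(round(x$normalized, 2))
  invisible(x)
}

#' Exact binomial test against the no-information rate
#'
#' One-sided tail probability `P(X >= correct)` for
#' `X ~ Binomial(n, nir)`.
#'
#' @param correct number of correct classifications
#' @param n number of subjects
#' @param nir no-information rate (largest class share), in (0, 1)
#' @return p-value
#' @export
nir_test <- function(correct, n, nir) {
  stopifnot(correct >= 0, correct <= n, nir > 0, nir < 1)
  pbinom(correct - 1, n, nir, lower.tail = FALSE)
}
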