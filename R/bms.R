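# Random-effects Bayesian model selection over subjects: variational
# Dirichlet scheme, exceedance probabilities, Bayes omnibus risk and
# protected exceedance probabilities.

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across subjects with a
#' Dirichlet prior over model frequencies (uniform counts `alpha0 = 1`).
#' Posterior counts come from the usual variational scheme; exceedance
#' probabilities (xp) quantify how likely each model is the most frequent
#' one, and the protected version (pxp) discounts them by the Bayes omnibus
#' risk (bor) that all models are equally frequent:
#' `pxp = (1 - bor) * xp + bor / K`.
#'
#' @param F subjects x models matrix of log evidences (free energies, nats);
#'   column names label the models
#' @param n_samples Monte-Carlo samples for xp when more than two models
#'   (default 1e6); with two models the exact Beta integral is used
#' @param seed seed for the Monte-Carlo draw
#' @param alpha0 prior Dirichlet counts (default 1 per model)
#' @param max_iter,tol variational convergence controls
#' @return object of class `bms_result`: `alpha`, `expected_r`, `xp`,
#'   `pxp`, `bor`, `u` (subject responsibilities), `converged`
#' @export
rfx_bms <- function(F, n_samples = 1e6, seed = NULL, alpha0 = 1,
                    max_iter = 500, tol = 1e-8) {
  F <- as.matrix(F)
  if (ncol(F) < 2) stop("need at least two models")
  if (nrow(F) < 2) stop("need at least two subjects")
  if (any(!is.finite(F))) stop("non-finite log evidences")
  N <- nrow(F); K <- ncol(F)
  if (is.null(colnames(F))) colnames(F) <- paste0("model", seq_len(K))
  a0 <- rep(alpha0, K)
  alpha <- a0 + N / K
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lr <- digamma(alpha) - digamma(sum(alpha))
    lu <- sweep(F, 2, lr, "+")
    lu <- lu - apply(lu, 1, logsumexp)
    u <- exp(lu)
    alpha_new <- a0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new; converged <- TRUE; break
    }
    alpha <- alpha_new
  }
  if (!converged)
    warning("RFX BMS variational scheme did not converge within max_iter")
  xp <- exceedance_prob(alpha, n_samples = n_samples, seed = seed)
  # Bayes omnibus risk: null model (equal frequencies) vs RFX alternative
  F0 <- sum(apply(F, 1, logsumexp) - log(K))
  lr <- digamma(alpha) - digamma(sum(alpha))
  lu <- sweep(F, 2, lr, "+")
  lu <- lu - apply(lu, 1, logsumexp)
  u <- exp(lu)
  data_term <- sum(u * (sweep(F, 2, lr, "+") - lu))
  kl_r <- lgamma(sum(alpha)) - sum(lgamma(alpha)) -
    lgamma(sum(a0)) + sum(lgamma(a0)) +
    sum((alpha - a0) * (digamma(alpha) - digamma(sum(alpha))))
  F1 <- data_term - kl_r
  bor <- 1 / (1 + exp(F1 - F0))
  pxp <- (1 - bor) * xp + bor / K
  structure(
    list(alpha = setNames(alpha, colnames(F)),
         expected_r = setNames(alpha / sum(alpha), colnames(F)),
         xp = setNames(xp, colnames(F)),
         pxp = setNames(pxp, colnames(F)),
         bor = bor, u = u, F1 = F1, F0 = F0, converged = converged),
    class = "bms_result"
  )
}

#' Exceedance probabilities of a Dirichlet belief
#'
#' Probability that each component of a Dirichlet-distributed frequency
#' vector is the largest. Exact (Beta tail) for two components; Monte Carlo
#' otherwise.
#'
#' @param alpha Dirichlet counts
#' @param n_samples Monte-Carlo sample count for K > 2
#' @param seed optional seed
#' @return probability vector summing to 1
#' @export
exceedance_prob <- function(alpha, n_samples = 1e6, seed = NULL) {
  K <- length(alpha)
  if (K == 2) {
    xp1 <- 1 - pbeta(0.5, alpha[1], alpha[2])
    return(c(xp1, 1 - xp1))
  }
  with_seed(seed, {
    counts <- integer(K)
    remaining <- n_samples
    chunk <- 1e5
    while (remaining > 0) {
      nb <- min(chunk, remaining)
      g <- matrix(rgamma(nb * K, shape = rep(alpha, each = nb)), nb, K)
      w <- max.col(g, ties.method = "first")
      counts <- counts + tabulate(w, K)
      remaining <- remaining - nb
    }
    counts / n_samples
  })
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Random-effects Bayesian model selection\n")
  out <- data.frame(model = names(x$alpha), alpha = x$alpha,
                    expected_r = x$expected_r, xp = x$xp, pxp = x$pxp)
  print(out, row.names = FALSE, digits = 4)
  cat(sprintf("Bayes omnibus risk: %.4f\n", x$bor))
  invisible(x)
}

#' Collect an evidence table from lists of fits
#'
#' @param ... named lists of `dcm_fit` objects, one list per model, all of
#'   the same length (subjects aligned)
#' @return subjects x models matrix of free energies
#' @export
evidence_table <- function(...) {
  fits <- list(...)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  n <- unique(vapply(fits, length, integer(1)))
  if (length(n) != 1) stop("model fit lists have different lengths")
  F <- vapply(fits, function(fl) vapply(fl, function(f) f$F, numeric(1)),
              numeric(n))
  matrix(F, nrow = n, dimnames = list(NULL, names(fits)))
}
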