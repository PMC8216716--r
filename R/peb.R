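# Second-level hierarchical (parametric empirical Bayes) model over
# subject-level coupling posteriors, Bayesian model reduction, greedy
# search with Bayesian model averaging, and empirical-Bayes subject updates.

#' Second-level design matrix
#'
#' Columns: intercept (commonalities), mean-centred performance,
#' mean-centred ordinal age-group code, and the mean-centred product of the
#' two centred columns (interaction). With `coding = "dummy"`, centred
#' indicator columns for each non-reference group (and their performance
#' interactions) replace the ordinal column.
#'
#' @param performance numeric performance scores
#' @param age_group group labels (factor or character); ordinal codes follow
#'   the factor level order
#' @param coding `"ordinal"` (default) or `"dummy"`
#' @return matrix with attribute `"names"`; columns after the first are
#'   mean-centred
#' @export
build_design_matrix <- function(performance, age_group,
                                coding = c("ordinal", "dummy")) {
  coding <- match.arg(coding)
  if (length(performance) != length(age_group)) stop("length mismatch")
  age_group <- factor(age_group)
  if (nlevels(age_group) < 2) stop("need at least two distinct groups")
  if (sd(performance) == 0)
    warning("constant performance: degenerate regressor")
  cp <- performance - mean(performance)
  if (coding == "ordinal") {
    ca <- as.numeric(age_group) - mean(as.numeric(age_group))
    inter <- cp * ca
    X <- cbind(commonalities = 1, performance = cp, age_group = ca,
               interaction = inter - mean(inter))
  } else {
    ind <- stats::model.matrix(~age_group)[, -1, drop = FALSE]
    ind <- scale(ind, scale = FALSE)
    inter <- ind * cp
    inter <- scale(inter, scale = FALSE)
    colnames(ind) <- paste0("age_", levels(age_group)[-1])
    colnames(inter) <- paste0("interaction_", levels(age_group)[-1])
    X <- cbind(commonalities = 1, performance = cp, ind, inter)
  }
  rownames(X) <- names(performance)
  X
}

#' Bayesian model reduction
#'
#' Closed-form posterior and change in log evidence of a model whose prior
#' has been reduced, given the full model's prior and posterior. With
#' precisions `P0` (full prior), `P` (full posterior) and `R0` (reduced
#' prior): `P_r = P + R0 - P0`,
#' `mu_r = P_r^{-1} (P mu + R0 nu0 - P0 mu0)`, and the evidence change is
#' the corresponding Gaussian normalization ratio.
#'
#' @param full_prior,full_post,reduced_prior Gaussian beliefs: lists with
#'   `mean` and `cov`
#' @return list with `dF` (nats) and `reduced_post` (mean, cov)
#' @export
bmr <- function(full_prior, full_post, reduced_prior) {
  P0 <- solve(symm(full_prior$cov))
  P <- solve(symm(full_post$cov))
  R0 <- solve(symm(reduced_prior$cov))
  bmr_prec(P0, full_prior$mean, P, full_post$mean, R0, reduced_prior$mean)
}

# precision-parameterized BMR core (avoids repeated inversions in loops)
bmr_prec <- function(P0, mu0, P, mu, R0, nu0) {
  Pr <- symm(P + R0 - P0)
  ok <- is_pd(Pr)
  if (!ok) stop("improper reduction: reduced posterior precision is not positive definite")
  rhs <- drop(P %*% mu + R0 %*% nu0 - P0 %*% mu0)
  mur <- drop(solve(Pr, rhs))
  dF <- 0.5 * (logdet_pd(R0) - logdet_pd(symm(P0)) + logdet_pd(symm(P)) -
                 logdet_pd(Pr)) +
    0.5 * (drop(t(mu0) %*% P0 %*% mu0) - drop(t(nu0) %*% R0 %*% nu0) +
             drop(t(mur) %*% Pr %*% mur) - drop(t(mu) %*% P %*% mu))
  list(dF = dF, reduced_post = list(mean = mur, cov = solve(Pr)))
}

#' Fit a parametric empirical Bayes model over subjects' couplings
#'
#' Hierarchical Gaussian GLM: subject coupling vectors are modelled as
#' `theta_i = X_i beta + eps_i` with isotropic random effects of log
#' precision `gamma`. The second-level free energy scores candidate
#' `(beta, gamma)` through Bayesian model reduction of each subject's
#' first-level posterior (no spectra are revisited). Given `gamma` the free
#' energy is exactly quadratic in `beta`, so `beta` is updated in closed
#' form; `gamma` follows a damped Newton ascent, accepted only when the free
#' energy increases.
#'
#' @param fits list of `dcm_fit` objects sharing one coupling
#'   parameterization, or a list with elements `mu` (list of posterior mean
#'   vectors), `Sigma` (list of posterior covariances), `prior`
#'   (first-level prior: `mean`, `cov`)
#' @param X design matrix from [build_design_matrix()] (rows align with fits)
#' @param priors list: `beta_var` (prior variance of each second-level
#'   effect, default 1/8), `gamma_mean` and `gamma_var` (hyperprior on the
#'   random-effects log precision, defaults 4 and 1/64)
#' @param max_iter,tol ascent controls
#' @return object of class `peb_fit`: `beta` (mean, cov; regressor-major
#'   effect order), `F`, `rfx_precision` (gamma), `trace`, plus the subject
#'   summaries needed for model search and extraction
#' @export
fit_peb <- function(fits, X, priors = list(), max_iter = 32, tol = 1e-4) {
  pr <- modifyList(list(beta_var = 1 / 8, gamma_mean = 4, gamma_var = 1 / 64),
                   priors)
  subj <- peb_subject_summaries(fits)
  p <- length(subj$mu[[1]])
  N <- length(subj$mu)
  if (nrow(X) != N) stop("design matrix rows do not align with fits")
  R <- ncol(X)
  # regressor-major effect order: all couplings for regressor 1, then 2, ...
  enames <- as.vector(t(outer(colnames(X), subj$names, paste, sep = ":")))
  P0 <- solve(symm(subj$prior$cov))
  mu0 <- subj$prior$mean
  Pis <- lapply(subj$Sigma, function(S) solve(symm(S)))
  cts <- lapply(seq_len(N), function(i) drop(Pis[[i]] %*% subj$mu[[i]] - P0 %*% mu0))
  mu_terms <- vapply(seq_len(N), function(i)
    drop(t(subj$mu[[i]]) %*% Pis[[i]] %*% subj$mu[[i]]), numeric(1))
  const0 <- 0.5 * drop(t(mu0) %*% P0 %*% mu0) * N - 0.5 * sum(mu_terms) -
    0.5 * N * logdet_pd(symm(P0))
  ldP <- vapply(Pis, function(P) logdet_pd(symm(P)), numeric(1))
  Sb_inv <- diag(1 / pr$beta_var, R * p)

  objective <- function(gamma) {
    R0 <- diag(exp(gamma), p)
    ldR0 <- p * gamma
    H <- Sb_inv
    a <- numeric(R * p)
    ksum <- const0 + 0.5 * N * ldR0 + 0.5 * sum(ldP)
    for (i in seq_len(N)) {
      Pr <- symm(Pis[[i]] + R0 - P0)
      if (!is_pd(Pr)) return(NULL)
      cPr <- chol(Pr)
      Pri_ct <- backsolve(cPr, forwardsolve(t(cPr), cts[[i]]))
      Pri_R0 <- backsolve(cPr, forwardsolve(t(cPr), R0))
      Gi_small <- R0 - R0 %*% Pri_R0            # p x p
      ai_small <- drop(R0 %*% Pri_ct)           # p
      Mi <- X[i, ]                              # length R; M_i = X_i (x) I_p
      # accumulate kron-structured quadratic form
      H <- H + kronecker(tcrossprod(Mi), Gi_small)
      a <- a + kronecker(Mi, ai_small)
      ksum <- ksum - 0.5 * 2 * sum(log(diag(cPr))) +
        0.5 * drop(t(cts[[i]]) %*% Pri_ct)
    }
    H <- symm(H)
    cH <- chol(H)
    Hinv_a <- backsolve(cH, forwardsolve(t(cH), a))
    klg <- (gamma - pr$gamma_mean)^2 / (2 * pr$gamma_var)
    Fv <- ksum + 0.5 * sum(a * Hinv_a) - sum(log(diag(cH))) -
      0.5 * (R * p) * log(pr$beta_var) - klg
    list(F = Fv, beta = Hinv_a, H = H)
  }

  gamma <- pr$gamma_mean
  cur <- objective(gamma)
  if (is.null(cur)) stop("random-effects precision at the hyperprior mean yields an improper reduction")
  step <- 1
  trace <- data.frame(iter = 0L, F = cur$F, gamma = gamma)
  for (iter in seq_len(max_iter)) {
    eps <- 1e-3
    up <- objective(gamma + eps); dn <- objective(gamma - eps)
    if (is.null(up) || is.null(dn)) break
    g1 <- (up$F - dn$F) / (2 * eps)
    g2 <- (up$F - 2 * cur$F + dn$F) / eps^2
    delta <- if (is.finite(g2) && g2 < 0) -g1 / g2 else sign(g1)
    delta <- sign(delta) * min(abs(delta), 2)
    accepted <- FALSE
    for (try in seq_len(8)) {
      cand_gamma <- gamma + step * delta
      cand <- objective(cand_gamma)
      if (!is.null(cand) && cand$F > cur$F) {
        dF <- cand$F - cur$F
        gamma <- cand_gamma; cur <- cand
        step <- min(step * 2, 1)
        accepted <- TRUE
        trace <- rbind(trace, data.frame(iter = iter, F = cur$F, gamma = gamma))
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    if (nrow(trace) >= 2 &&
        abs(trace$F[nrow(trace)] - trace$F[nrow(trace) - 1]) < tol) break
  }
  beta_cov <- solve(cur$H)
  structure(
    list(beta = list(mean = setNames(cur$beta, enames), cov = beta_cov),
         F = cur$F, rfx_precision = gamma,
         beta_prior = list(mean = setNames(rep(0, R * p), enames),
                           cov = diag(pr$beta_var, R * p)),
         X = X, edge_names = subj$names, trace = trace,
         subjects = subj, priors = pr),
    class = "peb_fit"
  )
}

# extract per-subject coupling posteriors (marginal over the couplings) and
# their shared first-level prior
peb_subject_summaries <- function(fits) {
  if (!is.null(fits$mu)) return(fits)
  stopifnot(all(vapply(fits, inherits, logical(1), "dcm_fit")))
  ne <- length(fits[[1]]$model$theta_A)
  names1 <- names(fits[[1]]$model$theta_A)
  for (f in fits) {
    if (!identical(names(f$model$theta_A), names1))
      stop("subjects do not share the same coupling parameterization")
  }
  idx <- seq_len(ne)
  list(
    mu = lapply(fits, function(f) f$posterior$mean[idx]),
    Sigma = lapply(fits, function(f) f$posterior$cov[idx, idx, drop = FALSE]),
    prior = list(mean = fits[[1]]$model$priors$mean[idx],
                 cov = fits[[1]]$model$priors$cov[idx, idx, drop = FALSE]),
    names = names1
  )
}

#' @export
print.peb_fit <- function(x, ...) {
  cat(sprintf("PEB fit: %d subjects, %d effects (%d regressors x %d couplings)\n",
              nrow(x$X), length(x$beta$mean), ncol(x$X), length(x$edge_names)))
  cat(sprintf("  F = %.2f, random-effects log precision = %.2f (sd %.3f)\n",
              x$F, x$rfx_precision, exp(-x$rfx_precision / 2)))
  invisible(x)
}

#' @export
coef.peb_fit <- function(object, ...) object$beta$mean

#' @export
summary.peb_fit <- function(object, ...) {
  data.frame(effect = names(object$beta$mean),
             estimate = unname(object$beta$mean),
             sd = sqrt(diag(object$beta$cov)))
}

#' Greedy search over nested second-level models with Bayesian model
#' averaging
#'
#' Reduced models switch subsets of second-level effects off by shrinking
#' their prior variance to (near) zero. With at most `exhaustive_limit`
#' candidate effects the search enumerates all on/off combinations;
#' otherwise it repeatedly scores each remaining effect by the evidence
#' change when removed alone, exhaustively searches the `exhaustive_limit`
#' least-contributing ones, permanently prunes those switched off in the
#' best model, and stops when no further pruning occurs. Parameters are then
#' averaged over the final model set weighted by a softmax of their
#' evidences; each effect's posterior probability is the summed weight of
#' the models that contain it.
#'
#' @param peb a `peb_fit`
#' @param threshold retention threshold on the posterior probability
#'   (default 0.95; retained effects have `pp > threshold` strictly)
#' @param exhaustive_limit block size for exhaustive enumeration (default 8)
#' @param f_drop models whose evidence is more than this many nats below the
#'   best are dropped from the average (default 20)
#' @return object of class `bma_result`: data frame `effects` (name, mean,
#'   sd, pp, retained), the searched `models`, and bookkeeping fields
#' @export
greedy_search_bma <- function(peb, threshold = 0.95, exhaustive_limit = 8,
                              f_drop = 20) {
  stopifnot(inherits(peb, "peb_fit"))
  post <- peb$beta
  prior <- peb$beta_prior
  K <- length(post$mean)
  P0 <- solve(symm(prior$cov))
  P <- solve(symm(post$cov))
  pinned_var <- 1e-8
  score <- function(off) {
    # reduced prior: pinned effects get (near) zero variance, mean zero
    v <- diag(prior$cov)
    v[off] <- pinned_var
    R0 <- diag(1 / v, K)
    bmr_prec(P0, prior$mean, P, post$mean, R0, rep(0, K))
  }
  free <- seq_len(K)
  pruned <- integer(0)
  repeat {
    if (length(free) <= exhaustive_limit) {
      block <- free
    } else {
      dF1 <- vapply(free, function(j) score(c(pruned, j))$dF, numeric(1))
      block <- free[order(dF1, decreasing = TRUE)][seq_len(exhaustive_limit)]
    }
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(block)))
    models <- lapply(seq_len(nrow(combos)), function(r) {
      off <- c(pruned, block[unlist(combos[r, ])])
      s <- score(off)
      list(off = off, dF = s$dF, post = s$reduced_post)
    })
    dFs <- vapply(models, function(m) m$dF, numeric(1))
    best <- models[[which.max(dFs)]]
    newly_pruned <- setdiff(best$off, pruned)
    if (length(free) <= exhaustive_limit || length(newly_pruned) == 0) {
      final <- models
      break
    }
    pruned <- sort(unique(best$off))
    free <- setdiff(seq_len(K), pruned)
  }
  dFs <- vapply(final, function(m) m$dF, numeric(1))
  keep <- dFs > max(dFs) - f_drop
  final <- final[keep]; dFs <- dFs[keep]
  w <- exp(dFs - logsumexp(dFs))
  mean_bma <- numeric(K); m2 <- numeric(K); pp <- numeric(K)
  for (j in seq_along(final)) {
    mu <- final[[j]]$post$mean
    v <- diag(final[[j]]$post$cov)
    mean_bma <- mean_bma + w[j] * mu
    m2 <- m2 + w[j] * (v + mu^2)
    on <- setdiff(seq_len(K), final[[j]]$off)
    pp[on] <- pp[on] + w[j]
  }
  sd_bma <- sqrt(pmax(m2 - mean_bma^2, 0))
  effects <- data.frame(effect = names(post$mean), mean = mean_bma,
                        sd = sd_bma, pp = pp, retained = pp > threshold)
  structure(
    list(effects = effects, threshold = threshold,
         n_models = length(final),
         model_weights = w,
         model_offsets = lapply(final, function(m) m$off),
         pruned = pruned),
    class = "bma_result"
  )
}

#' @export
print.bma_result <- function(x, ...) {
  cat(sprintf("Bayesian model average over %d reduced models (threshold %.2f)\n",
              x$n_models, x$threshold))
  sel <- x$effects[x$effects$retained, , drop = FALSE]
  if (nrow(sel) == 0) cat("No effects retained.\n")
  else print(sel, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Empirical-Bayes subject-level coupling estimates
#'
#' Re-evaluates each subject's coupling posterior using the group-level
#' prediction `X_i beta` as an empirical prior with the fitted
#' between-subject (co)variance: a precision-weighted combination of the
#' first-level posterior and the group prediction. As the between-subject
#' variance grows the estimates tend to the first-level means; as it
#' vanishes they tend to `X_i beta`.
#'
#' @param peb a `peb_fit`
#' @param bma optional `bma_result`; when given, group predictions use the
#'   model-averaged effects
#' @param gamma override for the random-effects log precision
#' @return subjects x couplings matrix of updated posterior means
#' @export
extract_subject_estimates <- function(peb, bma = NULL, gamma = NULL) {
  stopifnot(inherits(peb, "peb_fit"))
  beta <- if (is.null(bma)) peb$beta$mean else bma$effects$mean
  if (is.null(gamma)) gamma <- peb$rfx_precision
  p <- length(peb$edge_names)
  N <- nrow(peb$X)
  Bmat <- matrix(beta, nrow = p)  # couplings x regressors (regressor-major vec)
  out <- matrix(NA_real_, N, p, dimnames = list(rownames(peb$X), peb$edge_names))
  R0 <- diag(exp(gamma), p)
  for (i in seq_len(N)) {
    m_i <- drop(Bmat %*% peb$X[i, ])
    Pi <- solve(symm(peb$subjects$Sigma[[i]]))
    Pc <- Pi + R0
    out[i, ] <- drop(solve(Pc, Pi %*% peb$subjects$mu[[i]] + R0 %*% m_i))
  }
  out
}
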