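test_that("design matrix columns are centred and follow the stated layout", {
  X <- build_design_matrix(c(0, 1), c(1, 2))
  expect_equal(colnames(X), c("commonalities", "performance", "age_group",
                              "interaction"))
  expect_equal(unname(X[, "commonalities"]), c(1, 1))
  expect_equal(unname(X[, "performance"]), c(-0.5, 0.5))
  expect_equal(unname(X[, "age_group"]), c(-0.5, 0.5))
  # centred product of the two centred columns is (0.25, 0.25) -> (0, 0)
  expect_equal(unname(X[, "interaction"]), c(0, 0))

  set.seed(40)
  perf <- rnorm(20)
  grp <- sample(rep(1:4, 5))
  X2 <- build_design_matrix(perf, grp)
  expect_true(all(abs(colMeans(X2[, -1])) < 1e-10))
  # permuting subjects permutes rows identically
  idx <- sample(20)
  X3 <- build_design_matrix(perf[idx], grp[idx])
  expect_equal(unname(X3), unname(X2[idx, ]))
  expect_warning(build_design_matrix(rep(1, 4), c(1, 1, 2, 2)), "constant")
  # dummy coding produces per-group contrasts
  Xd <- build_design_matrix(perf, grp, coding = "dummy")
  expect_equal(ncol(Xd), 8)
})

test_that("Bayesian model reduction matches conjugate linear-Gaussian
          evidence differences", {
  set.seed(41)
  # y = theta + noise; evidence under any Gaussian prior is closed form
  lambda <- 2
  y <- c(0.8, -0.5)
  full_prior <- list(mean = c(0, 0), cov = diag(1, 2))
  post <- gaussian_posterior(y, full_prior$mean, full_prior$cov, lambda)
  # identical reduction changes nothing
  same <- bmr(full_prior, post, full_prior)
  expect_equal(same$dF, 0, tolerance = 1e-10)
  expect_equal(same$reduced_post$mean, post$mean, tolerance = 1e-10)

  # pin the second parameter to zero (variance 1e-8)
  red_prior <- list(mean = c(0, 0), cov = diag(c(1, 1e-8)))
  red <- bmr(full_prior, post, red_prior)
  ev_full <- gaussian_log_evidence(y, full_prior$mean, full_prior$cov, lambda)
  ev_red <- gaussian_log_evidence(y, red_prior$mean, red_prior$cov, lambda)
  expect_equal(red$dF, as.numeric(ev_red - ev_full), tolerance = 1e-3)
  # the reduced posterior matches the directly computed one
  direct <- gaussian_posterior(y, red_prior$mean, red_prior$cov, lambda)
  expect_equal(red$reduced_post$mean, direct$mean, tolerance = 1e-4)

  # pinning a parameter whose posterior sits far from zero loses evidence
  y2 <- c(0.1, 3)
  post2 <- gaussian_posterior(y2, full_prior$mean, full_prior$cov, lambda)
  expect_lt(bmr(full_prior, post2, red_prior)$dF, 0)
})

test_that("PEB estimates match a closed-form hierarchical evidence oracle on
          a small problem", {
  toy <- toy_peb_input(n = 24, p = 2, beta = c(0.5, -0.3, 0.2, 0.1),
                       gamma = 3, obs_sd = 0.1,
                       X = cbind(commonalities = 1,
                                 covariate = scale(1:24, scale = FALSE)[, 1]),
                       seed = 42)
  pr <- list(beta_var = 1 / 8, gamma_mean = 4, gamma_var = 1 / 64)
  peb <- fit_peb(toy$fits, toy$X, priors = pr)
  expect_true(all(diff(peb$trace$F) >= 0))

  # oracle: the toy first level is linear-Gaussian, so the marginal evidence
  # of (gamma) with beta integrated out is exactly Gaussian
  n <- nrow(toy$X); p <- 2
  M <- kronecker(toy$X, diag(p))
  Yv <- as.vector(t(toy$y))
  oracle <- function(gamma) {
    S <- pr$beta_var * tcrossprod(M) +
      diag(exp(-gamma) + toy$obs_sd^2, n * p)
    -0.5 * determinant(S)$modulus - 0.5 * drop(t(Yv) %*% solve(S, Yv)) -
      (gamma - pr$gamma_mean)^2 / (2 * pr$gamma_var)
  }
  gam_oracle <- optimize(function(g) -as.numeric(oracle(g)), c(0, 10))$minimum
  expect_equal(peb$rfx_precision, gam_oracle, tolerance = 0.05)
  # beta posterior mean oracle at the fitted gamma (ridge form)
  V <- exp(-peb$rfx_precision) + toy$obs_sd^2
  H <- crossprod(M) / V + diag(1 / pr$beta_var, ncol(M))
  beta_oracle <- solve(H, crossprod(M, Yv) / V)
  expect_equal(unname(peb$beta$mean), drop(beta_oracle), tolerance = 1e-3)
})

test_that("with an intercept-only design and homogeneous subjects the group
          effect shrinks to the average coupling", {
  toy <- toy_peb_input(n = 12, p = 2, beta = c(0.4, -0.2), gamma = 6,
                       obs_sd = 0.05, seed = 43)
  peb <- fit_peb(toy$fits, toy$X)
  avg <- rowMeans(vapply(toy$fits$mu, identity, numeric(2)))
  sds <- sqrt(diag(peb$beta$cov))
  expect_true(all(abs(peb$beta$mean - avg) < 2 * sds + 0.05))
})

test_that("greedy search reproduces exhaustive enumeration exactly on small
          problems", {
  toy <- toy_peb_input(n = 16, p = 3, beta = c(0.5, 0, 0, 0, 0.4, 0),
                       gamma = 4, obs_sd = 0.1,
                       X = cbind(commonalities = 1,
                                 covariate = scale(rnorm(16), scale = FALSE)[, 1]),
                       seed = 44)
  peb <- fit_peb(toy$fits, toy$X)
  bma <- greedy_search_bma(peb, f_drop = Inf)
  # independent enumeration over all 2^6 on/off patterns via bmr()
  K <- 6
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), K))
  dFs <- numeric(nrow(combos)); posts <- vector("list", nrow(combos))
  for (r in seq_len(nrow(combos))) {
    v <- diag(peb$beta_prior$cov)
    v[unlist(combos[r, ])] <- 1e-8
    red <- bmr(peb$beta_prior, peb$beta,
               list(mean = rep(0, K), cov = diag(v, K)))
    dFs[r] <- red$dF
    posts[[r]] <- red$reduced_post
  }
  w <- exp(dFs - max(dFs)); w <- w / sum(w)
  pp_oracle <- numeric(K); mean_oracle <- numeric(K)
  for (r in seq_len(nrow(combos))) {
    on <- !unlist(combos[r, ])
    pp_oracle[on] <- pp_oracle[on] + w[r]
    mean_oracle <- mean_oracle + w[r] * posts[[r]]$mean
  }
  expect_equal(bma$effects$pp, pp_oracle, tolerance = 1e-10)
  expect_equal(bma$effects$mean, mean_oracle, tolerance = 1e-10)
})

test_that("posterior probabilities do not depend on effect ordering", {
  toy <- toy_peb_input(n = 16, p = 3, beta = c(0.5, 0.2, 0), gamma = 4,
                       obs_sd = 0.1, seed = 45)
  peb1 <- fit_peb(toy$fits, toy$X)
  # permute the couplings
  perm <- c(3, 1, 2)
  fits2 <- toy$fits
  fits2$mu <- lapply(fits2$mu, function(m) m[perm])
  fits2$Sigma <- lapply(fits2$Sigma, function(S) S[perm, perm])
  fits2$prior <- list(mean = fits2$prior$mean[perm],
                      cov = fits2$prior$cov[perm, perm])
  fits2$names <- fits2$names[perm]
  peb2 <- fit_peb(fits2, toy$X)
  pp1 <- greedy_search_bma(peb1)$effects
  pp2 <- greedy_search_bma(peb2)$effects
  expect_equal(pp2$pp[match(pp1$effect, pp2$effect)], pp1$pp,
               tolerance = 1e-8)
})

test_that("subject-level empirical-Bayes updates interpolate between the
          first-level means and the group prediction", {
  toy <- toy_peb_input(n = 10, p = 2, beta = c(0.4, -0.2), gamma = 4,
                       obs_sd = 0.1, seed = 46)
  peb <- fit_peb(toy$fits, toy$X)
  mu_first <- t(vapply(toy$fits$mu, identity, numeric(2)))
  # between-subject variance -> infinity: estimates equal first-level means
  est_inf <- extract_subject_estimates(peb, gamma = -30)
  expect_equal(unname(est_inf), unname(mu_first), tolerance = 1e-8)
  # between-subject variance -> 0: estimates equal the group prediction
  est0 <- extract_subject_estimates(peb, gamma = 30)
  pred <- toy$X %*% t(matrix(peb$beta$mean, nrow = 2))
  expect_equal(unname(est0), unname(pred), tolerance = 1e-8)
  # scalar case: precision-weighted convex combination
  gmid <- 4
  est_mid <- extract_subject_estimates(peb, gamma = gmid)
  Pi <- solve(toy$fits$Sigma[[1]])
  for (i in c(1, 5)) {
    m_i <- drop(matrix(peb$beta$mean, nrow = 2) %*% toy$X[i, ])
    byhand <- solve(Pi + diag(exp(gmid), 2),
                    Pi %*% toy$fits$mu[[i]] + exp(gmid) * m_i)
    expect_equal(unname(est_mid[i, ]), drop(byhand), tolerance = 1e-10)
  }
})
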