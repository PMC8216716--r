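test_that("free energy has zero KL terms at the prior belief and hyperprior
          mean, and equals the conjugate evidence at the exact posterior", {
  set.seed(30)
  K <- 3
  m0 <- c(0.2, -0.1, 0); C0 <- diag(c(0.5, 1, 2))
  lambda <- 2
  y <- rnorm(K)
  f <- function(par) par  # identity forward map
  hyper <- list(hE = lambda, hC = 1 / 4)
  Fprior <- laplace_free_energy(y, f, q = list(mean = m0, cov = C0),
                                lambda = lambda, prior = list(mean = m0, cov = C0),
                                hyper = hyper)
  comp <- attr(Fprior, "components")
  expect_equal(unname(comp["kl_theta"]), 0, tolerance = 1e-10)
  expect_equal(unname(comp["kl_lambda"]), 0, tolerance = 1e-10)

  # at the analytic posterior, F equals the closed-form log evidence
  post <- gaussian_posterior(y, m0, C0, lambda)
  Fpost <- laplace_free_energy(y, f, q = post, lambda = lambda,
                               prior = list(mean = m0, cov = C0),
                               hyper = hyper)
  expect_equal(as.numeric(Fpost),
               as.numeric(gaussian_log_evidence(y, m0, C0, lambda)),
               tolerance = 1e-6)
})

test_that("an irrelevant extra parameter does not increase the free energy at
          the optimum (Occam property on a conjugate toy)", {
  set.seed(31)
  lambda <- 3
  for (rep in 1:5) {
    theta <- rnorm(1, sd = 1)
    y2 <- c(theta, theta) + rnorm(2, sd = exp(-lambda / 2))
    # small model: one parameter replicated to both observations
    f1 <- function(p) c(p, p)
    # larger model: second parameter adds an independent offset to y[2]
    f2 <- function(p) c(p[1], p[1] + p[2])
    # conjugate optima computed analytically through the linear maps
    X1 <- matrix(c(1, 1), 2, 1); X2 <- cbind(X1, c(0, 1))
    post_lin <- function(X, C0) {
      P <- solve(C0) + exp(lambda) * crossprod(X)
      S <- solve(P)
      list(mean = drop(S %*% (exp(lambda) * crossprod(X, y2))), cov = S)
    }
    q1 <- post_lin(X1, diag(1, 1)); q2 <- post_lin(X2, diag(1, 2))
    F1 <- laplace_free_energy(y2, f1, q1, lambda,
                              prior = list(mean = 0, cov = diag(1, 1)),
                              hyper = list(hE = lambda, hC = 1 / 4))
    F2 <- laplace_free_energy(y2, f2, q2, lambda,
                              prior = list(mean = c(0, 0), cov = diag(1, 2)),
                              hyper = list(hE = lambda, hC = 1 / 4))
    expect_lte(as.numeric(F2), as.numeric(F1) + 1e-6)
  }
})

test_that("variance explained follows the sum-of-squares formula", {
  f <- 4:5
  Gobs <- array(complex(real = c(1, 0, 0, 2, 2, 0, 0, 1)), c(2, 2, 2))
  pred <- new_csd(f, Gobs)
  obs <- new_csd(f, Gobs)
  expect_equal(variance_explained(pred, obs), 100)
  zero <- new_csd(f, array(0 + 0i, c(2, 2, 2)))
  expect_equal(variance_explained(zero, obs), 0)
  # hand-computed two-bin case
  Gp <- Gobs; Gp[1, 1, 1] <- 2 + 0i
  o <- c(Re(Gobs), Im(Gobs))
  p <- c(Re(Gp), Im(Gp))
  expect_equal(variance_explained(new_csd(f, Gp), obs),
               100 * (1 - sum((o - p)^2) / sum(o^2)))
  expect_error(variance_explained(zero, zero), "zero total variance")
})

test_that("fitting noiseless self-generated data from the truth is
          self-consistent", {
  m <- dcm_model()
  mt <- m
  mt$theta_A[c(3, 8)] <- c(0.3, -0.3)
  g <- predict(mt, 4:48)
  init <- c(mt$theta_A, 0)
  fit <- fit_dcm(g, m, opts = list(max_iter = 8, init = unname(init)))
  expect_gte(fit$r2, 99)
})

test_that("free energy is monotone over accepted iterations and the Jacobian
          path choice does not change the optimum", {
  m <- dcm_model()
  mt <- m
  mt$theta_A[c(1, 9)] <- c(0.35, -0.35)
  g <- predict(mt, 4:48)
  g$G <- specdcm:::add_spectral_noise(g$G, 0.02, seed = 77)
  fit <- fit_dcm(g, m, opts = list(max_iter = 16))
  expect_true(all(diff(fit$trace$F) >= 0))
  fit_fd <- fit_dcm(g, m, opts = list(max_iter = 16, jacobian = "fd"))
  expect_equal(coef(fit), coef(fit_fd), tolerance = 0.02)
  # posterior covariance is positive definite
  expect_true(all(eigen(fit$posterior$cov, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("planted couplings are recovered in sign and magnitude at low
          noise", {
  m <- dcm_model()
  edges <- c("forward:IPL->PMv", "backward:PMv->IPL", "backward:SMA->IPL")
  truth <- c(-0.4, 0.4, 0.4)
  ok <- 0
  for (r in 1:6) {
    mt <- m
    mt$theta_A[edges] <- truth
    g <- predict(mt, 4:48)
    g$G <- specdcm:::add_spectral_noise(g$G, 0.005, seed = 200 + r)
    fit <- fit_dcm(g, m, opts = list(max_iter = 24))
    est <- coef(fit)[edges]
    if (all(sign(est) == sign(truth)) && max(abs(est - truth)) < 0.15)
      ok <- ok + 1
  }
  expect_gte(ok, 5)
})

test_that("a parameter with vanishing prior variance stays at its prior mean", {
  m <- dcm_model()
  mt <- m
  mt$theta_A[["backward:PMv->IPL"]] <- 0.5
  g <- predict(mt, 4:48)
  m2 <- m
  j <- match("backward:PMv->IPL", names(m$priors$mean))
  m2$priors$cov[j, j] <- 1e-10
  fit <- fit_dcm(g, m2, opts = list(max_iter = 12))
  expect_lt(abs(fit$posterior$mean[j]), 1e-3)
})
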