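# Shared fixtures and independent oracles, all generated in code.

# Closed-form log evidence of the conjugate linear-Gaussian model
# y = theta + eps, theta ~ N(m0, C0), eps ~ N(0, exp(-lambda) I):
# y ~ N(m0, C0 + exp(-lambda) I).
gaussian_log_evidence <- function(y, m0, C0, lambda) {
  S <- C0 + diag(exp(-lambda), length(y))
  r <- y - m0
  -0.5 * (length(y) * log(2 * pi) + determinant(S)$modulus +
            drop(t(r) %*% solve(S, r)))
}

# analytic posterior of the same model
gaussian_posterior <- function(y, m0, C0, lambda) {
  P <- solve(C0) + diag(exp(lambda), length(y))
  S <- solve(P)
  list(mean = drop(S %*% (solve(C0, m0) + exp(lambda) * y)), cov = S)
}

# small low-noise cohort reused across tests (built once per test run)
small_cohort <- local({
  cache <- NULL
  function(n_per_group = c(3, 3, 3, 3), seed = 42) {
    key <- paste(c(n_per_group, seed), collapse = "-")
    if (!is.null(cache) && identical(cache$key, key)) return(cache$cohort)
    cohort <- generate_cohort(cohort_config(n_per_group = n_per_group,
                                            seed = seed))
    cache <<- list(key = key, cohort = cohort)
    cohort
  }
})

# toy PEB input: first-level linear-Gaussian posteriors for p couplings,
# y_i = theta_i + noise; returns the `fits` list format fit_peb accepts plus
# the raw data for independent oracles
toy_peb_input <- function(n = 6, p = 2, beta = c(0.5, -0.3), gamma = 4,
                          obs_sd = 0.1, X = NULL, seed = 1, prior_var = 1) {
  set.seed(seed)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "commonalities"))
  theta <- X %*% matrix(beta, ncol(X), p) +
    matrix(rnorm(n * p, sd = exp(-gamma / 2)), n, p)
  y <- theta + matrix(rnorm(n * p, sd = obs_sd), n, p)
  post_cov <- solve(diag(1 / prior_var, p) + diag(1 / obs_sd^2, p))
  mu <- lapply(seq_len(n), function(i)
    drop(post_cov %*% (y[i, ] / obs_sd^2)))
  names <- paste0("c", seq_len(p))
  list(fits = list(mu = lapply(mu, setNames, names),
                   Sigma = rep(list(post_cov), n),
                   prior = list(mean = setNames(rep(0, p), names),
                                cov = diag(prior_var, p)),
                   names = names),
       X = X, y = y, obs_sd = obs_sd, prior_var = prior_var)
}
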