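# Synthetic cohorts with known ground truth: subject couplings follow the
# second-level GLM the group analysis assumes, spectra come from the
# generative neural-mass model, and force traces reproduce each subject's
# planted performance score.

#' Default planted second-level effects
#'
#' A 4 x 14 matrix (regressors x couplings) mirroring the study's findings
#' qualitatively: performance raises backward PMv->IPL coupling and lowers
#' forward IPL->PMv coupling; age raises backward SMA->IPL coupling;
#' age-by-performance interactions act on forward PMv->DLPFC and backward
#' SMA->M1. All magnitudes `beta` (default 0.3 in log-scaling units).
#'
#' @param beta effect magnitude
#' @param net the network whose edges label the columns
#' @return matrix with regressor rownames and edge colnames
#' @export
default_planted_effects <- function(beta = 0.3, net = grasping_network()) {
  edges <- network_edges(net)
  eff <- matrix(0, 4, length(edges),
                dimnames = list(c("commonalities", "performance",
                                  "age_group", "interaction"), edges))
  eff["performance", "backward:PMv->IPL"] <- beta
  eff["performance", "forward:IPL->PMv"] <- -beta
  eff["age_group", "backward:SMA->IPL"] <- beta
  eff["interaction", "forward:PMv->DLPFC"] <- beta
  eff["interaction", "backward:SMA->M1"] <- beta
  eff
}

#' Configuration of a synthetic cohort
#'
#' Defaults emulate the study conditions: four age groups of 22, 19, 19 and
#' 28 subjects; 14 extrinsic couplings per subject generated from a
#' second-level GLM (intercept, performance, age group, interaction) with
#' isotropic random effects; cross-spectra over 4-48 Hz from the generative
#' model plus Hermitian observation noise; force traces at 10% of maximal
#' voluntary contraction whose tracking error reproduces the subject's
#' performance score.
#'
#' @param n_per_group subjects per age group
#' @param group_labels age-group names (ordinal order)
#' @param effects regressors x couplings effect matrix
#' @param re_sd between-subject coupling standard deviation
#' @param obs_noise spectral observation-noise scale, as a fraction of the
#'   mean diagonal spectral power
#' @param perf_group_means group means of the performance score (-ln rmse in
#'   newtons), ordered so adults perform best
#' @param perf_sd within-group performance standard deviation
#' @param age_ranges_months age range (months) sampled uniformly per group
#' @param trace_rate,trace_duration force-trace sampling (samples/s, s)
#' @param mvc maximal voluntary contraction (N); target line is
#'   `target * mvc`
#' @param target target force as a fraction of MVC
#' @param n_modes data modes of the lead field
#' @param freqs analysis frequencies (Hz)
#' @param seed master seed; all cohort randomness derives from it
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(n_per_group = c(22, 19, 19, 28),
                          group_labels = c("8-10", "12-14", "16-18", "20-30"),
                          effects = default_planted_effects(),
                          re_sd = 0.05,
                          obs_noise = 0.02,
                          perf_group_means = c(0.4, 0.7, 0.8, 1.1),
                          perf_sd = 0.3,
                          age_ranges_months = list(c(96, 131), c(144, 179),
                                                   c(192, 227), c(240, 371)),
                          trace_rate = 100, trace_duration = 120,
                          mvc = 60, target = 0.10,
                          n_modes = 4, freqs = 4:48, seed = 1) {
  stopifnot(re_sd >= 0, obs_noise >= 0, perf_sd >= 0,
            length(n_per_group) == length(group_labels),
            length(perf_group_means) == length(n_per_group),
            length(age_ranges_months) == length(n_per_group))
  structure(as.list(environment()), class = "cohort_config")
}

# deterministic covariates of the cohort (given the seed): group labels,
# performance scores, ages, and the second-level design matrix
cohort_covariates <- function(config) {
  with_seed(config$seed, {
    group <- factor(rep(config$group_labels, config$n_per_group),
                    levels = config$group_labels)
    n <- length(group)
    perf <- rnorm(n, mean = rep(config$perf_group_means, config$n_per_group),
                  sd = config$perf_sd)
    age <- vapply(as.integer(group), function(g)
      runif(1, config$age_ranges_months[[g]][1],
            config$age_ranges_months[[g]][2]), numeric(1))
    X <- build_design_matrix(perf, group)
    list(group = group, performance = perf, age_months = age, X = X, n = n)
  })
}

#' Ground-truth coupling parameters for one subject
#'
#' Implements the second-level generative assumption
#' `theta_i = X_i beta + eps_i`, `eps_i ~ N(0, re_sd^2 I)`, with the design
#' matrix built by [build_design_matrix()] from the cohort's covariates. The
#' random-effect draw uses a per-subject seed derived from the master seed,
#' so subjects are reproducible individually and as a cohort.
#'
#' @param config a `cohort_config`
#' @param subject_index subject number (1-based)
#' @param covariates optional precomputed [cohort_covariates()] result
#' @return named coupling vector (length 14 for the default network)
#' @export
sample_subject_parameters <- function(config, subject_index,
                                      covariates = NULL) {
  if (is.null(covariates)) covariates <- cohort_covariates(config)
  edges <- colnames(config$effects)
  mu <- drop(covariates$X[subject_index, ] %*% config$effects)
  eps <- with_seed(derive_seed(config$seed, subject_index),
                   rnorm(length(edges), sd = config$re_sd))
  setNames(mu + eps, edges)
}

#' Generate a full synthetic cohort
#'
#' Draws covariates and ground-truth couplings, evaluates each subject's
#' predicted cross-spectra from the neural-mass model (resampling the
#' random effects up to 10 times if a draw is dynamically unstable), adds
#' Hermitian positive-semidefinite observation noise in mode space, and
#' synthesizes a force trace (1/f-plus-white noise around the target line)
#' whose root-mean-square error reproduces the subject's performance score
#' exactly.
#'
#' @param config a `cohort_config`
#' @return object of class `synthetic_cohort`: `subjects` data frame
#'   (id, group, age_months, performance), `theta` (subjects x couplings
#'   ground truth), `spectra` (list of `csd`), `traces` (list of
#'   `force_trace`), `X`, `model` (the template `dcm_model`), `config`
#' @export
generate_cohort <- function(config) {
  cov <- cohort_covariates(config)
  template <- dcm_model(n_modes = config$n_modes,
                        leadfield_seed = config$seed + 7L)
  edges <- colnames(config$effects)
  n <- cov$n
  theta <- matrix(NA_real_, n, length(edges),
                  dimnames = list(NULL, edges))
  spectra <- vector("list", n)
  traces <- vector("list", n)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    mu <- drop(cov$X[i, ] %*% config$effects)
    th <- NULL
    for (attempt in 0:9) {
      eps <- with_seed(derive_seed(config$seed, i + attempt * 100000L),
                       rnorm(length(edges), sd = config$re_sd))
      cand <- setNames(mu + eps, edges)
      mod <- template
      mod$theta_A[] <- cand
      if (linearize(mod)$stable) { th <- cand; break }
    }
    if (is.null(th))
      stop("persistent dynamic instability for subject ", i)
    theta[i, ] <- th
    mod <- template
    mod$theta_A[] <- th
    g <- predict(mod, freqs = config$freqs)
    g$G <- add_spectral_noise(g$G, config$obs_noise,
                              seed = derive_seed(config$seed, 500000L + i))
    spectra[[i]] <- g
    scores[i] <- cov$performance[i]
    traces[[i]] <- synth_force_trace(
      score = scores[i], rate = config$trace_rate,
      duration = config$trace_duration, target = config$target,
      mvc = config$mvc, seed = derive_seed(config$seed, 900000L + i))
  }
  structure(
    list(subjects = data.frame(id = seq_len(n), group = cov$group,
                               age_months = cov$age_months,
                               performance = cov$performance),
         theta = theta, spectra = spectra, traces = traces,
         X = cov$X, model = template, config = config),
    class = "synthetic_cohort"
  )
}

# Hermitian observation noise in mode space: a centered complex
# Wishart-type perturbation per frequency bin (zero mean, emulating the
# estimation error of sample cross-spectra around the true spectrum), with
# eigenvalues clipped at zero so every bin remains a valid PSD matrix.
add_spectral_noise <- function(G, scale, seed = NULL) {
  if (scale == 0) return(G)
  m <- dim(G)[1]; nf <- dim(G)[3]
  pow <- mean(Re(apply(G, 3, diag)))
  with_seed(seed, {
    for (k in seq_len(nf)) {
      A <- matrix(complex(real = rnorm(m * m, sd = sqrt(0.5)),
                          imaginary = rnorm(m * m, sd = sqrt(0.5))), m, m)
      W <- (A %*% Conj(t(A))) / m - diag(m)
      Gk <- G[, , k] + scale * pow * W
      e <- eigen(Gk, symmetric = TRUE)
      d <- pmax(Re(e$values), 0)
      G[, , k] <- e$vectors %*% (d * Conj(t(e$vectors)))
    }
    G
  })
}

# force trace = target line + (1/f + white) noise scaled to an exact rmse
synth_force_trace <- function(score, rate, duration, target, mvc, seed) {
  rmse <- exp(-score)
  N <- round(rate * duration)
  with_seed(seed, {
    kpos <- seq_len(floor((N - 1) / 2))
    f <- kpos * rate / N
    # half the variance from a 1/f (pink) component, half white
    amp <- sqrt(1 / f) + sqrt(mean(1 / f))
    Z <- complex(real = rnorm(length(kpos), sd = sqrt(0.5)),
                 imaginary = rnorm(length(kpos), sd = sqrt(0.5)))
    X <- complex(length.out = N)
    X[kpos + 1] <- amp * Z
    X[N - kpos + 1] <- Conj(X[kpos + 1])
    e <- Re(fft(X, inverse = TRUE)) / N
    e <- e - mean(e)
    e <- e * rmse / sqrt(mean(e^2))
    force_trace(target * mvc + e, rate = rate, target = target, mvc = mvc)
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects in %d groups (%s)\n",
              nrow(x$subjects), nlevels(x$subjects$group),
              paste(table(x$subjects$group), collapse = ", ")))
  invisible(x)
}
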