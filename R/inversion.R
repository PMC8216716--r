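# First-level Bayesian inversion: variational Laplace on cross-spectral
# densities, Gauss-Newton/Levenberg-Marquardt ascent on the free energy with
# alternating parameter and log-precision updates.

# Laplace free energy given residuals e, local Jacobian J, log-precision
# lambda, parameter belief (m, Sigma) and priors. Single precision component
# across all residual elements.
fe_laplace <- function(e, J, lambda, m, Sigma, prior_mean, prior_cov,
                       hE, hC, lambda_var = NULL) {
  n <- length(e)
  K <- length(m)
  P0 <- solve(symm(prior_cov))
  el <- exp(lambda)
  tr_term <- sum((J %*% Sigma) * J)
  acc <- -0.5 * el * (sum(e^2) + tr_term) + 0.5 * n * lambda -
    0.5 * n * log(2 * pi)
  d <- m - prior_mean
  # KL(q(theta) || prior)
  kl_theta <- 0.5 * (sum(P0 * Sigma) + drop(t(d) %*% P0 %*% d) - K +
                       logdet_pd(prior_cov) - logdet_pd(symm(Sigma)))
  if (is.null(lambda_var)) {
    Hl <- -0.5 * el * (sum(e^2) + tr_term) - 1 / hC
    lambda_var <- -1 / Hl
  }
  kl_lambda <- 0.5 * ((lambda - hE)^2 / hC + lambda_var / hC - 1 -
                        log(lambda_var / hC))
  F <- acc - kl_theta - kl_lambda
  attr(F, "components") <- c(accuracy = acc, kl_theta = kl_theta,
                             kl_lambda = kl_lambda)
  F
}

#' Laplace free energy of a nonlinear-Gaussian model
#'
#' Evidence lower bound used by the inverter: expected log-likelihood of the
#' residuals `y - f(m)` under precision `exp(lambda)` (with the usual
#' curvature correction through the local Jacobian of `f`), minus the KL
#' divergence of the parameter belief from its prior, minus the KL
#' divergence over the log-precision.
#'
#' @param y data vector
#' @param f forward map taking a parameter vector to a prediction vector
#' @param q parameter belief: list with `mean` and `cov`
#' @param lambda log-precision of the observation noise
#' @param prior list with `mean` and `cov`
#' @param hyper list with `hE` (prior mean of lambda) and `hC` (its prior
#'   variance)
#' @param lambda_var posterior variance of lambda; defaults to `hyper$hC`,
#'   which makes the lambda KL term vanish at `lambda = hE`
#' @param fd_step central finite-difference step for the Jacobian
#' @return free energy in nats, with a `components` attribute
#' @export
laplace_free_energy <- function(y, f, q, lambda, prior,
                                hyper = list(hE = 18, hC = 1 / 128),
                                lambda_var = hyper$hC, fd_step = 1e-3) {
  if (!is_pd(symm(q$cov))) stop("belief covariance is not positive definite")
  J <- fd_jacobian(f, q$mean, fd_step)
  e <- y - f(q$mean)
  fe_laplace(e, J, lambda, q$mean, q$cov, prior$mean, prior$cov,
             hyper$hE, hyper$hC, lambda_var)
}

# central finite-difference Jacobian
fd_jacobian <- function(f, x, step = 1e-3) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- xp[j] + step
    xm <- x; xm[j] <- xm[j] - step
    J[, j] <- (f(xp) - f(xm)) / (2 * step)
  }
  J
}

#' Free energy of a DCM at a given belief
#'
#' Convenience wrapper around [laplace_free_energy()] using the model's
#' spectral forward map and priors. The data are scale-normalized exactly as
#' in [fit_dcm()].
#'
#' @param model a `dcm_model`
#' @param q parameter belief (list `mean`, `cov`) over the model's free
#'   parameters; defaults to the prior
#' @param lambda log noise precision; defaults to `hyper$hE`
#' @param data a `csd`
#' @param hyper hyperprior, list with `hE` and `hC`
#' @return free energy (nats) with a `components` attribute
#' @export
free_energy <- function(model, q = NULL, lambda = NULL, data,
                        hyper = list(hE = 18, hC = 1 / 128)) {
  setup <- fit_setup(model, data)
  if (is.null(q)) q <- list(mean = model$priors$mean, cov = model$priors$cov)
  if (is.null(lambda)) lambda <- hyper$hE
  laplace_free_energy(setup$y, setup$fwd, q, lambda,
                      prior = model$priors, hyper = hyper)
}

# Shared setup for fitting: scale the observed spectra so the mean diagonal
# power is 1, anchor the innovation amplitude so the prior-mean prediction
# matches that scale, and build the vectorized forward map.
fit_setup <- function(model, data) {
  G <- data$G
  m <- dim(G)[1]
  if (m != model$n_modes)
    stop("data modes do not match the model's lead field")
  freqs <- data$freqs
  sc <- mean(Re(apply(G, 3, function(x) diag(x))))
  if (sc <= 0) stop("observed spectra have non-positive mean power")
  y <- vec_csd(G / sc)
  base <- model
  base$theta_A[] <- 0
  base$nuisance$a[["a1"]] <- 0
  g0 <- predict(base, freqs = freqs)
  sc0 <- mean(Re(apply(g0$G, 3, function(x) diag(x))))
  a1_base <- log(1 / sc0)  # prior-mean prediction has unit mean diagonal
  ne <- length(model$theta_A)
  fwd <- function(par) {
    mod <- base
    mod$theta_A[] <- par[seq_len(ne)]
    mod$nuisance$a[["a1"]] <- a1_base + par[[ne + 1]]
    lin <- linearize(mod)
    if (!lin$stable) return(NULL)
    nz <- nuisance_spectra(mod, freqs)
    vec_csd(csd_predict_core(lin$J, lin$B, lin$Cout, mod$leadfield,
                             as.numeric(freqs), nz$gu, nz$Gn))
  }
  # make the map total for finite-difference calls: error on instability
  fwd_strict <- function(par) {
    v <- fwd(par)
    if (is.null(v)) stop("unstable linearization at requested parameters")
    v
  }
  m <- model$n_modes
  nf <- length(freqs)
  # prediction and exact analytic Jacobian of the vectorized spectra
  fwd_grad <- function(par) {
    mod <- base
    mod$theta_A[] <- par[seq_len(ne)]
    mod$nuisance$a[["a1"]] <- a1_base + par[[ne + 1]]
    lin <- linearize(mod)
    if (!lin$stable) return(NULL)
    nz <- nuisance_spectra(mod, freqs)
    res <- csd_predict_grad(lin$J, lin$B, lin$Cout, mod$leadfield,
                            as.numeric(freqs), nz$gu, nz$Gn,
                            coupling_jacobian_triplets(mod))
    pred <- vec_csd(res$G)
    Jm <- matrix(0, length(pred), ne + 1)
    for (j in seq_len(ne))
      Jm[, j] <- vec_csd(array(res$grad[, j], c(m, m, nf)))
    Jm[, ne + 1] <- vec_csd(res$G - nz$Gn)  # innovation amplitude scales the signal
    list(pred = pred, J = Jm)
  }
  list(y = y, fwd = fwd_strict, fwd_try = fwd, fwd_grad = fwd_grad,
       scale = sc, a1_base = a1_base, freqs = freqs, base = base, ne = ne)
}

# Newton ascent on the log-precision (concave 1-D objective).
newton_lambda <- function(lambda, sse_tr, n, hE, hC, steps = 8) {
  for (i in seq_len(steps)) {
    g <- 0.5 * n - 0.5 * exp(lambda) * sse_tr - (lambda - hE) / hC
    H <- -0.5 * exp(lambda) * sse_tr - 1 / hC
    lambda <- min(max(lambda - g / H, -16), 32)
  }
  lambda
}

#' Fit a DCM to observed cross-spectral densities by variational Laplace
#'
#' Gauss-Newton ascent on the Laplace free energy with Levenberg-Marquardt
#' damping, alternating parameter and log-precision updates. Steps are
#' accepted only if the free energy (evaluated with a fresh Jacobian at the
#' candidate) increases, so the recorded free-energy trace is monotone;
#' rejected or unstable steps double the damping.
#'
#' @param data a `csd` with the observed spectra
#' @param model a `dcm_model`; its priors define the free-parameter space
#'   (coupling log-scalings plus innovation log-amplitude)
#' @param hyper hyperprior on the log noise precision, list `hE`, `hC`
#' @param opts list: `max_iter` (default 64), `tol` (0.01), `tol_count`
#'   (4 consecutive small improvements), `fd_step` (1e-3), `init`
#'   (initial free-parameter vector, default prior mean), `verbose`
#' @return object of class `dcm_fit`: `posterior` (mean, cov), `F`,
#'   `lambda`, `r2`, `predicted` (a `csd`, original data units), `n_iter`,
#'   `converged`, `trace`, plus the fitted `model`
#' @export
fit_dcm <- function(data, model, hyper = list(hE = 18, hC = 1 / 128),
                    opts = list()) {
  o <- modifyList(list(max_iter = 64, tol = 0.01, tol_count = 4,
                       fd_step = 1e-3, init = NULL, verbose = FALSE,
                       jacobian = "analytic"), opts)
  setup <- fit_setup(model, data)
  y <- setup$y
  n <- length(y)
  prior <- model$priors
  P0 <- solve(symm(prior$cov))
  p0 <- prior$mean
  K <- length(p0)
  par <- if (is.null(o$init)) p0 else o$init
  hE <- hyper$hE; hC <- hyper$hC

  jac <- if (identical(o$jacobian, "fd")) {
    function(par) {
      pred <- setup$fwd_try(par)
      if (is.null(pred)) return(NULL)
      J <- tryCatch(fd_jacobian(setup$fwd, par, o$fd_step),
                    error = function(e) NULL)
      if (is.null(J)) return(NULL)
      list(pred = pred, J = J)
    }
  } else {
    setup$fwd_grad
  }
  ev0 <- jac(par)
  if (is.null(ev0)) stop("no stable starting point: prior-mean model is unstable")
  e <- y - ev0$pred
  J <- ev0$J
  lambda <- hE
  eval_F <- function(e, J, lambda, par) {
    Sigma <- solve(symm(exp(lambda) * crossprod(J) + P0))
    tr_term <- sum((J %*% Sigma) * J)
    lambda <- newton_lambda(lambda, sum(e^2) + tr_term, n, hE, hC)
    Sigma <- solve(symm(exp(lambda) * crossprod(J) + P0))
    tr_term <- sum((J %*% Sigma) * J)
    F <- fe_laplace(e, J, lambda, par, Sigma, p0, prior$cov, hE, hC)
    list(F = as.numeric(F), lambda = lambda, Sigma = Sigma)
  }
  cur <- eval_F(e, J, lambda, par)
  lambda <- cur$lambda
  Fref <- cur$F
  nu <- 0.5
  trace <- data.frame(iter = 0L, F = Fref, lambda = lambda, nu = nu,
                      accepted = TRUE)
  small <- 0L
  converged <- FALSE
  n_iter <- 0L
  for (iter in seq_len(o$max_iter)) {
    n_iter <- iter
    el <- exp(lambda)
    Hm <- symm(el * crossprod(J) + P0)
    g <- el * drop(crossprod(J, e)) - drop(P0 %*% (par - p0))
    D <- diag(diag(Hm), K)
    accepted <- FALSE
    for (try in seq_len(12)) {
      step <- tryCatch(solve(Hm + nu * D, g), error = function(err) NULL)
      if (is.null(step)) { nu <- nu * 2; next }
      parc <- par + step
      evc <- jac(parc)
      if (is.null(evc)) { nu <- nu * 2; next }  # unstable: damp and retry
      ec <- y - evc$pred
      cand <- eval_F(ec, evc$J, lambda, parc)
      if (cand$F > Fref) {
        dF <- cand$F - Fref
        par <- parc; e <- ec; J <- evc$J
        cur <- cand; lambda <- cand$lambda; Fref <- cand$F
        nu <- max(nu / 2, 1e-8)
        accepted <- TRUE
        small <- if (abs(dF) < o$tol) small + 1L else 0L
        break
      }
      nu <- nu * 2
    }
    if (!accepted) small <- small + 1L  # stalled step: no improvement found
    trace <- rbind(trace, data.frame(iter = iter, F = Fref, lambda = lambda,
                                     nu = nu, accepted = accepted))
    if (o$verbose)
      message(sprintf("iter %2d  F = %.3f  lambda = %.2f  nu = %.2g", iter,
                      Fref, lambda, nu))
    if (small >= o$tol_count) { converged <- TRUE; break }
    if (!accepted && nu > 1e8) break
  }
  Sigma <- cur$Sigma
  dimnames(Sigma) <- list(names(p0), names(p0))
  pred_full <- predict(set_free_params(setup$base,
                                       c(par[seq_len(setup$ne)],
                                         setup$a1_base + par[K])),
                       freqs = setup$freqs)
  pred_full$G <- pred_full$G * setup$scale
  r2 <- variance_explained(pred_full, data)
  structure(
    list(posterior = list(mean = setNames(par, names(p0)), cov = Sigma),
         F = Fref, lambda = lambda, r2 = r2, predicted = pred_full,
         n_iter = n_iter, converged = converged, trace = trace,
         model = set_free_params(setup$base,
                                 c(par[seq_len(setup$ne)],
                                   setup$a1_base + par[K])),
         scale = setup$scale, a1_base = setup$a1_base, hyper = hyper),
    class = "dcm_fit"
  )
}

#' Percent variance explained of observed spectra
#'
#' `100 * (1 - SS_residual / SS_total)` over the concatenated real and
#' imaginary parts of every frequency bin and mode pair.
#'
#' @param fit a `dcm_fit` or a `csd` of predictions
#' @param data a `csd` of observations (optional for a `dcm_fit`, which
#'   carries its predictions; then `data` must still be supplied)
#' @return percent (at most 100)
#' @export
variance_explained <- function(fit, data) {
  pred <- if (inherits(fit, "dcm_fit")) fit$predicted else fit
  stopifnot(inherits(pred, "csd"), inherits(data, "csd"))
  if (!all(dim(pred$G) == dim(data$G))) stop("shape mismatch")
  obs <- c(Re(data$G), Im(data$G))
  phat <- c(Re(pred$G), Im(pred$G))
  sst <- sum(obs^2)
  if (sst == 0) stop("zero total variance in observed spectra")
  100 * (1 - sum((obs - phat)^2) / sst)
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat("DCM fit (variational Laplace)\n")
  cat(sprintf("  F = %.2f nats, r2 = %.1f%%, %d iterations%s\n", x$F, x$r2,
              x$n_iter, if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' @export
coef.dcm_fit <- function(object, ...) {
  ne <- length(object$model$theta_A)
  object$posterior$mean[seq_len(ne)]
}

#' @export
fitted.dcm_fit <- function(object, ...) object$predicted

#' @export
residuals.dcm_fit <- function(object, data = NULL, ...) {
  if (is.null(data)) stop("supply the observed csd to compute residuals")
  data$G - object$predicted$G
}

#' @export
summary.dcm_fit <- function(object, ...) {
  ne <- length(object$model$theta_A)
  est <- object$posterior$mean[seq_len(ne)]
  se <- sqrt(diag(object$posterior$cov))[seq_len(ne)]
  out <- data.frame(edge = names(est), estimate = unname(est),
                    sd = unname(se))
  structure(list(table = out, F = object$F, r2 = object$r2,
                 converged = object$converged),
            class = "summary.dcm_fit")
}

#' @export
print.summary.dcm_fit <- function(x, ...) {
  cat(sprintf("DCM fit: F = %.2f, r2 = %.1f%%\n", x$F, x$r2))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
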