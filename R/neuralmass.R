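# Generative model: convolution-based neural masses coupled by extrinsic
# forward/backward/lateral connections, linearized around the resting
# operating point, with power-law innovations and observation noise.

#' Default neural-mass constants for one cortical source
#'
#' Three populations per source (spiny stellate cells, inhibitory
#' interneurons, pyramidal cells) with second-order synaptic kernels.
#' `tau_e`/`tau_i` are excitatory/inhibitory synaptic time constants in
#' seconds, `H_e`/`H_i` the corresponding maximal postsynaptic gains (mV),
#' `gamma` the four intrinsic coupling gains (pyramidal->stellate,
#' stellate->pyramidal, pyramidal->interneuron, interneuron->pyramidal) and
#' `sigmoid_slope` the firing-rate slope at the operating point.
#'
#' @return named list of constants
#' @export
source_params <- function() {
  list(
    tau_e = 0.004, tau_i = 0.016,
    H_e = 8, H_i = 32,
    gamma = 128 * c(1, 0.8, 0.25, 0.25),
    sigmoid_slope = 0.125
  )
}

#' Construct a generative model for EEG cross-spectral densities
#'
#' Combines a cortical network, neural-mass constants, extrinsic coupling
#' log-scalings, spectral nuisance parameters (innovations and observation
#' noise), and a lead field mapping sources to data modes. Effective
#' extrinsic strength is `baseline[type] * exp(theta)`, so `theta = 0`
#' leaves every connection at its baseline and priors are zero-mean in
#' log-space.
#'
#' @param graph a `dcm_network`, default [grasping_network()]
#' @param theta_A named numeric vector of coupling log-scalings, one per
#'   extrinsic edge (default all 0); names must match [network_edges()]
#' @param sources neural-mass constants, see [source_params()]
#' @param nuisance list with `a` (innovations: log-amplitude `a1` and
#'   log-exponent `a2`, spectral density `exp(a1) * f^(-exp(a2))`),
#'   `b` (mode-specific observation noise, same power-law form) and
#'   `c` (noise common to all modes)
#' @param leadfield modes x sources gain matrix; default is a seeded random
#'   mixing with unit column norms (a synthetic stand-in for a head model)
#' @param n_modes number of data modes when the default lead field is built
#' @param baseline baseline extrinsic strengths before exp-scaling
#' @param input_gain per-source innovation input gains
#' @param prior_var prior variance of each coupling log-scaling (and of the
#'   innovation amplitude when fitted)
#' @param leadfield_seed seed for the default lead field
#' @return an object of class `dcm_model`
#' @examples
#' m <- dcm_model()
#' gcsd <- predict(m, freqs = 4:48)
#' @export
dcm_model <- function(graph = grasping_network(),
                      theta_A = NULL,
                      sources = source_params(),
                      nuisance = list(a = c(a1 = 0, a2 = -32),
                                      b = c(b1 = -16, b2 = -32),
                                      c = c(c1 = -16, c2 = -32)),
                      leadfield = NULL,
                      n_modes = 4,
                      baseline = c(forward = 32, backward = 16, lateral = 4),
                      input_gain = NULL,
                      prior_var = 1 / 8,
                      leadfield_seed = 42) {
  edges <- network_edges(graph)
  if (is.null(theta_A)) {
    theta_A <- setNames(rep(0, length(edges)), edges)
  } else {
    if (is.null(names(theta_A))) names(theta_A) <- edges
    if (!identical(sort(names(theta_A)), sort(edges)))
      stop("theta_A names must match the network's extrinsic edges")
    theta_A <- theta_A[edges]
  }
  stopifnot(sources$tau_e > 0, sources$tau_i > 0,
            sources$H_e > 0, sources$H_i > 0, all(sources$gamma > 0))
  ns <- length(graph$nodes)
  if (is.null(input_gain)) input_gain <- rep(1, ns)
  if (is.null(leadfield)) {
    leadfield <- with_seed(leadfield_seed, {
      L <- matrix(rnorm(n_modes * ns), n_modes, ns)
      sweep(L, 2, sqrt(colSums(L^2)), "/")
    })
  }
  if (any(colSums(abs(leadfield)) == 0))
    stop("lead field has a zero column")
  free <- c(theta_A, a1 = unname(nuisance$a["a1"]))
  priors <- list(mean = setNames(rep(0, length(free)), names(free)),
                 cov = diag(prior_var, length(free)))
  dimnames(priors$cov) <- list(names(free), names(free))
  structure(
    list(graph = graph, theta_A = theta_A, sources = sources,
         nuisance = nuisance, leadfield = leadfield,
         baseline = baseline, input_gain = input_gain,
         priors = priors, n_modes = nrow(leadfield)),
    class = "dcm_model"
  )
}

# effective extrinsic coupling matrices (to x from) for each edge type
coupling_matrices <- function(model) {
  nodes <- model$graph$nodes
  ns <- length(nodes)
  out <- list()
  for (type in c("forward", "backward", "lateral")) {
    A <- matrix(0, ns, ns, dimnames = list(nodes, nodes))
    edges <- model$graph[[type]]
    if (nrow(edges) > 0) {
      ids <- edge_ids(edges, type)
      for (k in seq_len(nrow(edges))) {
        A[edges[k, 2], edges[k, 1]] <-
          model$baseline[[type]] * exp(model$theta_A[[ids[k]]])
      }
    }
    out[[type]] <- A
  }
  out
}

#' Linearize the neural-mass network
#'
#' Each population follows second-order synaptic dynamics
#' `v'' = (H/tau) u - (2/tau) v' - (1/tau^2) v`, with the firing-rate
#' sigmoid replaced by its slope at the operating point (fixed at the
#' origin). The pyramidal depolarization that other populations and other
#' sources see is the difference between the pyramidal excitatory and
#' inhibitory compartments. Forward connections drive the spiny-stellate
#' population, backward connections drive the pyramidal and inhibitory
#' populations, and lateral connections drive all three. Eight states per
#' source.
#'
#' @param model a `dcm_model`
#' @return list with `J` (state Jacobian), `B` (innovation input map),
#'   `Cout` (pyramidal depolarization read-out), `stable` (all eigenvalue
#'   real parts < 0) and `eigenvalues`
#' @export
linearize <- function(model) {
  p <- model$sources
  stopifnot(all(is.finite(unlist(model$theta_A))))
  nodes <- model$graph$nodes
  ns <- length(nodes)
  nx <- 8L * ns
  A <- coupling_matrices(model)
  s <- p$sigmoid_slope
  g <- p$gamma
  ke <- p$H_e / p$tau_e
  ki <- p$H_i / p$tau_i

  J <- matrix(0, nx, nx)
  B <- matrix(0, nx, ns)
  Cout <- matrix(0, ns, nx)
  # state layout per source: 1 stellate V, 2 pyr-exc V, 3 pyr-inh V,
  # 4 stellate I, 5 pyr-exc I, 6 pyr-inh I, 7 interneuron V, 8 interneuron I
  # pyramidal depolarization (output, drives all couplings) = x2 - x3
  exc <- 8L * (seq_len(ns) - 1L) + 2L  # pyr-exc voltage of all sources
  inh <- 8L * (seq_len(ns) - 1L) + 3L  # pyr-inh voltage of all sources
  for (k in seq_len(ns)) {
    o <- 8L * (k - 1L)
    # voltage derivatives
    J[o + 1, o + 4] <- 1
    J[o + 2, o + 5] <- 1
    J[o + 3, o + 6] <- 1
    J[o + 7, o + 8] <- 1
    # stellate current: intrinsic gamma1 + forward + lateral + input
    afl <- ke * s * (A$forward[k, ] + A$lateral[k, ])
    abl <- ke * s * (A$backward[k, ] + A$lateral[k, ])
    J[o + 4, o + 1] <- -1 / p$tau_e^2
    J[o + 4, o + 4] <- -2 / p$tau_e
    J[o + 4, exc] <- J[o + 4, exc] + afl
    J[o + 4, inh] <- J[o + 4, inh] - afl
    J[o + 4, o + 2] <- J[o + 4, o + 2] + ke * g[1] * s
    J[o + 4, o + 3] <- J[o + 4, o + 3] - ke * g[1] * s
    # pyramidal excitatory compartment: gamma2 from stellate + backward + lateral
    J[o + 5, o + 2] <- -1 / p$tau_e^2
    J[o + 5, o + 5] <- -2 / p$tau_e
    J[o + 5, o + 1] <- J[o + 5, o + 1] + ke * g[2] * s
    J[o + 5, exc] <- J[o + 5, exc] + abl
    J[o + 5, inh] <- J[o + 5, inh] - abl
    # pyramidal inhibitory compartment: gamma4 from interneurons
    J[o + 6, o + 3] <- -1 / p$tau_i^2
    J[o + 6, o + 6] <- -2 / p$tau_i
    J[o + 6, o + 7] <- ki * g[4] * s
    # inhibitory interneurons: gamma3 from pyramidal + backward + lateral
    J[o + 8, o + 7] <- -1 / p$tau_e^2
    J[o + 8, o + 8] <- -2 / p$tau_e
    J[o + 8, o + 2] <- J[o + 8, o + 2] + ke * g[3] * s
    J[o + 8, o + 3] <- J[o + 8, o + 3] - ke * g[3] * s
    J[o + 8, exc] <- J[o + 8, exc] + abl
    J[o + 8, inh] <- J[o + 8, inh] - abl
    # innovations drive the stellate population
    B[o + 4, k] <- ke * model$input_gain[k]
    Cout[k, o + 2] <- 1
    Cout[k, o + 3] <- -1
  }
  ev <- eigen(J, only.values = TRUE)$values
  list(J = J, B = B, Cout = Cout,
       stable = all(Re(ev) < 0), eigenvalues = ev)
}

# innovation and observation-noise spectra on a frequency grid
nuisance_spectra <- function(model, freqs) {
  ns <- length(model$graph$nodes)
  m <- model$n_modes
  a <- model$nuisance$a
  gu <- matrix(exp(a[["a1"]]) * freqs^(-exp(a[["a2"]])), ns, length(freqs),
               byrow = TRUE)
  b <- model$nuisance$b
  cc <- model$nuisance$c
  Gn <- array(0, c(m, m, length(freqs)))
  gb <- exp(b[["b1"]]) * freqs^(-exp(b[["b2"]]))
  gc <- exp(cc[["c1"]]) * freqs^(-exp(cc[["c2"]]))
  for (k in seq_along(freqs)) {
    Gn[, , k] <- diag(gb[k], m) + matrix(gc[k], m, m)
  }
  list(gu = gu, Gn = Gn)
}

#' Predicted cross-spectral densities of a model
#'
#' Evaluates `G(f) = L T(f) G_u(f) T(f)^H L^H + G_n(f)` with transfer
#' function `T(f) = C (2 pi i f I - J)^{-1} B` from the linearization, by a
#' direct resolvent solve per frequency bin.
#'
#' @param object a `dcm_model`
#' @param freqs frequencies in Hz (default 4--48 in 1-Hz steps)
#' @param ... unused
#' @return a `csd` object (fields `freqs`, `G`)
#' @export
predict.dcm_model <- function(object, freqs = 4:48, ...) {
  lin <- linearize(object)
  if (!lin$stable)
    stop("model linearization is unstable; cannot predict spectra")
  nz <- nuisance_spectra(object, freqs)
  G <- csd_predict_core(lin$J, lin$B, lin$Cout, object$leadfield,
                        as.numeric(freqs), nz$gu, nz$Gn)
  new_csd(freqs = as.numeric(freqs), G = G)
}

#' @rdname predict.dcm_model
#' @param model a `dcm_model`
#' @export
predict_csd <- function(model, freqs = 4:48) predict(model, freqs = freqs)

#' Simulate mode-level time series from a model
#'
#' Draws a stationary Gaussian time series whose spectrum equals the model's
#' predicted cross-spectral density (innovations filtered through the
#' linearized dynamics, plus observation noise), by spectral synthesis on
#' the discrete Fourier grid. Reproducible given `seed`.
#'
#' @param object a `dcm_model`
#' @param nsim number of replicates
#' @param seed integer seed or NULL
#' @param duration length in seconds
#' @param rate sampling rate (samples/s)
#' @param ... unused
#' @return for `nsim = 1`, a `channel_ts` (modes x samples matrix plus
#'   `rate`); otherwise a list of them
#' @export
simulate.dcm_model <- function(object, nsim = 1, seed = NULL,
                               duration = 120, rate = 256, ...) {
  lin <- linearize(object)
  if (!lin$stable)
    stop("refusing to simulate from an unstable model")
  N <- round(duration * rate)
  kpos <- seq_len(floor((N - 1) / 2))
  freqs <- kpos * rate / N
  nz <- nuisance_spectra(object, freqs)
  G <- csd_predict_core(lin$J, lin$B, lin$Cout, object$leadfield,
                        freqs, nz$gu, nz$Gn)
  m <- dim(G)[1]
  # matrix square roots per bin (Hermitian eigen, clip tiny negatives)
  R <- array(0 + 0i, dim(G))
  for (k in seq_along(freqs)) {
    e <- eigen(G[, , k], symmetric = TRUE)
    d <- pmax(Re(e$values), 0)
    R[, , k] <- e$vectors %*% (sqrt(d) * Conj(t(e$vectors)))
  }
  amp <- sqrt(N * rate / 2)
  sims <- with_seed(seed, {
    lapply(seq_len(nsim), function(j) {
      X <- matrix(0 + 0i, N, m)
      Z <- matrix(complex(real = rnorm(length(kpos) * m, sd = sqrt(0.5)),
                          imaginary = rnorm(length(kpos) * m, sd = sqrt(0.5))),
                  length(kpos), m)
      for (k in seq_along(kpos)) {
        X[kpos[k] + 1, ] <- amp * (R[, , k] %*% Z[k, ])
      }
      X[N - kpos + 1, ] <- Conj(X[kpos + 1, ])
      x <- Re(mvfft(X, inverse = TRUE)) / N
      new_channel_ts(t(x), rate = rate,
                     labels = paste0("mode", seq_len(m)))
    })
  })
  if (nsim == 1) sims[[1]] else sims
}

#' Remove a source's extrinsic connections from a model (hidden source)
#'
#' The returned model keeps the source in the dynamics and the lead field
#' (same data dimensionality) but deletes every extrinsic edge touching it,
#' together with the corresponding coupling parameters and their priors.
#'
#' @param model a `dcm_model`
#' @param source node name (e.g. `"IPL"`)
#' @return a `dcm_model`
#' @export
make_hidden_source_model <- function(model, source) {
  net <- hide_source(model$graph, source)
  keep <- network_edges(net)
  dcm_model(graph = net,
            theta_A = model$theta_A[keep],
            sources = model$sources,
            nuisance = model$nuisance,
            leadfield = model$leadfield,
            baseline = model$baseline,
            input_gain = model$input_gain,
            prior_var = model$priors$cov[1, 1])
}

# Sparse perturbation of the state Jacobian per coupling parameter:
# triplets (row, col, value) of dJ/dtheta_edge at the current parameters
# (the derivative of baseline * exp(theta) is the current effective entry).
coupling_jacobian_triplets <- function(model) {
  p <- model$sources
  ke <- p$H_e / p$tau_e
  s <- p$sigmoid_slope
  nodes <- model$graph$nodes
  pos <- setNames(seq_along(nodes), nodes)
  out <- list()
  for (type in c("forward", "backward", "lateral")) {
    edges <- model$graph[[type]]
    if (nrow(edges) == 0) next
    ids <- edge_ids(edges, type)
    for (k in seq_len(nrow(edges))) {
      from <- pos[[edges[k, 1]]]
      to <- pos[[edges[k, 2]]]
      v <- ke * s * model$baseline[[type]] * exp(model$theta_A[[ids[k]]])
      oe <- 8L * (from - 1L)
      ot <- 8L * (to - 1L)
      rows <- switch(type,
                     forward = ot + 4L,
                     backward = c(ot + 5L, ot + 8L),
                     lateral = c(ot + 4L, ot + 5L, ot + 8L))
      tr <- do.call(rbind, lapply(rows, function(r)
        rbind(c(r, oe + 2L, v), c(r, oe + 3L, -v))))
      out[[ids[k]]] <- tr
    }
  }
  out[names(model$theta_A)]
}

#' Update a model's free parameters
#'
#' Internal-facing helper used by the inverter: sets the coupling
#' log-scalings and the innovation log-amplitude from a named vector laid
#' out as the model's prior (couplings first, then `a1`).
#'
#' @param model a `dcm_model`
#' @param par numeric vector of length `n_extrinsic(graph) + 1`
#' @return updated `dcm_model`
#' @export
set_free_params <- function(model, par) {
  ne <- length(model$theta_A)
  stopifnot(length(par) == ne + 1)
  model$theta_A[] <- par[seq_len(ne)]
  model$nuisance$a[["a1"]] <- par[[ne + 1]]
  model
}

#' @export
print.dcm_model <- function(x, ...) {
  cat("Neural-mass CSD model\n")
  print(x$graph)
  cat(sprintf("  %d data modes, %d free parameters (couplings + innovation amplitude)\n",
              x$n_modes, length(x$priors$mean)))
  invisible(x)
}
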