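# Spatial-mode projection and cross-spectral density estimation.

#' Multichannel time series container
#'
#' @param data channels x samples numeric matrix
#' @param rate sampling rate in samples/s
#' @param labels optional channel names
#' @return object of class `channel_ts`
#' @export
new_channel_ts <- function(data, rate, labels = NULL) {
  data <- as.matrix(data)
  if (rate <= 0) stop("rate must be positive")
  if (any(!is.finite(data))) stop("non-finite samples in time series")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  structure(list(data = data, rate = rate, labels = labels),
            class = "channel_ts")
}

#' Cross-spectral density container
#'
#' Hermitian complex matrix per frequency bin with a real non-negative
#' diagonal.
#'
#' @param freqs ascending frequencies (Hz)
#' @param G complex array, modes x modes x length(freqs)
#' @return object of class `csd`
#' @export
new_csd <- function(freqs, G) {
  stopifnot(length(freqs) == dim(G)[3], dim(G)[1] == dim(G)[2])
  if (is.unsorted(freqs)) stop("freqs must be ascending")
  structure(list(freqs = freqs, G = G), class = "csd")
}

#' @export
print.csd <- function(x, ...) {
  cat(sprintf("Cross-spectral densities: %d modes, %d bins (%g-%g Hz)\n",
              dim(x$G)[1], length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Project multichannel data onto principal spatial modes
#'
#' Channels are mean-centred and the leading left singular vectors of the
#' channel x sample matrix (variance-ordered) form the orthonormal
#' projection; the mode series are the projected data.
#'
#' @param x a `channel_ts` or channels x samples matrix
#' @param n_modes number of modes to keep (default 4)
#' @param rate sampling rate, required when `x` is a bare matrix
#' @return list of class `spectral_modes` with `projection`
#'   (modes x channels, orthonormal rows), `series` (modes x samples),
#'   `rate` and `var_explained` (per-mode variance fractions)
#' @export
project_to_modes <- function(x, n_modes = 4, rate = NULL) {
  if (inherits(x, "channel_ts")) {
    rate <- x$rate
    x <- x$data
  }
  if (is.null(rate)) stop("rate required when x is a matrix")
  nc <- nrow(x)
  if (ncol(x) <= nc) stop("need more samples than channels")
  if (n_modes > nc) stop("cannot request more modes than channels")
  xc <- x - rowMeans(x)
  sv <- svd(xc, nu = nc, nv = 0)
  r <- sum(sv$d > max(dim(xc)) * .Machine$double.eps * sv$d[1])
  if (n_modes > r) stop("requested modes exceed the rank of the data")
  proj <- t(sv$u[, seq_len(n_modes), drop = FALSE])
  structure(
    list(projection = proj, series = proj %*% xc, rate = rate,
         var_explained = sv$d^2 / sum(sv$d^2)),
    class = "spectral_modes"
  )
}

#' Estimate cross-spectral densities of mode series
#'
#' `method = "mar"` fits a multivariate autoregression by ordinary least
#' squares ([stats::ar.ols()]) and evaluates its analytic spectrum;
#' `method = "welch"` averages Hann-windowed, 50\%-overlapped segment
#' cross-periodograms. Densities are one-sided (power per Hz) on a 1-Hz
#' grid spanning `[fmin, fmax]`.
#'
#' @param m a `spectral_modes`, `channel_ts`, or modes x samples matrix
#' @param fmin,fmax band edges in Hz (defaults 4 and 48)
#' @param method `"mar"` or `"welch"`
#' @param order autoregression order for `"mar"` (default 8)
#' @param rate sampling rate, required for bare matrices
#' @return a `csd`
#' @export
estimate_csd <- function(m, fmin = 4, fmax = 48,
                         method = c("mar", "welch"), order = 8,
                         rate = NULL) {
  method <- match.arg(method)
  if (inherits(m, "spectral_modes")) {
    x <- m$series; rate <- m$rate
  } else if (inherits(m, "channel_ts")) {
    x <- m$data; rate <- m$rate
  } else {
    x <- as.matrix(m)
    if (is.null(rate)) stop("rate required when m is a matrix")
  }
  if (fmax >= rate / 2) stop("fmax must be below the Nyquist frequency")
  if (floor(fmax) < ceiling(fmin)) stop("empty frequency band")
  freqs <- seq(ceiling(fmin), floor(fmax), by = 1)
  x <- x - rowMeans(x)
  if (method == "mar") {
    csd_mar(x, rate, freqs, order)
  } else {
    csd_welch(x, rate, freqs)
  }
}

# analytic spectrum of an OLS-fitted vector autoregression
csd_mar <- function(x, rate, freqs, order) {
  stopifnot(order >= 1)
  fit <- ar.ols(ts(t(x)), aic = FALSE, order.max = order,
                demean = TRUE, intercept = FALSE)
  m <- nrow(x)
  A <- fit$ar  # order x m x m
  # companion-matrix stability check
  p <- dim(A)[1]
  comp <- matrix(0, m * p, m * p)
  for (l in seq_len(p)) comp[seq_len(m), (l - 1) * m + seq_len(m)] <- A[l, , ]
  if (p > 1) comp[(m + 1):(m * p), seq_len(m * (p - 1))] <- diag(m * (p - 1))
  if (max(Mod(eigen(comp, only.values = TRUE)$values)) >= 1)
    stop("fitted autoregression is unstable")
  Sig <- fit$var.pred
  G <- array(0 + 0i, c(m, m, length(freqs)))
  for (k in seq_along(freqs)) {
    z <- exp(-2i * pi * freqs[k] / rate)
    Af <- diag(m) + 0i
    for (l in seq_len(p)) Af <- Af - A[l, , ] * z^l
    H <- solve(Af)
    Gk <- (2 / rate) * H %*% Sig %*% Conj(t(H))
    G[, , k] <- (Gk + Conj(t(Gk))) / 2
  }
  new_csd(freqs, G)
}

# averaged cross-periodogram with Hann window and 50% overlap
csd_welch <- function(x, rate, freqs, seg_len = NULL) {
  m <- nrow(x)
  N <- ncol(x)
  if (is.null(seg_len)) seg_len <- round(rate)  # 1-s segments -> 1-Hz bins
  if (seg_len > N) stop("time series shorter than one segment")
  step <- floor(seg_len / 2)
  starts <- seq(1, N - seg_len + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  W <- sum(w^2)
  fgrid <- (seq_len(seg_len) - 1) * rate / seg_len
  idx <- vapply(freqs, function(f) which.min(abs(fgrid - f)), integer(1))
  G <- array(0 + 0i, c(m, m, length(freqs)))
  for (s in starts) {
    seg <- x[, s:(s + seg_len - 1), drop = FALSE]
    seg <- seg - rowMeans(seg)
    X <- mvfft(t(seg * rep(w, each = m)))  # seg_len x m
    for (k in seq_along(idx)) {
      v <- X[idx[k], ]
      G[, , k] <- G[, , k] + (2 / (rate * W)) * (v %*% Conj(t(v)))
    }
  }
  G <- G / length(starts)
  for (k in seq_along(freqs)) G[, , k] <- (G[, , k] + Conj(t(G[, , k]))) / 2
  new_csd(freqs, G)
}
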