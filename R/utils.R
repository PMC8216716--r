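# Internal numerical helpers.

#' Log-sum-exp
#' @param x numeric vector
#' @return log(sum(exp(x))) computed stably
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log determinant of a symmetric positive-definite matrix via Cholesky;
# errors if the matrix is not PD.
logdet_pd <- function(A) {
  R <- chol(A)
  2 * sum(log(diag(R)))
}

is_pd <- function(A, tol = 0) {
  ok <- TRUE
  tryCatch(chol(A), error = function(e) ok <<- FALSE)
  ok
}

# symmetrize (guards against floating-point asymmetry before chol/solve)
symm <- function(A) (A + t(A)) / 2

# Evaluate an expression with a temporary RNG state seeded by `seed`,
# restoring the caller's RNG state afterwards. seed = NULL runs as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a reproducible sub-seed from a master seed, kept within 32-bit range
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 1000 + as.numeric(offset)) %% 2147483647)
}

# 32-bit FNV-1a hash of a character string, as 8 hex digits (provenance).
# Arithmetic in doubles, exact because intermediates stay below 2^53.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Vectorize a complex cross-spectral array for fitting
#'
#' Stacks, frequency by frequency, the real parts of the upper triangle
#' (including the diagonal) followed by the imaginary parts of the strict
#' upper triangle. Imaginary parts of the diagonal are identically zero for
#' Hermitian matrices and are dropped.
#'
#' @param G complex array, modes x modes x frequencies
#' @return numeric vector
#' @keywords internal
vec_csd <- function(G) {
  m <- dim(G)[1]
  ut <- upper.tri(matrix(0, m, m), diag = TRUE)
  sut <- upper.tri(matrix(0, m, m), diag = FALSE)
  nf <- dim(G)[3]
  out <- vector("list", nf)
  for (k in seq_len(nf)) {
    Gk <- G[, , k]
    out[[k]] <- c(Re(Gk[ut]), Im(Gk[sut]))
  }
  unlist(out, use.names = FALSE)
}
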