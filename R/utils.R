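#' @useDynLib bmerp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif fft mvfft sd var qt pt pf ptukey quantile
#'   kmeans cor setNames
#' @importFrom utils write.csv read.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# clamp to [-1, 1] preserving dim (safe acos argument)
clamp1 <- function(x) { x[x > 1] <- 1; x[x < -1] <- -1; x }

stop_bad_arg <- function(...) stop(..., call. = FALSE)

#' Legendre polynomials P_1..P_nmax evaluated at x
#'
#' Returns a matrix with one row per degree (1..nmax). Uses the standard
#' three-term recurrence; `x` may be any numeric vector with |x| <= 1.
#' @param x numeric vector of evaluation points.
#' @param nmax highest degree.
#' @keywords internal
legendre_table <- function(x, nmax) {
  p_prev <- rep(1, length(x))   # P_0
  p_cur <- x                    # P_1
  out <- matrix(0, nmax, length(x))
  out[1, ] <- p_cur
  if (nmax >= 2) {
    for (n in 2:nmax) {
      p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
      out[n, ] <- p_next
      p_prev <- p_cur
      p_cur <- p_next
    }
  }
  out
}

#' First derivatives P'_1..P'_nmax at x
#' @keywords internal
legendre_deriv_table <- function(x, nmax) {
  # dP_n/dx via recurrence P'_{n} = x P'_{n-1} + n P_{n-1}
  p <- rbind(rep(1, length(x)), legendre_table(x, nmax))  # P_0..P_nmax
  out <- matrix(0, nmax, length(x))
  dprev <- rep(0, length(x))  # P'_0
  for (n in 1:nmax) {
    dcur <- x * dprev + n * p[n, ]
    out[n, ] <- dcur
    dprev <- dcur
  }
  out
}

# Spherical linear interpolation between unit vectors p0 and p1.
slerp <- function(p0, p1, f) {
  om <- acos(max(-1, min(1, sum(p0 * p1))))
  if (om < 1e-12) return(p0)
  (sin((1 - f) * om) * p0 + sin(f * om) * p1) / sin(om)
}

# Great-circle distance matrix (radians) between rows of unit-vector matrix.
greatcircle_dist <- function(pos) {
  g <- tcrossprod(pos)
  g[g > 1] <- 1
  g[g < -1] <- -1
  acos(g)
}

# Moore-Penrose pseudo-inverse via eigen-decomposition (symmetric input).
sym_pinv <- function(m, tol = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values))
  if (!any(keep)) return(matrix(0, nrow(m), ncol(m)))
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

# Steady-state initial filter state for direct-form II transposed
# (the classical lfilter_zi construction).
filter_zi <- function(b, a) {
  m <- length(a) - 1
  A <- diag(1, m) - cbind(-a[-1], rbind(diag(1, m - 1), 0))
  rhs <- b[-1] - a[-1] * b[1]
  as.numeric(solve(A, rhs))
}

# Derive a child seed from a base seed and a stage label; keeps results
# independent across stages while fully determined by the top-level seed.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  # double-precision arithmetic: composed seeds must never overflow int32
  as.integer((as.numeric(seed) * 1009 + h %% 100003) %% 2147483562)
}
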