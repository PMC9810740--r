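# Fractional Gaussian noise by Davies-Harte circulant embedding.
#
# Used to generate sub- and super-diffusive trajectories with a controllable
# anomalous exponent alpha = 2H. For standard fGn at unit spacing,
# Var(sum of the first k increments) = k^(2H).

# Autocovariance of standard fGn at integer lag k.
#' @noRd
fgn_acov <- function(k, H) {
  0.5 * (abs(k - 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k + 1)^(2 * H))
}

#' Simulate standard fractional Gaussian noise
#'
#' Exact synthesis via circulant embedding of the covariance (Davies-Harte);
#' falls back to Cholesky factorization if the embedding is not nonnegative
#' definite (does not occur for 0 < H < 1 with this covariance, but guarded).
#' Draws from the current RNG state.
#'
#' @param n number of increments.
#' @param H Hurst exponent in (0, 1).
#' @return Numeric vector of n correlated standard-normal increments whose
#'   partial sums form fractional Brownian motion with `Var(B_H(k)) = k^(2H)`.
#' @export
fgn <- function(n, H) {
  if (H <= 0 || H >= 1) stop_fmt("Hurst exponent must be in (0, 1)")
  if (n < 1) stop_fmt("n must be >= 1")
  if (abs(H - 0.5) < 1e-12) return(stats::rnorm(n))
  if (n == 1) return(stats::rnorm(1))
  m <- 2 * n
  crow <- c(fgn_acov(0:(n - 1), H), 0, fgn_acov((n - 1):1, H))
  lambda <- Re(stats::fft(crow))
  if (min(lambda) < -1e-8 * max(lambda)) {
    # Cholesky fallback on the exact covariance
    sigma <- outer(1:n, 1:n, function(i, j) fgn_acov(i - j, H))
    return(as.numeric(chol(sigma + diag(1e-12, n)) %*% stats::rnorm(n)))
  }
  lambda <- pmax(lambda, 0)
  w <- complex(length.out = m)
  w[1] <- sqrt(lambda[1] / m) * stats::rnorm(1)
  w[n + 1] <- sqrt(lambda[n + 1] / m) * stats::rnorm(1)
  j <- 2:n
  re <- stats::rnorm(n - 1)
  im <- stats::rnorm(n - 1)
  w[j] <- sqrt(lambda[j] / (2 * m)) * complex(real = re, imaginary = im)
  w[m + 2 - j] <- Conj(w[j])
  Re(stats::fft(w))[1:n]
}
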