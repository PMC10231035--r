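#' Parameters of the fractional Gaussian noise generator
#'
#' Bundles the Hurst index, the per-component root-mean-square step size
#' (in grid units), the number of steps and the seed used to generate one
#' fiber's increment series.
#'
#' @param hurst Hurst index, strictly between 0 and 1. The default 0.8 is the
#'   superdiffusive regime used for the main simulations.
#' @param sigma Root-mean-square step per Cartesian component, in grid units
#'   (one grid unit corresponds to 6.6 micrometres of tissue). Default 0.4.
#' @param length Number of steps (positive integer). Defaults to 2^18, a
#'   desk-scale setting; the full-scale runs use 2^25 (about 0.8 GB of
#'   increments per fiber across three components).
#' @param seed Non-negative integer seed.
#' @return An object of class `noise_params`.
#' @examples
#' p <- noise_params(hurst = 0.8, sigma = 0.4, length = 1024, seed = 1)
#' p
#' @export
noise_params <- function(hurst = 0.8, sigma = 0.4, length = 2^18, seed = 1L) {
  if (!is.numeric(hurst) || length(hurst) != 1L || is.na(hurst) ||
      hurst <= 0 || hurst >= 1) {
    stop("'hurst' must be a single number in the open interval (0, 1)")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0) {
    stop("'sigma' must be a single positive number")
  }
  n <- as.numeric(length)
  if (length(n) != 1L || is.na(n) || n < 1 || n != floor(n)) {
    stop("'length' must be a positive integer")
  }
  s <- as.numeric(seed)
  if (length(s) != 1L || is.na(s) || s < 0 || s != floor(s)) {
    stop("'seed' must be a non-negative integer")
  }
  structure(
    list(hurst = hurst, sigma = sigma, length = as.integer(n),
         seed = as.integer(s %% 2147483647)),
    class = "noise_params"
  )
}

#' @export
print.noise_params <- function(x, ...) {
  cat("Fractional Gaussian noise parameters\n")
  cat(sprintf("  Hurst index H : %.3f (%s)\n", x$hurst,
              if (x$hurst > 0.5) "superdiffusive" else if (x$hurst < 0.5)
                "subdiffusive" else "Brownian"))
  cat(sprintf("  RMS step sigma: %.3f grid units\n", x$sigma))
  cat(sprintf("  Steps         : %d\n", x$length))
  cat(sprintf("  Seed          : %d\n", x$seed))
  invisible(x)
}

#' Closed-form autocovariance of fractional Gaussian noise
#'
#' The stationary covariance between increments separated by `lag` steps,
#' \deqn{\gamma(n) = \frac{\sigma^2}{2}\left(|n+1|^{2H} - 2|n|^{2H} +
#'   |n-1|^{2H}\right).}{gamma(n) = (sigma2/2) (|n+1|^2H - 2|n|^2H + |n-1|^2H).}
#' At lag 0 this reduces to \eqn{\sigma^2}; for \eqn{H = 0.5} all nonzero lags
#' vanish (uncorrelated Brownian increments); \eqn{H > 0.5} gives persistent
#' (positive) correlations decaying as \eqn{n^{2H-2}}.
#'
#' @param lag Non-negative integer lag (vectorized).
#' @param hurst Hurst index in (0, 1).
#' @param sigma2 Increment variance \eqn{\sigma^2 > 0}.
#' @return Covariance value(s), same length as `lag`.
#' @examples
#' fgn_covariance(0, hurst = 0.8, sigma2 = 0.16)  # = sigma^2
#' fgn_covariance(1, hurst = 0.5, sigma2 = 1)     # = 0
#' fgn_covariance(1, hurst = 0.8, sigma2 = 1)     # (2^1.6 - 2)/2
#' @export
fgn_covariance <- function(lag, hurst, sigma2) {
  if (!is.numeric(hurst) || length(hurst) != 1L || is.na(hurst) ||
      hurst <= 0 || hurst >= 1) {
    stop("'hurst' must be a single number in the open interval (0, 1)")
  }
  if (!is.numeric(sigma2) || length(sigma2) != 1L || is.na(sigma2) ||
      sigma2 <= 0) {
    stop("'sigma2' must be a single positive number")
  }
  if (!is.numeric(lag) || any(is.na(lag)) || any(lag < 0) ||
      any(lag != floor(lag))) {
    stop("'lag' must contain non-negative integers")
  }
  h2 <- 2 * hurst
  (sigma2 / 2) * (abs(lag + 1)^h2 - 2 * abs(lag)^h2 + abs(lag - 1)^h2)
}

# Deterministic seed splitting: (master, fiber, component) -> stream seed.
# Lehmer-style mixing mod 2^31 - 1; all intermediates stay below 2^53 so the
# arithmetic is exact in doubles.
derive_seed <- function(master, fiber = 0L, component = 0L) {
  m <- 2147483647
  s <- (as.numeric(master) %% m)
  s <- (s * 48271) %% m
  s <- (s + as.numeric(fiber) * 100003 + as.numeric(component) * 10007 + 1) %% m
  s <- (s * 48271) %% m
  as.integer(s %% (m - 1) + 1)
}

# Evaluate code with a temporary RNG state seeded by `seed`; the caller's
# .Random.seed is restored on exit.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

# Eigenvalues of the circulant embedding of the FGN covariance on a 2L grid,
# L = next power of two >= n. Non-negative for FGN with 0 < H < 1; tiny
# negative values from floating-point roundoff are clamped.
fgn_circulant_spectrum <- function(n, hurst, sigma2) {
  L <- 2^ceiling(log2(max(n, 2)))
  g <- fgn_covariance(0:L, hurst, sigma2)
  circ <- c(g, g[L:2])                      # length 2L, symmetric
  lam <- Re(stats::fft(circ))
  if (min(lam) < -1e-8 * max(lam)) {
    stop("internal error: circulant embedding of the FGN covariance is not ",
         "non-negative definite")
  }
  lam[lam < 0] <- 0
  list(lambda = lam, L = L, m = 2L * L)
}

#' Generate fractional Gaussian noise by Fourier filtering
#'
#' Filters white Gaussian noise in the frequency domain by the square root of
#' the noise spectral density, evaluated as the eigenvalue spectrum of the
#' circulant embedding of [fgn_covariance()] on a grid of twice the next
#' power of two above `length`; the first `length` values are returned.
#' The resulting sequence is stationary, mean zero, and has the closed-form
#' covariance at every lag below the grid half-length.
#'
#' @param params A [noise_params()] object.
#' @return Numeric vector of `params$length` increments for one component.
#' @seealso [generate_fgn_exact()] for the independent circulant-embedding
#'   (Davies-Harte) construction used to cross-validate this generator.
#' @examples
#' xi <- generate_fgn_fourier(noise_params(length = 4096, seed = 3))
#' c(mean(xi), sd(xi))
#' @export
generate_fgn_fourier <- function(params) {
  stopifnot(inherits(params, "noise_params"))
  n <- params$length
  if (n < 2L) stop("'length' must be at least 2 for the spectral construction")
  sp <- fgn_circulant_spectrum(n, params$hurst, params$sigma^2)
  m <- sp$m
  u <- with_seed(params$seed, stats::rnorm(m))
  v <- stats::fft(stats::fft(u) * sqrt(sp$lambda), inverse = TRUE) / m
  Re(v)[seq_len(n)]
}

#' Generate fractional Gaussian noise by circulant embedding (Davies-Harte)
#'
#' Exact-covariance construction: Hermitian complex Gaussian variates are
#' weighted by the square root of the circulant eigenvalues and transformed
#' by one FFT. Serves as the independent oracle for
#' [generate_fgn_fourier()]; both satisfy [fgn_covariance()] but consume
#' randomness differently.
#'
#' @param params A [noise_params()] object.
#' @param n_paths Number of independent replicate sequences (default 1).
#'   Replicates share the spectrum computation; replicate `i` uses the seed
#'   stream derived from `params$seed` and `i`.
#' @return A numeric vector (`n_paths = 1`) or a `length` x `n_paths` matrix
#'   of independent sequences.
#' @examples
#' xi <- generate_fgn_exact(noise_params(length = 512, seed = 9))
#' var(xi)  # close to sigma^2 = 0.16
#' @export
generate_fgn_exact <- function(params, n_paths = 1L) {
  stopifnot(inherits(params, "noise_params"))
  n <- params$length
  if (n < 2L) stop("'length' must be at least 2 for the spectral construction")
  n_paths <- as.integer(n_paths)
  stopifnot(n_paths >= 1L)
  sp <- fgn_circulant_spectrum(n, params$hurst, params$sigma^2)
  m <- sp$m
  half <- m %/% 2L
  w <- sqrt(sp$lambda / m)
  out <- matrix(0, nrow = n, ncol = n_paths)
  z <- complex(length.out = m)
  for (p in seq_len(n_paths)) {
    seed_p <- if (n_paths == 1L) params$seed else derive_seed(params$seed, p, 7L)
    draws <- with_seed(seed_p, stats::rnorm(2L * m))
    a <- draws[seq_len(m)]
    b <- draws[m + seq_len(m)]
    z[1L] <- a[1L]
    z[half + 1L] <- a[half + 1L]
    idx <- 2:half
    z[idx] <- (a[idx] + 1i * b[idx]) / sqrt(2)
    z[m + 2L - idx] <- Conj(z[idx])
    x <- Re(stats::fft(w * z))
    out[, p] <- x[seq_len(n)]
  }
  if (n_paths == 1L) out[, 1L] else out
}

#' Generate the three-component increment series of one fiber
#'
#' The x, y and z step components are statistically independent fractional
#' Gaussian noise streams; each component is generated by
#' [generate_fgn_fourier()] from a seed derived deterministically from
#' `params$seed`, the fiber index, and the component index, so cohorts are
#' reproducible regardless of execution order.
#'
#' @param params A [noise_params()] object; `params$seed` acts as the master
#'   seed for the derived component streams.
#' @param fiber_index Non-negative integer identifying the fiber within a
#'   cohort (default 0).
#' @return An `increment_series`: a `length` x 3 numeric matrix with columns
#'   `x`, `y`, `z` (grid units).
#' @examples
#' xi <- generate_increments_3d(noise_params(length = 1024, seed = 5))
#' colMeans(xi)
#' @export
generate_increments_3d <- function(params, fiber_index = 0L) {
  stopifnot(inherits(params, "noise_params"))
  out <- vapply(1:3, function(comp) {
    p <- params
    p$seed <- derive_seed(params$seed, fiber_index, comp)
    generate_fgn_fourier(p)
  }, numeric(params$length))
  colnames(out) <- c("x", "y", "z")
  class(out) <- c("increment_series", class(out))
  out
}
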