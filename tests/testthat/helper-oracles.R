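# Exact (Gaussian, Bartlett-type) standard error of the sample autocovariance
# at one lag for a stationary Gaussian series with the theoretical FGN
# covariance:
#   Var(g_hat(k)) = (1/n) sum_{|j|<n} (1 - |j|/n) [ g(j)^2 + g(j+k) g(j-k) ].
# The full triangular-weighted sum matters for H > 0.75, where sum g(j)^2
# diverges and the estimator converges slower than 1/sqrt(n).
bartlett_se <- function(lag, n, hurst, sigma2) {
  g <- fgn_covariance(0:(n - 1 + lag), hurst, sigma2)
  gv <- function(k) g[abs(k) + 1]              # k in -(n-1)..(n-1+lag)
  j <- -(n - 1):(n - 1)
  w <- 1 - abs(j) / n
  sqrt(sum(w * (gv(j)^2 + gv(j + lag) * gv(j - lag))) / n)
}

# Standard error of the lag-0 cross-covariance between two independent FGN
# streams: Var = (1/n) sum (1 - |j|/n) g(j)^2.
cross_cov_se <- function(n, hurst, sigma2) {
  g <- fgn_covariance(0:(n - 1), hurst, sigma2)
  j <- -(n - 1):(n - 1)
  sqrt(sum((1 - abs(j) / n) * g[abs(j) + 1]^2) / n)
}

# Independent per-cell inside test: scans the slice contour lists directly,
# cell by cell, rather than going through the rasterized mask.
brute_inside_cell <- function(volume, i, j, k) {
  if (k < 0L || k >= volume$z_extent || i < 0L || j < 0L) return(FALSE)
  allowed <- FALSE
  forbidden <- FALSE
  for (ct in volume$slices[[k + 1L]]) {
    m <- match(j, ct$rows[, "y"])
    if (!is.na(m) && ct$rows[m, "x_left"] <= i && i <= ct$rows[m, "x_right"]) {
      if (ct$kind == "allowed") allowed <- TRUE else forbidden <- TRUE
    }
  }
  allowed && !forbidden
}

# Plain sequential-addition oracle for the free walk: r[n+1] = r[n] + xi[n]
# in double precision, the same operation order as the walker.
cumsum_positions <- function(start, incr) {
  n <- nrow(incr)
  out <- matrix(0, n + 1L, 3L)
  pos <- as.numeric(start)
  out[1L, ] <- pos
  for (s in seq_len(n)) {
    pos <- pos + incr[s, ]
    out[s + 1L, ] <- pos
  }
  out
}

# Log-spaced integer lags for MSD fits.
log_lags <- function(from = 8, to = 512, n = 25) {
  unique(round(exp(seq(log(from), log(to), length.out = n))))
}

# Free-space cohort trajectories at the cohort defaults.
free_cohort <- function(n_fibers, n_steps, hurst = 0.8, sigma = 0.4,
                        master_seed = 42L) {
  cfg <- walk_config(noise_params(hurst = hurst, sigma = sigma,
                                  length = n_steps),
                     n_fibers = n_fibers,
                     start = start_region(c(0, 0, 0), c(1, 1, 1)),
                     master_seed = master_seed)
  simulate_cohort(NULL, cfg, record = "trajectories")
}
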