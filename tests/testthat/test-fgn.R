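# Shared fixtures: one long sequence per generator at the study defaults.
p_long <- noise_params(hurst = 0.8, sigma = 0.4, length = 2^18, seed = 101L)
x_fourier <- generate_fgn_fourier(p_long)
x_exact <- generate_fgn_exact(p_long)

test_that("closed-form covariance matches hand-derived values and rejects bad input", {
  # lag 0 reduces to sigma^2 for any H
  expect_equal(fgn_covariance(0, hurst = 0.8, sigma2 = 0.16), 0.16)
  expect_equal(fgn_covariance(0, hurst = 0.3, sigma2 = 2.5), 2.5)
  # Brownian increments are uncorrelated
  expect_equal(fgn_covariance(1, hurst = 0.5, sigma2 = 1), 0)
  expect_equal(fgn_covariance(7, hurst = 0.5, sigma2 = 0.16), 0)
  # frozen values of (2^1.6 - 2)/2 and its sigma2-scaled variant
  expect_equal(fgn_covariance(1, hurst = 0.8, sigma2 = 1),
               0.5157165665103981, tolerance = 1e-12)
  expect_equal(fgn_covariance(1, hurst = 0.8, sigma2 = 0.16),
               0.08251465064166369, tolerance = 1e-12)
  # persistence: positive, decaying covariances for H > 0.5
  g <- fgn_covariance(0:50, hurst = 0.8, sigma2 = 1)
  expect_true(all(g > 0))
  expect_true(all(diff(g) < 0))
  expect_error(fgn_covariance(1, hurst = 0, sigma2 = 1), "hurst")
  expect_error(fgn_covariance(1, hurst = 1, sigma2 = 1), "hurst")
  expect_error(fgn_covariance(1, hurst = 0.5, sigma2 = 0), "sigma2")
  expect_error(fgn_covariance(-1, hurst = 0.5, sigma2 = 1), "lag")
})

test_that("noise_params validates its domain", {
  expect_error(noise_params(hurst = 1.2), "hurst")
  expect_error(noise_params(sigma = -1), "sigma")
  expect_error(noise_params(length = 0), "length")
  expect_error(noise_params(seed = -3), "seed")
  expect_error(generate_fgn_fourier(noise_params(length = 1)), "at least 2")
})

test_that("both generators reproduce the closed-form covariance at lags 0..64", {
  n <- p_long$length
  g_target <- fgn_covariance(0:64, 0.8, 0.16)
  for (x in list(fourier = x_fourier, exact = x_exact)) {
    g_hat <- empirical_autocovariance(x, 64)
    se <- vapply(0:64, bartlett_se, numeric(1), n = n, hurst = 0.8,
                 sigma2 = 0.16)
    expect_true(all(abs(g_hat - g_target) < 3 * se))
    # lag-0 empirical variance close to sigma^2 = 0.16
    expect_lt(abs(g_hat[1] - 0.16), 3 * se[1])
    expect_lt(abs(mean(x)), 4 * sqrt(0.16 * n^(2 * 0.8)) / n)
  }
})

test_that("H = 0.5 degenerates to i.i.d. Gaussian noise", {
  p <- noise_params(hurst = 0.5, sigma = 0.4, length = 2^16, seed = 5L)
  for (x in list(generate_fgn_fourier(p), generate_fgn_exact(p))) {
    g_hat <- empirical_autocovariance(x, 8)
    se <- bartlett_se(1, p$length, 0.5, 0.16)
    expect_true(all(abs(g_hat[-1]) < 3 * se))
    expect_gt(stats::ks.test(x, "pnorm", 0, 0.4)$p.value, 0.01)
  }
})

test_that("generation is deterministic in the seed and sensitive to it", {
  p <- noise_params(length = 4096, seed = 7L)
  expect_identical(generate_fgn_fourier(p), generate_fgn_fourier(p))
  expect_identical(generate_fgn_exact(p), generate_fgn_exact(p))
  p2 <- p; p2$seed <- 8L
  expect_false(any(generate_fgn_fourier(p) == generate_fgn_fourier(p2)))
  # generators consume randomness differently: same seed, different streams
  expect_false(isTRUE(all.equal(generate_fgn_fourier(p),
                                generate_fgn_exact(p))))
})

test_that("three-component increments are independent, correctly scaled, seeded streams", {
  p <- noise_params(hurst = 0.8, sigma = 0.4, length = 2^18, seed = 11L)
  xi <- generate_increments_3d(p)
  expect_equal(dim(xi), c(p$length, 3L))
  expect_identical(colnames(xi), c("x", "y", "z"))
  se <- cross_cov_se(p$length, 0.8, 0.16)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_lt(abs(mean(xi[, pair[1]] * xi[, pair[2]])), 3 * se)
  }
  # per-component RMS near sigma = 0.4 (3 SEs, long-range dependence included)
  se_var <- bartlett_se(0, p$length, 0.8, 0.16)
  for (comp in 1:3) {
    expect_lt(abs(mean(xi[, comp]^2) - 0.16), 3 * se_var)
  }
  expect_identical(generate_increments_3d(p), xi)
  p2 <- p; p2$seed <- 12L
  expect_false(any(generate_increments_3d(p2) == xi))
  expect_false(any(generate_increments_3d(p, fiber_index = 1L) == xi))
})

test_that("partial sums obey the sigma^2 n^(2H) variance law (telescoping identity)", {
  # 10^4 independent replicate series of 64 steps, H = 0.8, sigma = 1
  paths <- generate_fgn_exact(noise_params(hurst = 0.8, sigma = 1,
                                           length = 64, seed = 21L),
                              n_paths = 1e4)
  # analytic check of the telescoping sum at n = 4 against the frozen value
  cum_cov <- function(n) {
    lags <- outer(seq_len(n), seq_len(n), function(a, b) abs(a - b))
    sum(fgn_covariance(as.vector(lags), 0.8, 1))
  }
  expect_equal(cum_cov(4), 4^1.6, tolerance = 1e-10)
  expect_equal(4^1.6, 9.18958683997628, tolerance = 1e-12)
  for (n in c(1L, 4L, 16L, 64L)) {
    target <- n^1.6
    v <- stats::var(colSums(paths[seq_len(n), , drop = FALSE]))
    expect_lt(abs(v - target), 4 * target * sqrt(2 / 1e4))
  }
})
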