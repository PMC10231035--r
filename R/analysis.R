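#' Sample autocovariance with unbiased normalization
#'
#' `g(k) = sum_{t} (x_t - m)(x_{t+k} - m) / (n - k)`, with `m` the overall
#' sample mean. Used to validate generated noise against [fgn_covariance()].
#'
#' @param series Numeric vector; must be longer than `4 * max_lag`.
#' @param max_lag Largest lag.
#' @return Numeric vector of autocovariances at lags `0:max_lag`.
#' @export
empirical_autocovariance <- function(series, max_lag) {
  n <- length(series)
  max_lag <- as.integer(max_lag)
  if (n <= 4L * max_lag) stop("series too short for the requested max_lag")
  x <- series - mean(series)
  vapply(0:max_lag, function(k) {
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / (n - k)
  }, numeric(1))
}

#' Ensemble- and time-averaged mean squared displacement
#'
#' For each lag, averages the squared 3D displacement over all time origins
#' and all fibers. Intended for free-space (unreflected) trajectories, whose
#' MSD follows `3 sigma^2 lag^(2H)`; reflected trajectories saturate at the
#' confinement scale and are rejected when `strict = TRUE`.
#'
#' @param trajectories List of `fbm_trajectory` objects (or bare position
#'   matrices), at least 8.
#' @param lags Strictly increasing positive integer lags.
#' @param strict Reject trajectories that recorded boundary rejections
#'   (default `TRUE`).
#' @return An object of class `msd_curve`: data frame with columns `lag`,
#'   `msd` (grid units squared, summed over the three components).
#' @export
ensemble_msd <- function(trajectories, lags, strict = TRUE) {
  stopifnot(length(trajectories) >= 8L)
  lags <- as.integer(lags)
  stopifnot(all(lags >= 1L), !is.unsorted(lags, strictly = TRUE))
  mats <- lapply(trajectories, function(tr) {
    if (inherits(tr, "fbm_trajectory")) {
      if (strict && tr$rejected > 0L) {
        stop("reflected trajectory passed to ensemble_msd (strict mode): ",
             "MSD scaling only holds in free space")
      }
      tr$positions
    } else as.matrix(tr)
  })
  msd <- vapply(lags, function(lag) {
    mean(vapply(mats, function(m) {
      n <- nrow(m)
      if (lag >= n) stop("lag exceeds trajectory length")
      d <- m[(lag + 1):n, , drop = FALSE] - m[seq_len(n - lag), , drop = FALSE]
      mean(rowSums(d * d))
    }, numeric(1)))
  }, numeric(1))
  structure(data.frame(lag = lags, msd = msd),
            class = c("msd_curve", "data.frame"))
}

#' Estimate the Hurst index from an MSD curve
#'
#' Half the least-squares slope of `log(msd)` against `log(lag)` over the fit
#' window. Exact on pure power laws; on simulated cohorts it recovers the
#' generator's H within Monte-Carlo error. The default window (lags 8 to 512)
#' skips the smallest lags, where discreteness matters most, and the largest,
#' where time-averaging is noisiest.
#'
#' @param curve An [ensemble_msd()] result (or data frame with `lag`, `msd`).
#' @param fit_range `c(min_lag, max_lag)` window (default `c(8, 512)`).
#' @return Estimated Hurst index.
#' @export
estimate_hurst <- function(curve, fit_range = c(8, 512)) {
  stopifnot(all(c("lag", "msd") %in% names(curve)))
  sel <- curve$lag >= fit_range[1] & curve$lag <= fit_range[2]
  if (sum(sel) < 5L) stop("need at least 5 MSD points inside the fit range")
  if (any(curve$msd[sel] <= 0)) stop("non-positive MSD values in fit range")
  fit <- stats::lm(log(msd) ~ log(lag), data = curve[sel, ])
  unname(stats::coef(fit)[2] / 2)
}

# Pool the cell-level inside mask to the bin grid: a bin is allowed when it
# contains at least one allowed cell.
bin_allowed_mask <- function(volume, bin_cells) {
  dims <- c(volume$nx, volume$ny, volume$z_extent)
  bdims <- as.integer(ceiling(dims / bin_cells))
  out <- array(FALSE, dim = bdims)
  idx <- which(volume$mask, arr.ind = TRUE)
  if (nrow(idx)) {
    b <- 1L + (idx - 1L) %/% bin_cells
    out[unique(b[, 1] + bdims[1] * ((b[, 2] - 1) + bdims[2] * (b[, 3] - 1)))] <- TRUE
  }
  out
}

# Chebyshev distance (in bins) from each allowed bin to the nearest
# non-allowed bin, bins outside the bounding box counting as non-allowed.
# Computed by iterative dilation of the complement.
chebyshev_border_distance <- function(allowed) {
  d <- dim(allowed)
  dist <- array(NA_integer_, dim = d)
  dist[!allowed] <- 0L
  # pad with a non-allowed shell so the box edge is a border
  pad <- array(0L, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- NA_integer_
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)][!allowed] <- 0L
  level <- 0L
  while (anyNA(pad)) {
    level <- level + 1L
    cur <- !is.na(pad) & pad == (level - 1L)
    # dilate cur by one Chebyshev step
    dil <- array(FALSE, dim = d + 2L)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      xs <- pmin(pmax(1:(d[1] + 2) + dx, 1), d[1] + 2)
      ys <- pmin(pmax(1:(d[2] + 2) + dy, 1), d[2] + 2)
      zs <- pmin(pmax(1:(d[3] + 2) + dz, 1), d[3] + 2)
      dil <- dil | cur[xs, ys, zs]
    }
    newly <- is.na(pad) & dil
    if (!any(newly)) stop("internal error: border distance did not converge")
    pad[newly] <- level
  }
  dist <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  dist[!allowed] <- NA_integer_
  dist
}

#' Mean density as a function of distance to the nearest border
#'
#' Groups allowed bins by Chebyshev distance (in bins) to the nearest
#' non-allowed bin — walls, forbidden regions, and the rostral/caudal ends
#' all count as borders — and averages `d_s` within each distance shell.
#' Superdiffusive reflected walkers (H > 0.5) pile up against borders, so
#' the shell at distance 1 carries the highest mean density; subdiffusive
#' walkers do not show this excess.
#'
#' @param grid A [density_grid()].
#' @param volume The [build_volume()] result the grid was accumulated on.
#' @return Data frame with columns `distance`, `mean_d_s`, `n_bins`; the bin
#'   counts partition the allowed bins.
#' @export
border_distance_profile <- function(grid, volume) {
  stopifnot(inherits(grid, "density_grid"), inherits(volume, "volume_model"))
  allowed <- bin_allowed_mask(volume, grid$bin_cells)
  if (!any(allowed)) stop("volume has no allowed bins")
  stopifnot(all(dim(allowed) == dim(grid$d_s)))
  dist <- chebyshev_border_distance(allowed)
  ds <- split(grid$d_s[allowed], dist[allowed])
  data.frame(distance = as.integer(names(ds)),
             mean_d_s = vapply(ds, mean, numeric(1)),
             n_bins = vapply(ds, length, integer(1)),
             row.names = NULL)
}

#' L1 convergence diagnostic between two density fields
#'
#' Half the L1 distance between two normalized density arrays (total
#' variation, in [0, 1]). Comparing the densities accumulated over the first
#' and second halves of a run indicates how close the cohort is to its
#' steady state; no universal threshold is imposed.
#'
#' @param d_s_a,d_s_b Normalized density arrays of identical shape.
#' @return Total-variation distance.
#' @export
density_tv_distance <- function(d_s_a, d_s_b) {
  stopifnot(all(dim(d_s_a) == dim(d_s_b)))
  sum(abs(d_s_a - d_s_b)) / 2
}
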