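#' Cuboid of allowed fiber start positions
#'
#' Fibers start in the rostral raphe region, approximated by a cuboid under
#' the cerebral aqueduct. Coordinates are grid units.
#'
#' @param origin `c(x, y, z)`, the minimal corner.
#' @param extents `c(dx, dy, dz)`, positive edge lengths.
#' @return An object of class `start_region`.
#' @export
start_region <- function(origin, extents) {
  origin <- as.numeric(origin); extents <- as.numeric(extents)
  stopifnot(length(origin) == 3L, length(extents) == 3L, all(extents > 0),
            all(is.finite(c(origin, extents))))
  structure(list(origin = origin, extents = extents), class = "start_region")
}

#' Start region from physical dimensions
#'
#' Converts micrometre dimensions to grid units. The raphe start cuboid of
#' the full-scale model measures 680 x 1200 x 400 um^3 (mediolateral,
#' dorsoventral, rostrocaudal), i.e. about 103 x 182 x 61 cells at 6.6 um
#' per cell.
#'
#' @param origin Minimal corner in grid units.
#' @param dims_um `c(dx, dy, dz)` in micrometres.
#' @param cell_um Grid cell size in micrometres (default 6.6).
#' @return A [start_region()].
#' @export
start_region_from_um <- function(origin, dims_um = c(680, 1200, 400),
                                 cell_um = 6.6) {
  start_region(origin, round(dims_um / cell_um))
}

#' Sample a uniform start position from a cuboid
#'
#' @param region A [start_region()].
#' @param seed Integer seed (deterministic draw).
#' @return Numeric `c(x, y, z)`.
#' @export
sample_start <- function(region, seed) {
  stopifnot(inherits(region, "start_region"))
  u <- with_seed(seed, stats::runif(3))
  region$origin + u * region$extents
}

#' Configuration of a fiber cohort simulation
#'
#' Defaults mirror the full-scale study conditions (H = 0.8, sigma = 0.4
#' grid units, 960 fibers) except the per-fiber step count, which defaults to
#' the desk-scale 2^18; the full-scale runs used 2^25 steps per fiber.
#'
#' @param noise A [noise_params()]; its seed field is ignored in favour of
#'   `master_seed`-derived per-fiber streams.
#' @param n_fibers Number of independent fibers (default 960).
#' @param start A [start_region()].
#' @param master_seed Master seed; each fiber/component stream seed is derived
#'   from `(master_seed, fiber_index, component)` so results are independent
#'   of execution order.
#' @return An object of class `walk_config`.
#' @export
walk_config <- function(noise = noise_params(), n_fibers = 960L, start,
                        master_seed = 1L) {
  stopifnot(inherits(noise, "noise_params"), inherits(start, "start_region"))
  n_fibers <- as.integer(n_fibers)
  stopifnot(n_fibers >= 1L)
  if (noise$sigma > 1) {
    warning("sigma > 1 grid unit: the endpoint-only boundary test can step ",
            "across one-cell walls")
  }
  structure(list(noise = noise, n_fibers = n_fibers, start = start,
                 master_seed = as.integer(master_seed)),
            class = "walk_config")
}

fiber_increments <- function(config, fiber_index) {
  p <- config$noise
  p$seed <- config$master_seed
  generate_increments_3d(p, fiber_index = fiber_index)
}

fiber_start <- function(volume, config, fiber_index, max_retries = 100L) {
  for (r in seq_len(max_retries)) {
    s <- sample_start(config$start,
                      derive_seed(config$master_seed, fiber_index, 100L + r))
    if (is.null(volume) || is_inside(volume, s)) return(s)
  }
  stop(sprintf("could not sample an inside start position for fiber %d: %s",
               fiber_index,
               "check that the start cuboid lies in the allowed region"))
}

#' Advance a walker position by one increment with boundary rejection
#'
#' Returns `position + increment` when the endpoint lies inside the volume;
#' otherwise the step is simply not carried out and the position is returned
#' unchanged (the increment is consumed, not retried). With `sigma` below one
#' grid unit a step cannot jump across a wall, so testing only the endpoint
#' suffices.
#'
#' @param volume A [build_volume()] result, or `NULL` for free space.
#' @param position Current `c(x, y, z)`; must be inside.
#' @param increment Step `c(dx, dy, dz)`.
#' @return The new position.
#' @export
advance <- function(volume, position, increment) {
  if (!is.null(volume) && !is_inside(volume, position)) {
    stop("internal invariant violated: position is outside the volume")
  }
  cand <- position + increment
  if (is.null(volume) || is_inside(volume, cand)) cand else position
}

#' Simulate one fiber trajectory
#'
#' The fiber performs discrete fractional Brownian motion: the recursion
#' r[n+1] = r[n] + xi[n] with xi a three-component fractional Gaussian noise,
#' and steps whose endpoint leaves the allowed region rejected. The whole
#' increment series is generated up front (the noise is non-Markovian and
#' cannot be extended incrementally).
#'
#' @param volume A [build_volume()] result, or `NULL` for an unconfined
#'   (free-space) walk, in which case the trajectory equals the start plus
#'   cumulative increment sums exactly.
#' @param config A [walk_config()].
#' @param fiber_index Fiber number within the cohort (0-based, default 0).
#' @return An object of class `fbm_trajectory`: list with `positions`
#'   (an (n_steps + 1) x 3 matrix), `rejected` (count of rejected steps), and
#'   `fiber_index`.
#' @export
simulate_fiber <- function(volume, config, fiber_index = 0L) {
  stopifnot(inherits(config, "walk_config"))
  if (!is.null(volume)) stopifnot(inherits(volume, "volume_model"))
  incr <- fiber_increments(config, fiber_index)
  start <- fiber_start(volume, config, fiber_index)
  res <- walk_fiber_cpp(unclass(incr), start,
                        if (is.null(volume)) NULL else volume$mask,
                        if (is.null(volume)) integer(3) else
                          c(volume$nx, volume$ny, volume$z_extent))
  structure(list(positions = res$positions, rejected = res$rejected,
                 fiber_index = as.integer(fiber_index)),
            class = "fbm_trajectory")
}

#' @export
print.fbm_trajectory <- function(x, ...) {
  n <- nrow(x$positions) - 1L
  cat(sprintf("FBM fiber trajectory: %d steps, %d rejected at boundaries (%.2f%%)\n",
              n, x$rejected, 100 * x$rejected / max(n, 1L)))
  invisible(x)
}

#' Plot a fiber trajectory projection
#'
#' @param x An `fbm_trajectory`.
#' @param plane Which coordinate plane to project on (default `"xy"`).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fbm_trajectory <- function(x, plane = c("xy", "xz", "yz"), ...) {
  plane <- match.arg(plane)
  cols <- match(strsplit(plane, "")[[1]], c("x", "y", "z"))
  graphics::plot(x$positions[, cols[1]], x$positions[, cols[2]], type = "l",
                 xlab = substr(plane, 1, 1), ylab = substr(plane, 2, 2),
                 asp = 1, ...)
}

#' Simulate a cohort of fibers
#'
#' Runs `config$n_fibers` independent fibers. In `"density"` mode positions
#' are streamed straight into pooled bin counts without retaining
#' trajectories, so memory stays flat; in `"trajectories"` mode the full
#' paths are returned (use small cohorts). Per-fiber seeding makes the result
#' invariant to execution order.
#'
#' @param volume A [build_volume()] result (`NULL` allowed only in
#'   trajectory mode, for free-space cohorts).
#' @param config A [walk_config()].
#' @param record `"density"` (default) or `"trajectories"`.
#' @param bin_cells Grid cells per density bin edge (default 2, i.e. 2x2x2
#'   pooling).
#' @param count_rejected Tally the unchanged position of a rejected step
#'   (default `TRUE`, keeping the total tally at
#'   `n_fibers * (n_steps + 1)`); set `FALSE` to exclude rejected-step
#'   duplicates for sensitivity analyses.
#' @param fibers Optional subset/order of 0-based fiber indices to run
#'   (defaults to `0:(n_fibers-1)`); density results do not depend on the
#'   order.
#' @return In density mode, a `density_counts` list: integer `counts` array
#'   over bins, `bin_cells`, `n_positions` streamed, `rejected` per fiber.
#'   In trajectory mode, a list of [simulate_fiber()] results.
#' @export
simulate_cohort <- function(volume, config,
                            record = c("density", "trajectories"),
                            bin_cells = 2L, count_rejected = TRUE,
                            fibers = NULL) {
  record <- match.arg(record)
  stopifnot(inherits(config, "walk_config"))
  if (is.null(fibers)) fibers <- seq_len(config$n_fibers) - 1L
  if (record == "trajectories") {
    return(lapply(fibers, function(fi) simulate_fiber(volume, config, fi)))
  }
  stopifnot(inherits(volume, "volume_model"))
  bin_cells <- as.integer(bin_cells)
  dims <- c(volume$nx, volume$ny, volume$z_extent)
  bdims <- as.integer(ceiling(dims / bin_cells))
  counts <- array(0L, dim = bdims)
  rejected <- integer(length(fibers))
  for (i in seq_along(fibers)) {
    fi <- fibers[i]
    incr <- fiber_increments(config, fi)
    start <- fiber_start(volume, config, fi)
    rejected[i] <- walk_accumulate_cpp(unclass(incr), start, volume$mask,
                                       as.integer(dims), counts, bdims,
                                       bin_cells, isTRUE(count_rejected))
  }
  n_pos <- length(fibers) * (config$noise$length + 1)
  if (isTRUE(count_rejected)) {
    stopifnot(sum(as.numeric(counts)) == n_pos)
  }
  structure(list(counts = counts, bin_cells = bin_cells,
                 n_positions = n_pos, rejected = rejected),
            class = "density_counts")
}
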