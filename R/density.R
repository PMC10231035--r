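#' Pool walker positions into bin counts
#'
#' Each position increments the bin containing its floor cell; bins pool
#' `bin_cells`^3 grid cells (default 2 x 2 x 2, suppressing counting noise).
#' Trailing partial bins at grid edges pool fewer cells but are kept, so no
#' position is lost and the total count equals the number of positions.
#'
#' @param positions n x 3 matrix of positions (grid units), all inside the
#'   volume.
#' @param volume A [build_volume()] result.
#' @param bin_cells Grid cells per bin edge (default 2).
#' @return Integer 3D array of counts over bins.
#' @export
accumulate <- function(positions, volume, bin_cells = 2L) {
  stopifnot(inherits(volume, "volume_model"))
  p <- if (is.matrix(positions)) positions else matrix(positions, ncol = 3L)
  if (!all(is_inside(volume, p))) {
    stop("invariant violated: positions outside the volume cannot be tallied")
  }
  bin_cells <- as.integer(bin_cells)
  dims <- c(volume$nx, volume$ny, volume$z_extent)
  bdims <- as.integer(ceiling(dims / bin_cells))
  bx <- floor(p[, 1L]) %/% bin_cells
  by <- floor(p[, 2L]) %/% bin_cells
  bz <- floor(p[, 3L]) %/% bin_cells
  lin <- 1 + bx + bdims[1L] * (by + bdims[2L] * bz)
  counts <- array(0L, dim = bdims)
  tab <- tabulate(lin, nbins = prod(bdims))
  counts[] <- as.integer(tab)
  counts
}

#' Normalize bin counts to densities summing to one
#'
#' Dividing by the total tally removes any dependence on the arbitrarily
#' chosen trajectory length and fiber count.
#'
#' @param counts Non-negative 3D count array.
#' @return Array `d_s` of the same shape with `sum(d_s) == 1`.
#' @export
normalize_density <- function(counts) {
  total <- sum(as.numeric(counts))
  if (total <= 0) stop("empty simulation: all bin counts are zero")
  counts / total
}

#' Beer-Lambert-like optical density transform
#'
#' `d_o = 1 - exp(-k * d_s)`: maps the sum-normalized densities onto [0, 1)
#' to emulate immunostained-section optical densities. Strictly increasing,
#' so bin rankings are preserved. The full-scale study used the empirically
#' optimized k = 10^8.3; because `d_s` sums to one, grids with far fewer
#' bins need a different dynamic range (see [auto_k()]).
#'
#' @param d_s Normalized density array (non-negative).
#' @param k Positive transform constant (default `10^8.3`).
#' @return Array `d_o` of the same shape, values in [0, 1).
#' @export
optical_transform <- function(d_s, k = 10^8.3) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    stop("'k' must be a single positive number")
  }
  if (any(d_s < 0)) stop("'d_s' must be non-negative")
  1 - exp(-k * d_s)
}

#' Choose k so the median nonzero optical density is one half
#'
#' @param d_s Normalized density array.
#' @return Positive `k` with `median(1 - exp(-k * d_s[d_s > 0])) = 0.5`.
#' @export
auto_k <- function(d_s) {
  nz <- d_s[d_s > 0]
  if (!length(nz)) stop("empty simulation: no nonzero densities")
  log(2) / stats::median(nz)
}

#' Assemble a density grid from pooled counts
#'
#' @param counts Integer bin-count array (from [accumulate()] or
#'   [simulate_cohort()] density mode).
#' @param bin_cells Grid cells per bin edge used for pooling.
#' @param cell_um Physical grid cell size (um).
#' @param k Optical transform constant, or `"auto"` for [auto_k()].
#' @return An object of class `density_grid` with fields `counts`, `d_s`,
#'   `d_o`, `k`, `bin_cells`, `bin_um`.
#' @export
density_grid <- function(counts, bin_cells = 2L, cell_um = 6.6, k = 10^8.3) {
  if (inherits(counts, "density_counts")) {
    bin_cells <- counts$bin_cells
    counts <- counts$counts
  }
  d_s <- normalize_density(counts)
  if (identical(k, "auto")) k <- auto_k(d_s)
  d_o <- optical_transform(d_s, k)
  structure(list(counts = counts, d_s = d_s, d_o = d_o, k = k,
                 bin_cells = as.integer(bin_cells), cell_um = cell_um,
                 bin_um = bin_cells * cell_um),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("Density grid: %d x %d x %d bins (%.1f um/bin), %s positions\n",
              d[1], d[2], d[3], x$bin_um,
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  cat(sprintf("  occupied bins: %d (%.1f%%); k = 10^%.2f\n",
              sum(x$counts > 0), 100 * mean(x$counts > 0), log10(x$k)))
  invisible(x)
}

#' @export
summary.density_grid <- function(object, ...) {
  nz <- object$d_s[object$counts > 0]
  cat("Normalized densities d_s (occupied bins):\n")
  print(stats::quantile(nz, c(0, .25, .5, .75, 1)))
  cat("Optical densities d_o (occupied bins):\n")
  print(stats::quantile(object$d_o[object$counts > 0], c(0, .25, .5, .75, 1)))
  invisible(object)
}

#' Plot one coronal slice of a density grid
#'
#' @param x A `density_grid`.
#' @param slice Bin index along z (default: middle slice).
#' @param which `"d_o"` (default), `"d_s"` or `"counts"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.density_grid <- function(x, slice = NULL,
                              which = c("d_o", "d_s", "counts"), ...) {
  which <- match.arg(which)
  arr <- x[[which]]
  if (is.null(slice)) slice <- ceiling(dim(arr)[3] / 2)
  graphics::image(arr[, , slice], col = grDevices::hcl.colors(64, "Spectral",
                                                              rev = TRUE),
                  asp = dim(arr)[2] / dim(arr)[1],
                  main = sprintf("%s, slice %d", which, slice), ...)
}

#' Extract a one-dimensional density profile cut
#'
#' Values of the grid along one axis with the other two bin indices fixed;
#' the standard way to compare density bands across a section.
#'
#' @param grid A [density_grid()].
#' @param axis `"x"`, `"y"` or `"z"`: the axis the cut runs along.
#' @param at Integer vector of length 2: the fixed bin indices of the other
#'   two axes, in axis order (e.g. for `axis = "x"`, `at = c(y, z)`).
#' @return A data frame with columns `bin`, `d_s`, `d_o`.
#' @export
profile_cut <- function(grid, axis = c("x", "y", "z"), at) {
  stopifnot(inherits(grid, "density_grid"))
  axis <- match.arg(axis)
  d <- dim(grid$d_s)
  ai <- match(axis, c("x", "y", "z"))
  others <- setdiff(1:3, ai)
  at <- as.integer(at)
  if (length(at) != 2L || any(at < 1L) || any(at > d[others])) {
    stop("'at' must give in-bounds bin indices for the two fixed axes")
  }
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[others[1]]] <- at[1]
  idx[[others[2]]] <- at[2]
  data.frame(bin = seq_len(d[ai]),
             d_s = as.vector(grid$d_s[idx[[1]], idx[[2]], idx[[3]]]),
             d_o = as.vector(grid$d_o[idx[[1]], idx[[2]], idx[[3]]]))
}

#' Export a density volume as NIfTI
#'
#' Writes the selected field with the bin size (`bin_cells * cell_um`,
#' default 13.2 um) recorded as the isotropic voxel size. Counts are written
#' as 32-bit integers, densities as doubles, so the round trip is lossless.
#'
#' @param grid A [density_grid()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param which `"counts"`, `"d_s"` or `"d_o"`.
#' @return `path`, invisibly.
#' @export
export_volume <- function(grid, path, which = c("counts", "d_s", "d_o")) {
  stopifnot(inherits(grid, "density_grid"))
  which <- match.arg(which)
  arr <- grid[[which]]
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(grid$bin_um, 3)
  RNifti::writeNifti(img, path,
                     datatype = if (which == "counts") "int32" else "double")
  invisible(path)
}
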