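#' Rectangular slab phantom
#'
#' The minimal geometry for boundary-accumulation experiments: identical
#' rectangular allowed contours in every section.
#'
#' @param nx,ny Slab cross-section in grid cells.
#' @param n_sections Number of physical sections.
#' @param cell_um,section_step_um Physical calibration (defaults 6.6 / 80 um).
#' @return A [section_stack()].
#' @export
make_slab <- function(nx, ny, n_sections, cell_um = 6.6,
                      section_step_um = 80) {
  stopifnot(nx >= 1, ny >= 1, n_sections >= 1)
  rows <- cbind(0:(ny - 1L), 0L, nx - 1L)
  secs <- lapply(seq_len(n_sections), function(i)
    physical_section(i - 1L, list(contour_rows("allowed", rows))))
  section_stack(secs, cell_um = cell_um, section_step_um = section_step_um,
                midline_x = (nx - 1) / 2)
}

# Rows rasterizing the disc x^2 + y^2 <= r2 at integer lattice points,
# centred at (cx, cy).
disc_rows <- function(cx, cy, r2) {
  ylim <- floor(sqrt(r2))
  ys <- (cy - ylim):(cy + ylim)
  half <- floor(sqrt(r2 - (ys - cy)^2))
  cbind(ys, cx - half, cx + half)
}

#' Spherical phantom
#'
#' Rasterizes a ball of the given radius as one section per z-level (use
#' `build_volume(..., subdivisions = 1)` so each section is one slice).
#' An isotropic fixture for boundary-curvature and border-accumulation
#' checks; bilaterally symmetric by construction.
#'
#' @param radius Ball radius in grid cells (>= 4).
#' @param cell_um Physical cell size.
#' @return A [section_stack()]; the allowed cells are the integer lattice
#'   points within `radius` of the centre `(radius, radius, radius)`.
#' @export
make_sphere_stack <- function(radius, cell_um = 6.6) {
  stopifnot(radius >= 4)
  r <- as.integer(radius)
  secs <- list()
  for (dz in -r:r) {
    r2 <- r^2 - dz^2
    if (r2 < 0) next
    secs[[length(secs) + 1L]] <- physical_section(
      dz + r, list(contour_rows("allowed", disc_rows(r, r, r2))))
  }
  section_stack(secs, cell_um = cell_um, section_step_um = cell_um,
                midline_x = r)
}

#' Specification of the brain-like phantom
#'
#' @param n_sections Physical sections along the rostro-caudal axis.
#' @param nx,ny Maximal cross-section in grid cells.
#' @param ventricles Include paired lateral-ventricle-like forbidden slots.
#' @param concavity Include a dorsomedial forbidden notch over a contiguous
#'   run of middle sections.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_sections = 12L, nx = 81L, ny = 61L,
                         ventricles = TRUE, concavity = TRUE) {
  stopifnot(n_sections >= 4L, nx >= 31L, ny >= 21L, nx %% 2L == 1L)
  structure(list(n_sections = as.integer(n_sections), nx = as.integer(nx),
                 ny = as.integer(ny), ventricles = isTRUE(ventricles),
                 concavity = isTRUE(concavity)),
            class = "phantom_spec")
}

#' Brain-like phantom geometry
#'
#' A deterministic, elongated, tapering stack of elliptical sections with the
#' structural features of the embryonic brain model: paired forbidden
#' lateral-ventricle slots in the rostral half, a dorsomedial forbidden notch
#' (the concavity between the hemispheres) over a contiguous run of middle
#' sections, and a raphe-like start cuboid in the caudal third at the ventral
#' midline. No anatomical realism is attempted; the phantom exists so every
#' pipeline stage is testable without external data.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `stack` (a [section_stack()]) and `start`
#'   (a [start_region()] in grid units of the built volume with the default
#'   12 subdivisions).
#' @export
make_brain_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_sections
  cx <- (spec$nx - 1L) %/% 2L
  # tapering half-axes: widest around two-thirds caudally, narrow poles
  t <- (seq_len(n) - 1) / (n - 1)
  shape <- 0.35 + 0.65 * sin(pi * t^0.8)
  ax <- pmax(10L, as.integer(round((spec$nx - 1L) / 2 * shape)))
  ay <- pmax(8L, as.integer(round((spec$ny - 1L) / 2 * shape)))
  cy <- as.integer(round(spec$ny / 2))
  vent_secs <- seq(2L, max(3L, n %/% 2L))           # rostral half
  notch_secs <- seq(max(2L, n %/% 3L), n %/% 2L + 2L)  # contiguous middle run
  secs <- vector("list", n)
  for (i in seq_len(n)) {
    ys <- (cy - ay[i]):(cy + ay[i])
    half <- floor(ax[i] * sqrt(pmax(0, 1 - ((ys - cy) / ay[i])^2)))
    half <- pmax(half, 1L)
    cts <- list(contour_rows("allowed", cbind(ys, cx - half, cx + half)))
    if (spec$ventricles && i %in% vent_secs && ax[i] > 14L) {
      vy <- (cy - ay[i] %/% 2L):(cy - 1L)
      vw <- max(1L, ax[i] %/% 8L)
      voff <- ax[i] %/% 3L
      cts <- c(cts, list(
        contour_rows("forbidden", cbind(vy, cx - voff - vw, cx - voff)),
        contour_rows("forbidden", cbind(vy, cx + voff, cx + voff + vw))
      ))
    }
    if (spec$concavity && i %in% notch_secs && ay[i] > 10L) {
      nw <- max(1L, ax[i] %/% 10L)
      # keep the notch strictly inside the allowed rows: start at the first
      # dorsal row wide enough for the notch plus a margin
      wide <- ys[half >= nw + 2L & ys < cy]
      nys <- wide[seq_len(min(length(wide), ay[i] %/% 3L))]
      if (length(nys) >= 2L) {
        cts <- c(cts, list(contour_rows("forbidden",
                                        cbind(nys, cx - nw, cx + nw))))
      }
    }
    secs[[i]] <- physical_section(i - 1L, cts)
  }
  stack <- section_stack(secs, midline_x = cx)
  # start cuboid: caudal third, ventral midline, safely inside the taper
  i0 <- max(1L, n - n %/% 3L)
  sx <- max(2L, ax[i0] %/% 3L)
  sy <- max(2L, ay[i0] %/% 4L)
  start <- start_region(origin = c(cx - sx / 2, cy + ay[i0] / 4, 12 * (i0 - 1)),
                        extents = c(sx, sy, 12))
  list(stack = stack, start = start)
}
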