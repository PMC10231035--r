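#' Contour rows describing one closed shape within a coronal section
#'
#' A shape is stored as consecutive dorsoventral rows; each row holds the
#' y-coordinate and the leftmost and rightmost x-coordinates of the shape at
#' that level. Concavities opening in the dorsoventral direction cannot be
#' captured this way and are coded as separate `"forbidden"` contours
#' (ventricular spaces, the dorsomedial notch).
#'
#' @param kind `"allowed"` or `"forbidden"`.
#' @param rows Integer matrix with columns `y`, `x_left`, `x_right`; y values
#'   must be consecutive (dorsal to ventral, increasing y is ventral) and
#'   `x_left <= x_right` in every row.
#' @return An object of class `contour_rows`.
#' @export
contour_rows <- function(kind, rows) {
  kind <- match.arg(kind, c("allowed", "forbidden"))
  rows <- as.matrix(rows)
  if (ncol(rows) != 3L || nrow(rows) < 1L) {
    stop("'rows' must be a matrix with >= 1 row and columns y, x_left, x_right")
  }
  storage.mode(rows) <- "integer"
  if (any(is.na(rows))) stop("contour rows contain NA")
  if (nrow(rows) > 1L && any(diff(rows[, 1L]) != 1L)) {
    bad <- which(diff(rows[, 1L]) != 1L)[1L]
    stop(sprintf("contour y values must be consecutive; gap after y = %d",
                 rows[bad, 1L]))
  }
  if (any(rows[, 2L] > rows[, 3L])) {
    bad <- which(rows[, 2L] > rows[, 3L])[1L]
    stop(sprintf("x_left > x_right at y = %d", rows[bad, 1L]))
  }
  colnames(rows) <- c("y", "x_left", "x_right")
  structure(list(kind = kind, rows = rows), class = "contour_rows")
}

#' Mirror-symmetrize a contour about a midline
#'
#' Replaces each row by the symmetric hull of the row and its mirror image
#' about `midline_x`: `x_left' = min(x_left, round(2 m - x_right))`,
#' `x_right' = max(x_right, round(2 m - x_left))`. Idempotent; leaves a
#' contour that is already bilaterally symmetric unchanged.
#'
#' @param contour A [contour_rows()] object.
#' @param midline_x Midline x-coordinate; must lie within the contour's
#'   x-range.
#' @return The symmetrized `contour_rows`.
#' @export
symmetrize_contour <- function(contour, midline_x) {
  stopifnot(inherits(contour, "contour_rows"))
  r <- contour$rows
  if (midline_x < min(r[, "x_left"]) || midline_x > max(r[, "x_right"])) {
    stop("'midline_x' lies outside the contour's x-range")
  }
  xl <- pmin(r[, "x_left"], as.integer(round(2 * midline_x - r[, "x_right"])))
  xr <- pmax(r[, "x_right"], as.integer(round(2 * midline_x - r[, "x_left"])))
  m <- cbind(r[, "y"], xl, xr)
  dimnames(m) <- NULL
  contour_rows(contour$kind, m)
}

#' One physical coronal section
#'
#' @param index Rostro-caudal position (integer; one unit = one 80 um
#'   sectioning step).
#' @param contours List of [contour_rows()]; at least one `"allowed"` contour
#'   when the section is present.
#' @param present `FALSE` marks a missing or damaged section to be recreated
#'   by interpolation between its present neighbours.
#' @return An object of class `physical_section`.
#' @export
physical_section <- function(index, contours = list(), present = TRUE) {
  stopifnot(is.numeric(index), length(index) == 1L)
  if (present) {
    if (!length(contours) || !any(vapply(contours, function(ct)
      ct$kind == "allowed", logical(1L)))) {
      stop(sprintf("present section %d needs at least one allowed contour",
                   as.integer(index)))
    }
    lapply(contours, function(ct) stopifnot(inherits(ct, "contour_rows")))
  }
  structure(list(index = as.integer(index), contours = contours,
                 present = isTRUE(present)),
            class = "physical_section")
}

#' A stack of coronal sections
#'
#' @param sections List of [physical_section()]s with strictly increasing
#'   indices.
#' @param cell_um Physical side of one square grid cell (default 6.6 um).
#' @param section_step_um Rostro-caudal distance between consecutive physical
#'   sections (default 80 um).
#' @param midline_x Optional midline x-coordinate recorded for symmetrization.
#' @return An object of class `section_stack`.
#' @export
section_stack <- function(sections, cell_um = 6.6, section_step_um = 80,
                          midline_x = NULL) {
  stopifnot(is.list(sections), length(sections) >= 1L)
  lapply(sections, function(s) stopifnot(inherits(s, "physical_section")))
  idx <- vapply(sections, function(s) s$index, integer(1L))
  if (any(diff(idx) <= 0L)) stop("section indices must be strictly increasing")
  structure(list(sections = sections, cell_um = as.numeric(cell_um),
                 section_step_um = as.numeric(section_step_um),
                 midline_x = if (is.null(midline_x)) NULL else
                   as.numeric(midline_x)),
            class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  n <- length(x$sections)
  miss <- sum(!vapply(x$sections, function(s) s$present, logical(1L)))
  cat(sprintf("Section stack: %d sections (%d missing), %g um steps, %g um cells\n",
              n, miss, x$section_step_um, x$cell_um))
  invisible(x)
}

# Interpolate two matched contours row-by-row; rows present in only one
# neighbour follow the nearest-section rule (ties kept with `a`).
interp_contour_pair <- function(ca, cb, fraction) {
  ra <- ca$rows
  rb <- cb$rows
  ys <- sort(union(ra[, "y"], rb[, "y"]))
  keep <- logical(length(ys))
  out <- matrix(0L, nrow = length(ys), ncol = 3L)
  for (i in seq_along(ys)) {
    y <- ys[i]
    ia <- match(y, ra[, "y"])
    ib <- match(y, rb[, "y"])
    if (!is.na(ia) && !is.na(ib)) {
      xl <- as.integer(round((1 - fraction) * ra[ia, "x_left"] +
                               fraction * rb[ib, "x_left"]))
      xr <- as.integer(round((1 - fraction) * ra[ia, "x_right"] +
                               fraction * rb[ib, "x_right"]))
    } else if (!is.na(ia)) {
      if (fraction > 0.5) next
      xl <- ra[ia, "x_left"]; xr <- ra[ia, "x_right"]
    } else {
      if (fraction <= 0.5) next
      xl <- rb[ib, "x_left"]; xr <- rb[ib, "x_right"]
    }
    keep[i] <- TRUE
    out[i, ] <- c(y, xl, xr)
  }
  contour_rows(ca$kind, out[keep, , drop = FALSE])
}

#' Linearly interpolate between two sections
#'
#' Contours are matched across the two sections by kind and rank order; rows
#' are matched by y, with x-extents rounded to the nearest integer. A row
#' present in only one section is included when `fraction` lies nearer that
#' section, and the same nearest-section rule applies to whole contours left
#' unmatched when the two sections have different contour counts (e.g. a
#' ventricle that ends between sections). With `strict = TRUE` a contour
#' count mismatch is a geometry error instead.
#'
#' @param a,b Present [physical_section()]s.
#' @param fraction Position between `a` (0) and `b` (1).
#' @param strict Error on contour count mismatches rather than applying the
#'   nearest-section rule (default `FALSE`).
#' @return A list of [contour_rows()] for the interpolated plane.
#' @export
interpolate_sections <- function(a, b, fraction, strict = FALSE) {
  stopifnot(inherits(a, "physical_section"), inherits(b, "physical_section"),
            a$present, b$present, fraction >= 0, fraction <= 1)
  out <- list()
  for (kind in c("allowed", "forbidden")) {
    as_ <- Filter(function(ct) ct$kind == kind, a$contours)
    bs_ <- Filter(function(ct) ct$kind == kind, b$contours)
    if (length(as_) != length(bs_) && strict) {
      stop(sprintf(
        "cannot rank-match %s contours between sections %d (%d) and %d (%d)",
        kind, a$index, length(as_), b$index, length(bs_)))
    }
    np <- min(length(as_), length(bs_))
    for (i in seq_len(np)) {
      out[[length(out) + 1L]] <- interp_contour_pair(as_[[i]], bs_[[i]], fraction)
    }
    extra <- if (length(as_) > np && fraction <= 0.5) {
      as_[(np + 1L):length(as_)]
    } else if (length(bs_) > np && fraction > 0.5) {
      bs_[(np + 1L):length(bs_)]
    } else list()
    out <- c(out, extra)
  }
  out
}

# Clip forbidden rows to the allowed extent of the same plane; drops rows that
# fall entirely outside, with a warning.
clip_forbidden <- function(contours) {
  allowed <- Filter(function(ct) ct$kind == "allowed", contours)
  forb <- Filter(function(ct) ct$kind == "forbidden", contours)
  if (!length(forb)) return(contours)
  clipped <- FALSE
  out_f <- list()
  for (ct in forb) {
    r <- ct$rows
    keep <- logical(nrow(r))
    for (i in seq_len(nrow(r))) {
      y <- r[i, "y"]
      spans <- do.call(rbind, lapply(allowed, function(a) {
        j <- match(y, a$rows[, "y"])
        if (is.na(j)) NULL else a$rows[j, c("x_left", "x_right"), drop = FALSE]
      }))
      if (is.null(spans)) { clipped <- TRUE; next }
      xl <- max(r[i, "x_left"], min(spans[, 1L]))
      xr <- min(r[i, "x_right"], max(spans[, 2L]))
      if (xl > xr) { clipped <- TRUE; next }
      if (xl != r[i, "x_left"] || xr != r[i, "x_right"]) clipped <- TRUE
      r[i, "x_left"] <- xl
      r[i, "x_right"] <- xr
      keep[i] <- TRUE
    }
    r <- r[keep, , drop = FALSE]
    # re-split if clipping broke y-contiguity
    if (nrow(r)) {
      grp <- cumsum(c(1L, diff(r[, "y"]) != 1L))
      for (g in unique(grp)) {
        out_f[[length(out_f) + 1L]] <-
          contour_rows("forbidden", r[grp == g, , drop = FALSE])
      }
    }
  }
  if (clipped) {
    warning("forbidden contour rows clipped to the allowed extent")
  }
  c(allowed, out_f)
}

#' Build the voxel volume model from a section stack
#'
#' Missing physical sections are recreated by linear interpolation between
#' their nearest present neighbours (proportionally for runs of misses); each
#' physical step is then subdivided into `subdivisions` virtual slices of
#' about `cell_um` thickness, so that the simulation grid voxels are cubes.
#' The caudal-most section's slices are copies of that section.
#'
#' @param stack A [section_stack()]; at least two sections present, and the
#'   first and last present (no extrapolation).
#' @param subdivisions Virtual slices per physical step (default 12; 80 um /
#'   6.6 um).
#' @param cell_um Physical size of one grid unit (default 6.6 um).
#' @return An object of class `volume_model` with fields `nx`, `ny`,
#'   `z_extent`, the per-slice contour sets, and the rasterized inside mask.
#' @export
build_volume <- function(stack, subdivisions = 12L, cell_um = NULL) {
  stopifnot(inherits(stack, "section_stack"))
  subdivisions <- as.integer(subdivisions)
  stopifnot(subdivisions >= 1L)
  if (is.null(cell_um)) cell_um <- stack$cell_um
  secs <- stack$sections
  n <- length(secs)
  present <- vapply(secs, function(s) s$present, logical(1L))
  if (sum(present) < 2L) stop("need at least two present sections")
  if (!present[1L] || !present[n]) {
    stop("missing sections at the stack ends cannot be extrapolated")
  }
  # recreate missing sections
  pres_idx <- which(present)
  for (i in which(!present)) {
    lo <- max(pres_idx[pres_idx < i])
    hi <- min(pres_idx[pres_idx > i])
    f <- (i - lo) / (hi - lo)
    secs[[i]] <- physical_section(secs[[i]]$index,
                                  interpolate_sections(secs[[lo]], secs[[hi]], f),
                                  present = TRUE)
  }
  z_extent <- subdivisions * n
  slices <- vector("list", z_extent)
  for (k in seq_len(z_extent) - 1L) {
    i <- k %/% subdivisions + 1L
    if (i >= n) {
      cts <- secs[[n]]$contours
    } else {
      f <- (k %% subdivisions) / subdivisions
      cts <- if (f == 0) secs[[i]]$contours else
        interpolate_sections(secs[[i]], secs[[i + 1L]], f)
    }
    slices[[k + 1L]] <- clip_forbidden(cts)
  }
  all_rows <- do.call(rbind, lapply(slices, function(sl)
    do.call(rbind, lapply(sl, function(ct) ct$rows))))
  if (min(all_rows[, "y"]) < 0L || min(all_rows[, "x_left"]) < 0L) {
    stop("contour coordinates must be non-negative (0-based grid)")
  }
  nx <- max(all_rows[, "x_right"]) + 1L
  ny <- max(all_rows[, "y"]) + 1L
  mask <- array(FALSE, dim = c(nx, ny, z_extent))
  for (k in seq_len(z_extent)) {
    for (ct in slices[[k]]) {
      r <- ct$rows
      val <- ct$kind == "allowed"
      for (i in seq_len(nrow(r))) {
        mask[(r[i, "x_left"]:r[i, "x_right"]) + 1L, r[i, "y"] + 1L, k] <- val
      }
    }
    # forbidden overrides allowed where contours overlap
    forb <- Filter(function(ct) ct$kind == "forbidden", slices[[k]])
    for (ct in forb) {
      r <- ct$rows
      for (i in seq_len(nrow(r))) {
        mask[(r[i, "x_left"]:r[i, "x_right"]) + 1L, r[i, "y"] + 1L, k] <- FALSE
      }
    }
  }
  structure(list(slices = slices, nx = nx, ny = ny, z_extent = z_extent,
                 subdivisions = subdivisions, cell_um = cell_um, mask = mask),
            class = "volume_model")
}

#' @export
print.volume_model <- function(x, ...) {
  cat(sprintf("Volume model: %d x %d x %d cells (%.1f um/cell), %d virtual slices/section\n",
              x$nx, x$ny, x$z_extent, x$cell_um, x$subdivisions))
  cat(sprintf("  allowed cells: %d (%.1f%% of bounding box)\n",
              sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Inside-outside test
#'
#' A continuous point lies inside when its floor cell is within bounds, is
#' covered by an allowed contour row of the slice at `floor(z)`, and is not
#' covered by a forbidden row. Total: any real point is answerable, and
#' points beyond the rostral/caudal ends are outside (those ends therefore
#' act as reflecting boundaries for the walker).
#'
#' @param volume A [build_volume()] result.
#' @param point Numeric vector `c(x, y, z)` or an n x 3 matrix of points.
#' @return Logical scalar or vector.
#' @export
is_inside <- function(volume, point) {
  stopifnot(inherits(volume, "volume_model"))
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3L)
  i <- floor(p[, 1L]); j <- floor(p[, 2L]); k <- floor(p[, 3L])
  ok <- i >= 0 & i < volume$nx & j >= 0 & j < volume$ny &
    k >= 0 & k < volume$z_extent & is.finite(i) & is.finite(j) & is.finite(k)
  res <- logical(nrow(p))
  if (any(ok)) {
    idx <- cbind(i[ok] + 1, j[ok] + 1, k[ok] + 1)
    res[ok] <- volume$mask[idx]
  }
  res
}

#' Write a section stack to a JSON manifest
#'
#' The canonical on-disk dialect: a `stack.json` object with `cell_um`,
#' `section_step_um`, `midline_x` and a `sections` array, each section
#' carrying its index, presence flag and contours as `[y, x_left, x_right]`
#' integer triples.
#'
#' @param stack A [section_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "section_stack"))
  obj <- list(
    cell_um = stack$cell_um,
    section_step_um = stack$section_step_um,
    midline_x = stack$midline_x,
    sections = lapply(stack$sections, function(s) list(
      index = s$index,
      present = s$present,
      contours = lapply(s$contours, function(ct) list(
        kind = ct$kind,
        rows = unname(ct$rows)
      ))
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a section stack from a JSON manifest
#'
#' Validates every invariant (consecutive y, `x_left <= x_right`, increasing
#' section indices, presence of allowed contours) and reports the first
#' offending section on failure.
#'
#' @param path Path to a `stack.json` file written by [write_stack()].
#' @return A [section_stack()].
#' @export
read_stack <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("cell_um", "section_step_um", "sections")) {
    if (is.null(obj[[f]])) stop(sprintf("stack manifest lacks field '%s'", f))
  }
  secs <- lapply(seq_along(obj$sections), function(si) {
    s <- obj$sections[[si]]
    cts <- lapply(s$contours, function(ct) {
      rows <- do.call(rbind, lapply(ct$rows, function(r) {
        r <- unlist(r)
        if (length(r) != 3L || any(r != floor(r))) {
          stop(sprintf("section %d: malformed contour row", s$index))
        }
        as.integer(r)
      }))
      tryCatch(contour_rows(ct$kind, rows), error = function(e) {
        stop(sprintf("section %d: %s", s$index, conditionMessage(e)))
      })
    })
    physical_section(s$index, cts, present = isTRUE(s$present))
  })
  section_stack(secs, cell_um = obj$cell_um,
                section_step_um = obj$section_step_um,
                midline_x = obj$midline_x)
}
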