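sq_section <- function(idx, n = 20L, present = TRUE) {
  physical_section(idx, if (present)
    list(contour_rows("allowed", cbind(0:(n - 1L), 0L, n - 1L))) else list(),
    present = present)
}

test_that("contour_rows enforces consecutive y and ordered x", {
  expect_error(contour_rows("allowed", rbind(c(0, 1, 5), c(2, 1, 5))),
               "consecutive")
  expect_error(contour_rows("allowed", rbind(c(0, 6, 5))), "x_left > x_right")
  expect_error(contour_rows("walls", rbind(c(0, 1, 5))))
  ct <- contour_rows("forbidden", rbind(c(3, 1, 5), c(4, 0, 6)))
  expect_identical(ct$kind, "forbidden")
  expect_identical(ct$rows[, "y"], c(3L, 4L))
})

test_that("symmetrization takes the mirror hull and is idempotent", {
  ct <- contour_rows("allowed", rbind(c(0, 3, 7), c(1, 2, 10)))
  s <- symmetrize_contour(ct, 5)
  expect_identical(unname(s$rows[1, ]), c(0L, 3L, 7L))   # already symmetric
  expect_identical(unname(s$rows[2, ]), c(1L, 0L, 10L))  # hull of (2,10)+(0,8)
  expect_identical(symmetrize_contour(s, 5), s)
  expect_error(symmetrize_contour(ct, 30), "x-range")
})

test_that("section interpolation is linear with nearest-section row fallback", {
  a <- physical_section(0, list(contour_rows("allowed",
                                             rbind(c(0, 0, 10), c(1, 0, 10)))))
  b <- physical_section(1, list(contour_rows("allowed", rbind(c(0, 6, 22)))))
  mid <- interpolate_sections(a, b, 0.5)
  expect_identical(unname(mid[[1]]$rows[1, ]), c(0L, 3L, 16L))
  # endpoint identity
  expect_identical(interpolate_sections(a, b, 0)[[1]]$rows, a$contours[[1]]$rows)
  # row y=1 exists only in a: kept near a, dropped near b
  expect_true(1L %in% interpolate_sections(a, b, 0.25)[[1]]$rows[, "y"])
  expect_false(1L %in% interpolate_sections(a, b, 0.75)[[1]]$rows[, "y"])
  # self-interpolation is the identity for any fraction
  for (f in c(0, 0.25, 0.5, 0.75, 1)) {
    expect_identical(interpolate_sections(a, a, f)[[1]]$rows,
                     a$contours[[1]]$rows)
  }
  # strict mode refuses unmatched contours; default applies the nearest rule
  bf <- physical_section(1, c(b$contours,
                              list(contour_rows("forbidden", rbind(c(0, 8, 9))))))
  expect_error(interpolate_sections(a, bf, 0.5, strict = TRUE), "rank-match")
  expect_length(interpolate_sections(a, bf, 0.75), 2L)
  expect_length(interpolate_sections(a, bf, 0.25), 1L)
})

test_that("build_volume extrudes, interpolates missing sections, and counts slices", {
  stack <- section_stack(list(sq_section(0), sq_section(1), sq_section(2)))
  v <- build_volume(stack)
  expect_s3_class(v, "volume_model")
  expect_identical(v$z_extent, 36L)
  expect_identical(dim(v$mask), c(20L, 20L, 36L))
  # identical sections extrude: inside-test constant along z
  expect_true(all(apply(v$mask, c(1, 2), function(col) length(unique(col)) == 1L)))
  # a missing middle section is recreated as the midpoint interpolation
  grow <- function(idx, n) physical_section(idx,
    list(contour_rows("allowed", cbind(0:9, 0L, n))))
  full <- section_stack(list(grow(0, 10L), grow(1, 16L), grow(2, 22L)))
  holed <- section_stack(list(grow(0, 10L),
                              physical_section(1, list(), present = FALSE),
                              grow(2, 22L)))
  expect_identical(build_volume(holed)$mask, build_volume(full)$mask)
  expect_error(build_volume(section_stack(list(
    physical_section(0, list(), present = FALSE), sq_section(1), sq_section(2)))),
    "ends")
  expect_error(build_volume(section_stack(list(
    sq_section(0), physical_section(1, list(), present = FALSE)))),
    "present")
})

test_that("is_inside answers any real point; ends are outside (reflecting)", {
  v <- build_volume(make_slab(20, 20, 2))  # z_extent 24
  expect_identical(v$z_extent, 24L)
  expect_true(is_inside(v, c(5.5, 5.5, 5.5)))
  expect_true(is_inside(v, c(0, 0, 0)))
  expect_false(is_inside(v, c(-0.5, 5, 5)))
  expect_false(is_inside(v, c(5, 5, -0.1)))
  expect_false(is_inside(v, c(5, 5, 24)))
  expect_false(is_inside(v, c(20, 5, 5)))
  expect_identical(is_inside(v, rbind(c(1, 1, 1), c(-1, 1, 1))),
                   c(TRUE, FALSE))
})

test_that("mask agrees cell-for-cell with brute-force contour scanning", {
  ph <- make_brain_phantom(phantom_spec(n_sections = 6L, nx = 41L, ny = 31L))
  v <- build_volume(ph$stack, subdivisions = 2L)
  for (k in seq_len(v$z_extent) - 1L) {
    brute <- outer(seq_len(v$nx) - 1L, seq_len(v$ny) - 1L,
                   Vectorize(function(i, j) brute_inside_cell(v, i, j, k)))
    expect_identical(unname(v$mask[, , k + 1L]), unname(brute))
  }
  # sphere fixture too (curved contours, one section per slice)
  vs <- build_volume(make_sphere_stack(8), subdivisions = 1L)
  for (k in seq_len(vs$z_extent) - 1L) {
    brute <- outer(seq_len(vs$nx) - 1L, seq_len(vs$ny) - 1L,
                   Vectorize(function(i, j) brute_inside_cell(vs, i, j, k)))
    expect_identical(unname(vs$mask[, , k + 1L]), unname(brute))
  }
})

test_that("stack.json round-trips bit-identically and the reader validates", {
  ph <- make_brain_phantom()
  path <- file.path(tempdir(), "stack.json")
  write_stack(ph$stack, path)
  back <- read_stack(path)
  expect_identical(back, ph$stack)
  # corrupt one row: x_left > x_right
  bad <- jsonlite::read_json(path, simplifyVector = FALSE)
  bad$sections[[1]]$contours[[1]]$rows[[1]] <- list(0L, 9L, 2L)
  jsonlite::write_json(bad, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_stack(path), "section 0")
})
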