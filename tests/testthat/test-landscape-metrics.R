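test_that("buffer composition equals exhaustive cell enumeration on a toy raster", {
  set.seed(31)
  ct <- default_class_table()
  vals <- matrix(sample(c(1, 2, 6), 400, replace = TRUE), 20, 20)
  r <- occ_raster(vals, cellsize = 5)
  patch <- rect_poly(30, 30, 50, 55)
  scale <- 12
  comp <- buffer_composition(r, patch, scale, ct)
  # oracle: loop over every cell centre, point-rectangle distance by hand
  counts <- c(`1` = 0, `2` = 0, `6` = 0)
  for (row in 1:20) {
    for (col in 1:20) {
      cx <- (col - 0.5) * 5
      cy <- (20 - row + 0.5) * 5
      dx <- max(30 - cx, 0, cx - 50)
      dy <- max(30 - cy, 0, cy - 55)
      d <- sqrt(dx^2 + dy^2)
      if (d > 0 && d <= scale) {
        key <- as.character(vals[row, col])
        counts[key] <- counts[key] + 1
      }
    }
  }
  props <- counts / sum(counts)
  expect_equal(comp$proportion[comp$class == "crop_pas"], unname(props["1"]))
  expect_equal(comp$proportion[comp$class == "urban"], unname(props["2"]))
  expect_equal(comp$proportion[comp$class == "grass"], unname(props["6"]))
  base <- comp[comp$class != "habitat", ]
  expect_equal(sum(base$proportion), 1)
  expect_equal(
    comp$proportion[comp$class == "habitat"],
    sum(base$proportion[base$class %in% ct$class[ct$habitat]])
  )
})

test_that("an empty buffer ring fails explicitly", {
  r <- occ_raster(matrix(NA_real_, 10, 10), cellsize = 5)
  expect_error(
    buffer_composition(r, rect_poly(10, 10, 40, 40), 10),
    "no classified cells"
  )
})

test_that("proximity index equals the hand-summed area/distance ratios", {
  patches <- tibble::tibble(
    patch_id = 1:3,
    polygon = list(
      rect_poly(0, 0, 10, 10),     # focal
      rect_poly(20, 0, 30, 10),    # area 100, distance 10
      rect_poly(0, 30, 20, 40)     # area 200, distance 20
    )
  )
  expect_equal(proximity_index(patches, 1, scale = 25), 100 / 10 + 200 / 20)
  # neighbour straddling the buffer boundary is counted in full
  expect_equal(proximity_index(patches, 1, scale = 10), 100 / 10)
  # no neighbour within the buffer
  expect_equal(proximity_index(patches, 1, scale = 5), 0)
  # squared-distance convention
  expect_equal(
    proximity_index(patches, 1, scale = 25, squared = TRUE),
    100 / 100 + 200 / 400
  )
})

test_that("proximity is monotone non-decreasing in scale and safe for touching patches", {
  region <- small_region()
  patches <- region$landscape$patches
  scales <- c(25, 50, 100, 200, 400)
  for (id in patches$patch_id[1:4]) {
    prox <- vapply(scales, function(s) proximity_index(patches, id, s), numeric(1))
    expect_true(all(diff(prox) >= 0))
  }
  touching <- tibble::tibble(
    patch_id = 1:2,
    polygon = list(rect_poly(0, 0, 10, 10), rect_poly(10, 0, 20, 10))
  )
  expect_equal(proximity_index(touching, 1, 50, floor_m = 5), 100 / 5)
})

test_that("nearest-patch distance matches hand-placed geometry and is minimal", {
  patches <- tibble::tibble(
    patch_id = 1:3,
    polygon = list(
      rect_poly(0, 0, 10, 10),
      rect_poly(25, 5, 35, 15),   # 15 m from patch 1 (edge-to-edge in x)
      rect_poly(0, 18, 10, 28)    # 8 m above patch 1
    )
  )
  expect_equal(nearest_patch_distance(patches, 1), 8)
  expect_equal(nearest_patch_distance(patches, 3), 8)
  # diagonal separation: corner-to-corner
  diag_patches <- tibble::tibble(
    patch_id = 1:2,
    polygon = list(rect_poly(0, 0, 10, 10), rect_poly(13, 14, 20, 20))
  )
  expect_equal(nearest_patch_distance(diag_patches, 1), 5)
  touching <- tibble::tibble(
    patch_id = 1:2,
    polygon = list(rect_poly(0, 0, 10, 10), rect_poly(10, 0, 20, 10))
  )
  expect_equal(nearest_patch_distance(touching, 1), 0)
  expect_error(
    nearest_patch_distance(touching[1, ], 1),
    "at least two patches"
  )
  # minimality across all patches of the small region
  patches_r <- small_region()$landscape$patches
  for (id in patches_r$patch_id[1:3]) {
    focal <- patches_r$polygon[[match(id, patches_r$patch_id)]]
    np <- nearest_patch_distance(patches_r, id)
    for (other_id in setdiff(patches_r$patch_id, id)) {
      other <- patches_r$polygon[[match(other_id, patches_r$patch_id)]]
      d <- scaleocc:::cpp_dist_segments_segments(
        scaleocc:::poly_segments(focal), scaleocc:::poly_segments(other)
      )
      expect_lte(np, d + 1e-9)
    }
  }
})

test_that("distance to class matches the toy-grid oracle and is translation invariant", {
  ct <- default_class_table()
  vals <- matrix(1, 40, 40) # all crop
  # patch occupies cols 1-4 (x in 0..20); urban cell 10 full cells after the
  # patch edge: gap of 10 cells (50 m)
  vals[20, 15] <- 2
  r <- occ_raster(vals, cellsize = 5)
  patch <- rect_poly(0, 0, 20, 200)
  expect_equal(distance_to_class(r, patch, codes = 2), 50)
  # adjacency gives zero
  vals2 <- vals
  vals2[10, 5] <- 2
  r2 <- occ_raster(vals2, cellsize = 5)
  expect_equal(distance_to_class(r2, patch, codes = 2), 0)
  # translation invariance of the whole scene
  r3 <- occ_raster(vals, xmin = 1000, ymin = -500, cellsize = 5)
  patch3 <- patch
  patch3[, 1] <- patch3[, 1] + 1000
  patch3[, 2] <- patch3[, 2] - 500
  expect_equal(distance_to_class(r3, patch3, codes = 2), 50)
  expect_error(distance_to_class(r, patch, codes = 99), "absent")
})

test_that("distance to a linear feature is zero when crossing, exact otherwise", {
  patch <- rect_poly(0, 0, 10, 10)
  crossing <- cbind(c(-5, 15), c(5, 5))
  expect_equal(distance_to_feature(patch, crossing), 0)
  beside <- cbind(c(17, 17), c(-5, 15))
  expect_equal(distance_to_feature(patch, beside), 7)
})

test_that("patch geometry matches closed forms and is scale invariant", {
  sq <- patch_geometry(rect_poly(0, 0, 100, 100))
  expect_equal(sq$area, 1e4)
  expect_equal(sq$perimeter, 400)
  expect_equal(sq$shape_index, 1)
  rect <- patch_geometry(rect_poly(0, 0, 200, 50))
  expect_equal(rect$shape_index, 500 / (4 * 100))
  expect_equal(rect$per_area, 500 / 1e4)
  # scaling by c leaves shape_index unchanged
  poly <- cbind(c(0, 30, 30, 15, 0), c(0, 0, 20, 35, 20))
  s1 <- patch_geometry(poly)$shape_index
  s2 <- patch_geometry(poly * 7.3)$shape_index
  expect_equal(s1, s2)
  # rectilinear (cell-aligned) outlines always score >= 1: an L-shape
  lshape <- cbind(c(0, 20, 20, 10, 10, 0), c(0, 0, 10, 10, 30, 30))
  expect_gte(patch_geometry(lshape)$shape_index, 1 - 1e-9)
  expect_error(patch_geometry(cbind(c(0, 1, 2), c(0, 0, 0))), "degenerate")
})

test_that("traced patch outlines agree with their cell sets", {
  land <- small_region()$landscape
  cs <- land$land_cover$cellsize
  for (i in seq_len(nrow(land$patches))) {
    ncells <- nrow(land$patches$cells[[i]])
    expect_equal(poly_area(land$patches$polygon[[i]]), ncells * cs^2)
    # rectilinear outlines satisfy the square-normalized lower bound
    expect_gte(patch_geometry(land$patches$polygon[[i]])$shape_index, 1 - 1e-9)
  }
})

test_that("patch metrics table is tidy and complete", {
  region <- small_region()
  m <- patch_metrics(region$landscape, scales = c(50, 150))
  expect_equal(nrow(m), nrow(region$landscape$patches))
  expect_true(all(c(
    "patch_id", "area", "perimeter", "per_area", "shape_index",
    "np_dist", "dist_river", "dist_crop", "dist_urban",
    "habitat_50", "crop_pas_50", "urban_50", "prox_50",
    "habitat_150", "crop_pas_150", "urban_150", "prox_150"
  ) %in% names(m)))
  expect_true(all(m$area > 0))
  expect_true(all(m$prox_150 >= m$prox_50))
  comp_cols <- c("habitat_50", "crop_pas_50", "urban_50")
  expect_true(all(dplyr::select(m, dplyr::all_of(comp_cols)) >= 0))
  expect_true(all(dplyr::select(m, dplyr::all_of(comp_cols)) <= 1))
})
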