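# Landscape composition/configuration variables of the patch-landscape
# design. Vector polygons are authoritative for geometry; the raster is
# authoritative for composition; cell membership is by cell centre.

#' Default land-cover class table
#'
#' Class names, integer codes and habitat membership used throughout the
#' package. "Habitat" composition is the sum of the proportions of all
#' habitat-flagged classes. The `river` class is the rasterized linear
#' water feature.
#'
#' @return A tibble with columns `class`, `code`, `habitat`.
#' @export
default_class_table <- function() {
  tibble::tribble(
    ~class,        ~code, ~habitat,
    "crop_pas",        1, FALSE,
    "urban",           2, FALSE,
    "river",           3, FALSE,
    "bare_soil",       4, TRUE,
    "rocky_veg",       5, TRUE,
    "grass",           6, TRUE,
    "dry_grass",       7, TRUE,
    "humid_grass",     8, FALSE,
    "shrubland",       9, TRUE,
    "trans_veg",      10, TRUE,
    "woodland",       11, TRUE,
    "openwood",       12, TRUE,
    "densewood",      13, FALSE
  )
}

#' Default buffer scale set (m)
#'
#' Buffer distances at which composition variables and the proximity index
#' are evaluated: 50, 150, 250, 500, 750, 1000, 1500, 2000, 2500, 3000 m.
#'
#' @return Numeric vector of strictly increasing distances.
#' @export
default_scales <- function() c(50, 150, 250, 500, 750, 1000, 1500, 2000, 2500, 3000)

check_scales <- function(scales) {
  stopifnot(length(scales) >= 1, all(scales > 0), !is.unsorted(scales, strictly = TRUE))
  scales
}

#' Land-cover composition in a buffer ring around a patch
#'
#' Proportions of each land-cover class among cells whose centres fall in
#' the ring `0 < d <= scale`, where `d` is distance to the patch boundary
#' (cells inside the focal patch are excluded; cells of other patches are
#' not). An aggregate `habitat` proportion (sum over habitat-flagged
#' classes) is appended; base-class proportions sum to 1.
#'
#' @param raster land-cover [occ_raster()] of integer class codes.
#' @param patch_polygon open-ring polygon of the focal patch (metres).
#' @param scale buffer distance (m), > 0.
#' @param class_table tibble as [default_class_table()].
#' @return Tibble with columns `class`, `proportion`; one row per base class
#'   present in the table plus one `habitat` aggregate row.
#' @export
buffer_composition <- function(raster, patch_polygon, scale,
                               class_table = default_class_table()) {
  stopifnot(scale > 0)
  d <- ring_distances(raster, patch_polygon, scale)
  ring <- which(d$dist > 0 & d$dist <= scale)
  vals <- as.vector(raster$values)[d$index][ring]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    stop("buffer ring contains no classified cells at scale ", scale, " m")
  }
  composition_from_codes(vals, class_table)
}

composition_from_codes <- function(vals, class_table) {
  counts <- vapply(class_table$code, function(cd) sum(vals == cd), numeric(1))
  props <- counts / length(vals)
  out <- tibble::tibble(class = class_table$class, proportion = props)
  dplyr::bind_rows(
    out,
    tibble::tibble(
      class = "habitat",
      proportion = sum(props[class_table$habitat])
    )
  )
}

# Distances from cell centres (in the bbox of the polygon grown by `scale`)
# to the polygon boundary; returns linear cell indexes and distances.
ring_distances <- function(raster, patch_polygon, scale) {
  ext <- raster_extent(raster)
  cs <- raster$cellsize
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  xr <- range(patch_polygon[, 1]); yr <- range(patch_polygon[, 2])
  c0 <- max(1L, floor((xr[1] - scale - raster$xmin) / cs) + 1L)
  c1 <- min(nc, ceiling((xr[2] + scale - raster$xmin) / cs))
  r1 <- min(nr, nr - floor((yr[1] - scale - raster$ymin) / cs))
  r0 <- max(1L, nr - ceiling((yr[2] + scale - raster$ymin) / cs) + 1L)
  rows <- rep(r0:r1, times = c1 - c0 + 1L)
  cols <- rep(c0:c1, each = r1 - r0 + 1L)
  pts <- cell_center_xy(raster, rows, cols)
  list(
    index = (cols - 1L) * nr + rows,
    dist = dist_points_to_poly(pts, patch_polygon)
  )
}

#' Proximity index of a focal patch
#'
#' Scale-dependent isolation measure: the sum, over all non-focal patches
#' whose polygon falls at least partially within the buffer of the given
#' distance around the focal patch, of patch area divided by edge-to-edge
#' distance to the focal patch. Patches touching the focal patch have their
#' distance floored at `floor_m` so the ratio stays finite. `squared = TRUE`
#' divides by squared distance instead (the FRAGSTATS PROX convention).
#'
#' @param patches patch tibble with `patch_id` and `polygon` columns.
#' @param focal_id id of the focal patch.
#' @param scale buffer distance (m), > 0.
#' @param squared use area / distance^2 instead of area / distance.
#' @param floor_m minimum distance (m) substituted for touching patches.
#' @return Dimensionless proximity index (0 when no patch is in the buffer).
#' @export
proximity_index <- function(patches, focal_id, scale, squared = FALSE,
                            floor_m = 5) {
  stopifnot(scale > 0)
  focal <- patches$polygon[[match(focal_id, patches$patch_id)]]
  others <- patches[patches$patch_id != focal_id, ]
  if (nrow(others) == 0) return(0)
  total <- 0
  for (i in seq_len(nrow(others))) {
    poly <- others$polygon[[i]]
    d <- dist_poly_to_poly(focal, poly)
    if (d <= scale) {
      total <- total + poly_area(poly) / max(d, floor_m)^(if (squared) 2 else 1)
    }
  }
  total
}

#' Edge-to-edge distance to the nearest patch
#'
#' Minimum Euclidean distance between the boundary of the focal patch and
#' the boundary of any other patch; 0 if two boundaries touch or cross.
#'
#' @inheritParams proximity_index
#' @return Distance in metres.
#' @export
nearest_patch_distance <- function(patches, focal_id) {
  if (nrow(patches) < 2) {
    stop("nearest_patch_distance needs at least two patches")
  }
  focal <- patches$polygon[[match(focal_id, patches$patch_id)]]
  others <- patches[patches$patch_id != focal_id, ]
  min(vapply(
    others$polygon,
    function(poly) dist_poly_to_poly(focal, poly),
    numeric(1)
  ))
}

#' Distance from a patch to the nearest cell of a land-cover class
#'
#' Edge-to-edge distance between the patch polygon and the nearest raster
#' cell (treated as a square of ground) carrying any of the given class
#' codes; 0 if the patch touches or overlaps such a cell.
#'
#' @param raster land-cover [occ_raster()].
#' @param patch_polygon open-ring polygon (metres).
#' @param codes integer class code(s) defining the target class.
#' @return Distance in metres.
#' @export
distance_to_class <- function(raster, patch_polygon, codes) {
  hits <- which(matrix(as.vector(raster$values) %in% codes,
    nrow = nrow(raster$values)
  ), arr.ind = TRUE)
  if (nrow(hits) == 0) {
    stop("class code(s) ", paste(codes, collapse = ","), " absent from raster")
  }
  centers <- cell_center_xy(raster, hits[, 1], hits[, 2])
  dcent <- dist_points_to_poly(centers, patch_polygon)
  if (min(dcent) == 0) return(0)
  # refine candidates whose centre distance could still win edge-to-edge
  cand <- which(dcent <= min(dcent) + raster$cellsize)
  segs <- poly_segments(patch_polygon)
  best <- Inf
  for (k in cand) {
    d <- cpp_dist_segments_segments(
      segs, cell_square_segments(raster, hits[k, 1], hits[k, 2])
    )
    if (d < best) best <- d
    if (best == 0) break
  }
  best
}

#' Distance from a patch to a linear feature
#'
#' Minimum distance between the patch boundary and a polyline (e.g. a
#' river); 0 if the polyline crosses or touches the patch.
#'
#' @param patch_polygon open-ring polygon (metres).
#' @param line k x 2 polyline coordinate matrix (metres).
#' @return Distance in metres.
#' @export
distance_to_feature <- function(patch_polygon, line) {
  lsegs <- cbind(
    line[-nrow(line), 1], line[-nrow(line), 2],
    line[-1, 1], line[-1, 2]
  )
  cpp_dist_segments_segments(poly_segments(patch_polygon), lsegs)
}

#' Patch geometry metrics
#'
#' Area, perimeter, perimeter-to-area ratio and shape index of a simple
#' polygon. The shape index normalizes the perimeter by that of a square of
#' equal area, `P / (4 * sqrt(A))`: exactly 1 for a square, larger for
#' irregular shapes, and invariant to uniform rescaling.
#'
#' @param patch_polygon open-ring polygon (metres).
#' @return Tibble with one row: `area` (m^2), `perimeter` (m), `per_area`
#'   (1/m), `shape_index` (dimensionless).
#' @export
patch_geometry <- function(patch_polygon) {
  a <- poly_area(patch_polygon)
  if (a <= 0) stop("degenerate polygon with zero area")
  p <- poly_perimeter(patch_polygon)
  tibble::tibble(
    area = a, perimeter = p,
    per_area = p / a, shape_index = p / (4 * sqrt(a))
  )
}

#' All landscape and geometry metrics for every patch
#'
#' One tidy row per patch: geometry, nearest-patch distance, distances to
#' the river line and to the crop and urban classes, and — at every scale —
#' buffer composition proportions (`habitat_<s>`, `crop_pas_<s>`,
#' `urban_<s>`) and the proximity index (`prox_<s>`). Composition at all
#' scales reuses a single distance pass per patch over the raster window of
#' the largest scale.
#'
#' @param landscape a landscape list as produced by [generate_landscape()],
#'   or any list with elements `land_cover`, `patches`, `river` (optional),
#'   `class_table` (optional).
#' @param scales buffer distances (m), strictly increasing.
#' @param composition_classes base classes reported per scale.
#' @param squared_prox use the squared-distance proximity convention.
#' @return Tibble, one row per patch.
#' @export
patch_metrics <- function(landscape, scales = default_scales(),
                          composition_classes = c("habitat", "crop_pas", "urban"),
                          squared_prox = FALSE) {
  check_scales(scales)
  raster <- landscape$land_cover
  patches <- landscape$patches
  class_table <- landscape$class_table %||% default_class_table()
  n <- nrow(patches)
  crop_codes <- class_table$code[class_table$class == "crop_pas"]
  urban_codes <- class_table$code[class_table$class == "urban"]
  vals <- as.vector(raster$values)

  # pairwise edge-to-edge distances, computed once and reused by np_dist
  # and by prox at every scale
  D <- matrix(0, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- dist_poly_to_poly(
          patches$polygon[[i]], patches$polygon[[j]]
        )
      }
    }
  }
  areas_all <- vapply(patches$polygon, poly_area, numeric(1))

  rows <- purrr::map(seq_len(n), function(i) {
    poly <- patches$polygon[[i]]
    id <- patches$patch_id[i]
    out <- patch_geometry(poly)
    out$patch_id <- id
    out$np_dist <- if (n >= 2) min(D[i, -i]) else NA_real_
    out$dist_river <- if (!is.null(landscape$river)) {
      distance_to_feature(poly, landscape$river)
    } else {
      NA_real_
    }
    out$dist_crop <- distance_to_class(raster, poly, crop_codes)
    out$dist_urban <- distance_to_class(raster, poly, urban_codes)
    d <- ring_distances(raster, poly, max(scales))
    for (s in scales) {
      ring <- which(d$dist > 0 & d$dist <= s)
      v <- vals[d$index][ring]
      v <- v[!is.na(v)]
      if (length(v) == 0) {
        stop("empty buffer ring for patch ", id, " at scale ", s, " m")
      }
      comp <- composition_from_codes(v, class_table)
      for (cl in composition_classes) {
        out[[paste0(cl, "_", s)]] <- comp$proportion[comp$class == cl]
      }
      within_buffer <- which(D[i, ] <= s & seq_len(n) != i)
      out[[paste0("prox_", s)]] <- sum(
        areas_all[within_buffer] /
          pmax(D[i, within_buffer], raster$cellsize)^(if (squared_prox) 2 else 1)
      )
    }
    out
  })
  dplyr::bind_rows(rows) |>
    dplyr::relocate("patch_id")
}
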