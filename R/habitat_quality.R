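# Patch habitat-quality covariates: foliage height diversity, patch
# vegetation structure, DEM-derived slope. Radiation, when present, is a
# pass-through column supplied by the user.

#' Foliage height diversity of one vegetation plot
#'
#' Shannon entropy of the normalized coverage vector across the nine
#' structural classes (herbs <30 cm, herbs 40-80 cm, herbs >90 cm, woody
#' <2 m, woody >2 m, dry leaves, rocks and fallen trunks, bare soil,
#' branches). All nine classes enter by default; `mask` restricts the
#' index to a subset (e.g. foliage-only).
#'
#' @param coverages numeric vector of 9 coverage percentages in \[0, 100\].
#' @param base logarithm base; natural log by default, use `2` for bits.
#' @param mask optional logical vector selecting the classes that enter.
#' @return FHD value in `[0, log(9)]` (for the default base and full mask).
#' @export
fhd <- function(coverages, base = exp(1), mask = NULL) {
  if (!is.null(mask)) coverages <- coverages[mask]
  stopifnot(all(coverages >= 0))
  tot <- sum(coverages)
  if (tot <= 0) stop("all coverage classes are zero; FHD undefined")
  q <- coverages / tot
  q <- q[q > 0]
  -sum(q * log(q, base = base))
}

#' Patch vegetation structure from plot FHD values
#'
#' Plot FHD values are averaged within habitat type — pooled across all
#' patches supplying plots of that type — and the patch score is the mean
#' of the type-level FHD values weighted by the area each habitat type
#' occupies within the patch. The result is a convex combination of the
#' type means.
#'
#' @param plots tibble with columns `habitat_type` and the nine coverage
#'   columns `cover_1` ... `cover_9` (one row per plot; plots from all
#'   patches in the region).
#' @param habitat_type_areas named numeric vector: area (m^2) of each
#'   habitat type within the focal patch.
#' @param ... passed on to [fhd()].
#' @return `veg_str`, the area-weighted mean FHD (dimensionless).
#' @export
patch_veg_structure <- function(plots, habitat_type_areas, ...) {
  habitat_type_areas <- habitat_type_areas[habitat_type_areas > 0]
  if (length(habitat_type_areas) == 0) stop("no habitat type with positive area")
  cover_cols <- grep("^cover_", names(plots), value = TRUE)
  stopifnot(length(cover_cols) == 9)
  plot_fhd <- apply(as.matrix(plots[cover_cols]), 1, fhd, ...)
  type_mean <- tapply(plot_fhd, plots$habitat_type, mean)
  missing <- setdiff(names(habitat_type_areas), names(type_mean))
  if (length(missing) > 0) {
    stop(
      "habitat type(s) with area but no plot FHD estimate: ",
      paste(missing, collapse = ", ")
    )
  }
  w <- habitat_type_areas / sum(habitat_type_areas)
  sum(type_mean[names(w)] * w)
}

#' Patch vegetation structure for every patch
#'
#' Tidy wrapper around [patch_veg_structure()]: pools plot FHD by habitat
#' type across the whole region once, then computes the area-weighted
#' score per patch.
#'
#' @param plots region plot table (see [patch_veg_structure()]), with a
#'   `patch_id` column.
#' @param type_areas tibble with columns `patch_id`, `habitat_type`,
#'   `area` (m^2 of that type within that patch).
#' @param ... passed on to [fhd()].
#' @return Tibble with `patch_id`, `veg_str`.
#' @export
veg_structure_table <- function(plots, type_areas, ...) {
  type_areas |>
    dplyr::group_by(.data$patch_id) |>
    dplyr::summarise(veg_str = patch_veg_structure(
      plots,
      stats::setNames(.data$area, .data$habitat_type),
      ...
    )) |>
    dplyr::ungroup()
}

#' Mean terrain slope of a patch
#'
#' Per-cell slope by Horn's 3x3 finite-difference method on the DEM,
#' averaged over DEM cells whose centres fall inside the patch polygon.
#' If the patch is too small to contain any DEM cell centre, the slope of
#' the nearest DEM cell is used. Border DEM cells (incomplete 3x3
#' neighbourhood) carry no slope estimate.
#'
#' @param dem elevation [occ_raster()] (metres).
#' @param patch_polygon open-ring polygon (metres).
#' @return Mean slope in degrees, in `[0, 90]`.
#' @export
dem_slope <- function(dem, patch_polygon) {
  ext <- raster_extent(dem)
  xr <- range(patch_polygon[, 1]); yr <- range(patch_polygon[, 2])
  if (xr[1] < ext["xmin"] - 1e-9 || xr[2] > ext["xmax"] + 1e-9 ||
      yr[1] < ext["ymin"] - 1e-9 || yr[2] > ext["ymax"] + 1e-9) {
    stop("patch polygon extends outside the DEM")
  }
  sl <- horn_slope(dem)
  centers <- cell_centers(dem)
  vals <- as.vector(sl)
  ok <- !is.na(vals)
  inside <- cpp_points_in_polygon(centers, patch_polygon) & ok
  if (any(inside)) {
    mean(vals[inside])
  } else {
    ctr <- matrix(poly_centroid(patch_polygon), ncol = 2)
    d <- cpp_dist_points_points(centers[ok, , drop = FALSE], ctr)
    vals[ok][which.min(d)]
  }
}

# Horn (1981) 3x3 slope in degrees; NA on the border.
horn_slope <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("DEM too small for a 3x3 slope window")
  cs <- dem$cellsize
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  # neighbours: letters a b c / d e f / g h k, row 1 = north
  a <- z[i - 1, j - 1]; b <- z[i - 1, j]; cc <- z[i - 1, j + 1]
  d <- z[i, j - 1];                      f <- z[i, j + 1]
  g <- z[i + 1, j - 1]; h <- z[i + 1, j]; k <- z[i + 1, j + 1]
  dzdx <- ((cc + 2 * f + k) - (a + 2 * d + g)) / (8 * cs)
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + k)) / (8 * cs)
  out <- matrix(NA_real_, nr, nc)
  out[i, j] <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  out
}
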