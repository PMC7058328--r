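# GeoJSON exchange for patch polygons and polylines. Coordinates are planar
# metres; the files carry no CRS member and are read back verbatim.

#' Write / read patch polygons as GeoJSON
#'
#' Patches travel as a `FeatureCollection` of `Polygon` features with
#' `patch_id` (and any other scalar columns) in `properties`. The polygon
#' list-column holds open rings (k x 2 matrices, metres).
#'
#' @param patches tibble with columns `patch_id` and `polygon` (list of
#'   k x 2 matrices) plus optional scalar property columns.
#' @param path file path.
#' @return `write_patches_geojson` returns `path` invisibly;
#'   `read_patches_geojson` returns the patch tibble.
#' @export
write_patches_geojson <- function(patches, path) {
  keep <- setdiff(names(patches), c("polygon", "cells"))
  features <- purrr::map(seq_len(nrow(patches)), function(i) {
    ring <- close_ring(patches$polygon[[i]])
    props <- as.list(patches[i, keep, drop = FALSE])
    list(
      type = "Feature",
      properties = props,
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(j) ring[j, ]))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_patches_geojson
#' @export
read_patches_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  rows <- purrr::map(fc$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    # drop the closing vertex to get an open ring
    if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
    dimnames(ring) <- list(NULL, c("x", "y"))
    props <- lapply(f$properties, function(p) if (is.null(p)) NA else p)
    tibble::tibble(!!!props, polygon = list(ring))
  })
  dplyr::bind_rows(rows)
}

#' Write / read a polyline as GeoJSON
#'
#' @param coords k x 2 coordinate matrix (metres).
#' @param path file path.
#' @return `write_line_geojson` returns `path` invisibly;
#'   `read_line_geojson` returns the coordinate matrix.
#' @export
write_line_geojson <- function(coords, path) {
  jsonlite::write_json(
    list(
      type = "FeatureCollection",
      features = list(list(
        type = "Feature",
        properties = list(name = "river"),
        geometry = list(
          type = "LineString",
          coordinates = lapply(seq_len(nrow(coords)), function(j) coords[j, ])
        )
      ))
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_line_geojson
#' @export
read_line_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  m <- do.call(rbind, lapply(fc$features[[1]]$geometry$coordinates, unlist))
  dimnames(m) <- list(NULL, c("x", "y"))
  m
}
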