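#' Planar raster with integer or numeric cells
#'
#' A minimal in-memory raster: a matrix of cell values plus a planar extent
#' in metres. Row 1 is the northernmost row (the usual on-screen and ESRI
#' ASCII ordering); column 1 is the westernmost column. All package
#' computations assume planar coordinates in metres — no geographic CRS math
#' is performed.
#'
#' @param values numeric or integer matrix of cell values.
#' @param xmin,ymin coordinates (m) of the lower-left corner of the grid.
#' @param cellsize cell edge length (m).
#' @return An object of class `occ_raster`.
#' @export
occ_raster <- function(values, xmin = 0, ymin = 0, cellsize = 5) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cellsize = cellsize),
    class = "occ_raster"
  )
}

#' @export
print.occ_raster <- function(x, ...) {
  cat(sprintf(
    "<occ_raster> %d x %d cells, %.6g m resolution, origin (%.6g, %.6g)\n",
    nrow(x$values), ncol(x$values), x$cellsize, x$xmin, x$ymin
  ))
  invisible(x)
}

#' @export
dim.occ_raster <- function(x) dim(x$values)

raster_extent <- function(r) {
  c(
    xmin = r$xmin, xmax = r$xmin + ncol(r$values) * r$cellsize,
    ymin = r$ymin, ymax = r$ymin + nrow(r$values) * r$cellsize
  )
}

#' Coordinates of all cell centres
#'
#' @param r an [occ_raster()].
#' @return A two-column matrix (x, y) in row-major (by matrix column) order
#'   matching `as.vector(r$values)`.
#' @export
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cellsize
  xs <- r$xmin + (seq_len(nc) - 0.5) * cs
  ys <- r$ymin + (nr - seq_len(nr) + 0.5) * cs
  cbind(x = rep(xs, each = nr), y = rep(ys, times = nc))
}

# Centre coordinates for (row, col) index pairs.
cell_center_xy <- function(r, rows, cols) {
  cs <- r$cellsize
  cbind(
    x = r$xmin + (cols - 0.5) * cs,
    y = r$ymin + (nrow(r$values) - rows + 0.5) * cs
  )
}

#' Read or write a raster as an ESRI ASCII grid
#'
#' Plain-text grid exchange format (`ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value` header followed by rows north to south). `NA` cells are
#' written as the nodata value.
#'
#' @param r an [occ_raster()].
#' @param path file path.
#' @param nodata nodata sentinel used on write.
#' @return `write_esri_ascii` returns `path` invisibly; `read_esri_ascii`
#'   returns an [occ_raster()].
#' @export
write_esri_ascii <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  header <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", r$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(v, 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_esri_ascii
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  vals <- stats::setNames(
    vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
    tolower(vapply(kv, `[`, character(1), 1))
  )
  body <- lines[-(1:6)]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  m[m == vals[["nodata_value"]]] <- NA
  occ_raster(m,
    xmin = vals[["xllcorner"]], ymin = vals[["yllcorner"]],
    cellsize = vals[["cellsize"]]
  )
}
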