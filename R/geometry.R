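# Planar polygon helpers. Polygons are open rings: k x 2 coordinate matrices
# in metres, vertices in order, first vertex not repeated at the end.

close_ring <- function(poly) rbind(poly, poly[1, , drop = FALSE])

poly_segments <- function(poly) {
  p1 <- poly
  p2 <- poly[c(2:nrow(poly), 1), , drop = FALSE]
  cbind(p1, p2)
}

#' Polygon area and perimeter
#'
#' Shoelace area (absolute value) and boundary length of a simple planar
#' polygon given as an open ring.
#'
#' @param poly k x 2 coordinate matrix (metres), vertices in order.
#' @return Area in m^2 / perimeter in m.
#' @export
poly_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' @rdname poly_area
#' @export
poly_perimeter <- function(poly) {
  segs <- poly_segments(poly)
  sum(sqrt((segs[, 3] - segs[, 1])^2 + (segs[, 4] - segs[, 2])^2))
}

poly_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + xs) * cr) / (6 * a), sum((y + ys) * cr) / (6 * a))
}

# Distance from points (n x 2) to a polygon: 0 inside or on the boundary,
# else distance to the nearest boundary segment.
dist_points_to_poly <- function(pts, poly) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  d <- cpp_dist_points_segments(pts, poly_segments(poly))
  inside <- cpp_points_in_polygon(pts, poly)
  d[inside] <- 0
  d
}

# Edge-to-edge distance between two polygons (0 if boundaries cross or touch).
dist_poly_to_poly <- function(poly_a, poly_b) {
  cpp_dist_segments_segments(poly_segments(poly_a), poly_segments(poly_b))
}

# Outline of a set of raster cells as a rectilinear polygon. Cells are given
# as (row, col) pairs on raster r; the set must be edge-connected and simply
# connected (no holes, no diagonal-only pinch points). Shared edges between
# neighbouring cells cancel; the surviving edges are chained into one ring.
cells_to_polygon <- function(r, cells) {
  if (!is.matrix(cells)) cells <- matrix(cells, ncol = 2)
  nr <- nrow(r$values)
  cs <- r$cellsize
  # grid vertex (i, j) = corner at x = xmin + j*cs, y = ymin + (nr - i)*cs,
  # i in 0..nr (top to bottom), j in 0..ncol.
  vid <- function(i, j) i * (ncol(r$values) + 1L) + j + 1L
  edges <- vector("list", nrow(cells) * 4L)
  k <- 0L
  for (idx in seq_len(nrow(cells))) {
    i <- cells[idx, 1]; j <- cells[idx, 2]
    corners <- c(vid(i - 1L, j - 1L), vid(i - 1L, j), vid(i, j), vid(i, j - 1L))
    for (e in 1:4) {
      a <- corners[e]; b <- corners[e %% 4L + 1L]
      k <- k + 1L
      edges[[k]] <- c(min(a, b), max(a, b))
    }
  }
  em <- do.call(rbind, edges)
  key <- paste(em[, 1], em[, 2])
  boundary <- em[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  # chain the boundary edges into a ring
  adj <- split(
    c(boundary[, 2], boundary[, 1]),
    c(boundary[, 1], boundary[, 2])
  )
  start <- boundary[1, 1]
  ring <- integer(nrow(boundary))
  ring[1] <- start
  prev <- -1L
  cur <- start
  for (s in seq_len(nrow(boundary))[-1]) {
    nxt <- adj[[as.character(cur)]]
    nxt <- nxt[nxt != prev]
    if (length(nxt) == 0L) stop("patch outline could not be traced")
    prev <- cur
    cur <- nxt[1]
    ring[s] <- cur
  }
  ncp1 <- ncol(r$values) + 1L
  i <- (ring - 1L) %/% ncp1
  j <- (ring - 1L) %% ncp1
  coords <- cbind(
    x = r$xmin + j * cs,
    y = r$ymin + (nr - i) * cs
  )
  drop_collinear(coords)
}

# Remove vertices that sit on a straight run between their neighbours.
drop_collinear <- function(coords) {
  n <- nrow(coords)
  if (n <= 4) return(coords)
  keep <- logical(n)
  for (v in seq_len(n)) {
    a <- coords[if (v == 1) n else v - 1, ]
    b <- coords[v, ]
    cc <- coords[if (v == n) 1 else v + 1, ]
    cross <- (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1])
    keep[v] <- abs(cross) > 1e-9
  }
  coords[keep, , drop = FALSE]
}

# Segments of a raster cell treated as a square patch of ground.
cell_square_segments <- function(r, row, col) {
  cs <- r$cellsize
  x0 <- r$xmin + (col - 1) * cs
  y0 <- r$ymin + (nrow(r$values) - row) * cs
  poly_segments(cbind(
    c(x0, x0 + cs, x0 + cs, x0),
    c(y0, y0, y0 + cs, y0 + cs)
  ))
}
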