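# Planar geometry primitives on lon/lat coordinates.
#
# All region geometries handled by this package are stored as a list of
# polygons (a "multipolygon"); each polygon is a list of rings; each ring is a
# closed n x 2 numeric matrix (first row == last row) of lon/lat vertices.
# Containment uses the even-odd rule, so holes need no special casing.

.EPS <- 1e-9

#' Test points against a multipolygon geometry
#'
#' Even-odd (ray casting) containment of points in a multipolygon. Points
#' exactly on a boundary may land on either side; callers that need boundary
#' determinism must keep test points off polygon edges (grid-cell centers are
#' strictly interior to lattice-aligned regions by construction).
#'
#' @param lon,lat numeric vectors of equal length, point coordinates in degrees.
#' @param geom multipolygon: list of polygons, each a list of closed ring
#'   matrices (n x 2).
#' @return logical vector, `TRUE` where the point falls inside the geometry.
#' @export
points_in_geom <- function(lon, lat, geom) {
  stopifnot(length(lon) == length(lat))
  inside <- rep(FALSE, length(lon))
  for (poly in geom) {
    crossings <- integer(length(lon))
    for (ring in poly) {
      x <- ring[, 1]; y <- ring[, 2]
      n <- length(x) - 1L  # closed ring
      for (i in seq_len(n)) {
        x1 <- x[i]; y1 <- y[i]; x2 <- x[i + 1L]; y2 <- y[i + 1L]
        if (y1 == y2) next
        str <- ((y1 > lat) != (y2 > lat)) &
          (lon < (x2 - x1) * (lat - y1) / (y2 - y1) + x1)
        crossings <- crossings + as.integer(str)
      }
    }
    inside <- inside | (crossings %% 2L == 1L)
  }
  inside
}

# Flatten a multipolygon into a segment matrix (x1, y1, x2, y2), one row per
# boundary edge across all rings.
geom_segments <- function(geom) {
  segs <- list()
  for (poly in geom) {
    for (ring in poly) {
      n <- nrow(ring) - 1L
      if (n < 1L) next
      segs[[length(segs) + 1L]] <- cbind(
        ring[seq_len(n), 1], ring[seq_len(n), 2],
        ring[seq_len(n) + 1L, 1], ring[seq_len(n) + 1L, 2]
      )
    }
  }
  do.call(rbind, segs)
}

# Shoelace area of a multipolygon in squared degrees; holes (even-odd) are
# assumed absent in generated mosaics, so rings simply add absolute areas.
geom_area_deg2 <- function(geom) {
  tot <- 0
  for (poly in geom) {
    for (ring in poly) {
      x <- ring[, 1]; y <- ring[, 2]
      n <- nrow(ring) - 1L
      tot <- tot + abs(sum(x[1:n] * y[2:(n + 1)] - x[2:(n + 1)] * y[1:n])) / 2
    }
  }
  tot
}

# Classify how two segment sets touch. Returns list(edge =, point =):
# `edge` TRUE when some pair of segments overlaps collinearly with positive
# length; `point` TRUE when some pair intersects (possibly only at a point).
# Vectorized over the full cross product of segment pairs with a bounding-box
# prefilter, adequate for the mosaic sizes this package targets.
segments_touch <- function(A, B, eps = .EPS) {
  if (is.null(A) || is.null(B) || nrow(A) == 0L || nrow(B) == 0L) {
    return(list(edge = FALSE, point = FALSE))
  }
  # bbox prefilter per pair
  axmin <- pmin(A[, 1], A[, 3]); axmax <- pmax(A[, 1], A[, 3])
  aymin <- pmin(A[, 2], A[, 4]); aymax <- pmax(A[, 2], A[, 4])
  bxmin <- pmin(B[, 1], B[, 3]); bxmax <- pmax(B[, 1], B[, 3])
  bymin <- pmin(B[, 2], B[, 4]); bymax <- pmax(B[, 2], B[, 4])

  ia <- rep(seq_len(nrow(A)), times = nrow(B))
  ib <- rep(seq_len(nrow(B)), each = nrow(A))
  keep <- axmin[ia] <= bxmax[ib] + eps & axmax[ia] >= bxmin[ib] - eps &
    aymin[ia] <= bymax[ib] + eps & aymax[ia] >= bymin[ib] - eps
  if (!any(keep)) return(list(edge = FALSE, point = FALSE))
  ia <- ia[keep]; ib <- ib[keep]

  p1x <- A[ia, 1]; p1y <- A[ia, 2]; p2x <- A[ia, 3]; p2y <- A[ia, 4]
  q1x <- B[ib, 1]; q1y <- B[ib, 2]; q2x <- B[ib, 3]; q2y <- B[ib, 4]

  cross3 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  d1 <- cross3(p1x, p1y, p2x, p2y, q1x, q1y)
  d2 <- cross3(p1x, p1y, p2x, p2y, q2x, q2y)
  d3 <- cross3(q1x, q1y, q2x, q2y, p1x, p1y)
  d4 <- cross3(q1x, q1y, q2x, q2y, p2x, p2y)

  collinear <- abs(d1) <= eps & abs(d2) <= eps
  # project collinear pairs onto the dominant axis of segment p
  dx <- p2x - p1x; dy <- p2y - p1y
  usex <- abs(dx) >= abs(dy)
  pa <- ifelse(usex, p1x, p1y); pb <- ifelse(usex, p2x, p2y)
  qa <- ifelse(usex, q1x, q1y); qb <- ifelse(usex, q2x, q2y)
  lo <- pmax(pmin(pa, pb), pmin(qa, qb))
  hi <- pmin(pmax(pa, pb), pmax(qa, qb))
  edge <- collinear & (hi - lo > eps)
  pt_overlap <- collinear & (hi - lo >= -eps)  # touch at one collinear point

  proper <- !collinear &
    (pmin(d1, d2) <= eps & pmax(d1, d2) >= -eps) &
    (pmin(d3, d4) <= eps & pmax(d3, d4) >= -eps)

  list(edge = any(edge), point = any(edge) || any(pt_overlap) || any(proper))
}
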