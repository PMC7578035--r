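# Half-degree analysis grid with latitude-corrected cell areas.

# Authalic Earth radius (km); gives sub-0.5% error for 0.5-degree cells under
# the flat cos(lat) area approximation.
EARTH_RADIUS_KM <- 6371.0088

#' Area of one equatorial grid cell
#'
#' @param resolution cell edge in degrees.
#' @return area in km2 of a `resolution x resolution` cell at the equator.
#' @export
equatorial_cell_area_km2 <- function(resolution = 0.5) {
  (EARTH_RADIUS_KM * resolution * pi / 180)^2
}

#' Build a regular lon/lat grid over a bounding box
#'
#' Cells tile the box exactly; centers sit on the half-resolution lattice.
#' Cell area uses the spherical approximation `A_eq * cos(lat_center)`.
#'
#' @param bbox numeric length-4, `c(lon_min, lat_min, lon_max, lat_max)`.
#' @param resolution cell edge in degrees; must divide both box extents.
#' @return `data.table` with `cell_id`, `lon`, `lat` (centers), `area_km2`,
#'   and `region_id` (all `NA` until [assign_cells()]).
#' @examples
#' g <- build_grid(c(0, 0, 10, 10), 0.5)   # 400 cells
#' @export
build_grid <- function(bbox, resolution = 0.5) {
  check_bbox(bbox)
  dlon <- bbox[3] - bbox[1]
  dlat <- bbox[4] - bbox[2]
  nx <- dlon / resolution
  ny <- dlat / resolution
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9) {
    stop("resolution ", resolution, " does not divide bbox extents (",
         dlon, " x ", dlat, ")")
  }
  nx <- as.integer(round(nx)); ny <- as.integer(round(ny))
  lon <- bbox[1] + (seq_len(nx) - 0.5) * resolution
  lat <- bbox[2] + (seq_len(ny) - 0.5) * resolution
  g <- data.table::CJ(lat = lat, lon = lon, sorted = FALSE)
  data.table::setcolorder(g, c("lon", "lat"))
  g[, `:=`(
    cell_id  = seq_len(.N),
    area_km2 = equatorial_cell_area_km2(resolution) * cos(lat * pi / 180),
    region_id = NA_character_
  )]
  data.table::setcolorder(g, c("cell_id", "lon", "lat", "area_km2", "region_id"))
  g[]
}

check_bbox <- function(bbox) {
  if (length(bbox) != 4 || !is.numeric(bbox)) {
    stop("bbox must be numeric c(lon_min, lat_min, lon_max, lat_max)")
  }
  if (bbox[3] <= bbox[1] || bbox[4] <= bbox[2]) {
    stop("degenerate bbox: lon_max/lat_max must exceed lon_min/lat_min")
  }
  invisible(bbox)
}

#' Assign grid cells to EEZ regions
#'
#' Default rule assigns each cell to the region containing its center point
#' (cells whose center falls in no region keep `region_id = NA`). The
#' `"majority"` rule samples a `k x k` lattice of points inside each cell and
#' assigns the region holding the most sample points (ties broken by region
#' order), an approximation to majority-area assignment.
#'
#' @param grid a grid from [build_grid()].
#' @param regions an `eez_regions` object (see [read_regions_geojson()]).
#' @param rule `"center"` (default) or `"majority"`.
#' @param k sample lattice size per cell for `rule = "majority"`.
#' @return copy of `grid` with `region_id` filled.
#' @export
assign_cells <- function(grid, regions, rule = c("center", "majority"), k = 4L) {
  rule <- match.arg(rule)
  g <- data.table::copy(grid)
  ids <- regions$features$region_id
  if (rule == "center") {
    hits <- matrix(FALSE, nrow(g), length(ids))
    for (j in seq_along(ids)) {
      hits[, j] <- points_in_geom(g$lon, g$lat, regions$geoms[[ids[j]]])
    }
    multi <- rowSums(hits) > 1L
    if (any(multi)) {
      i <- which(multi)[1L]
      pair <- ids[which(hits[i, ])[1:2]]
      stop("overlapping regions both contain a cell center: ",
           pair[1], " and ", pair[2])
    }
    idx <- apply(hits, 1L, function(r) { w <- which(r); if (length(w)) w else NA_integer_ })
    g[, region_id := ifelse(is.na(idx), NA_character_, ids[idx])]
  } else {
    res_lon <- sort(unique(g$lon)); res <- if (length(res_lon) > 1) min(diff(res_lon)) else 0.5
    off <- (seq_len(k) - 0.5) / k - 0.5
    votes <- matrix(0L, nrow(g), length(ids))
    for (ox in off) for (oy in off) {
      for (j in seq_along(ids)) {
        votes[, j] <- votes[, j] +
          as.integer(points_in_geom(g$lon + ox * res, g$lat + oy * res,
                                    regions$geoms[[ids[j]]]))
      }
    }
    best <- apply(votes, 1L, function(v) if (max(v) == 0L) NA_integer_ else which.max(v))
    g[, region_id := ifelse(is.na(best), NA_character_, ids[best])]
  }
  g[]
}
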