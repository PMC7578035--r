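# Synthetic EEZ mosaic: grid-snapped Voronoi partition of the bounding box.

#' Generate a synthetic EEZ mosaic
#'
#' Draws `n_regions` seed points uniformly in the bbox and assigns every grid
#' cell to its nearest seed (a Voronoi partition snapped to the grid), so the
#' regions exactly tile the bbox and the adjacency structure is known. Region
#' polygons are emitted as lattice-aligned MultiPolygons (one rectangle per
#' row-run of cells), for which the package's containment and adjacency
#' predicates are exact. Seed points are redrawn (deterministically) until
#' every region owns at least one cell.
#'
#' Default metadata makes each region its own continental country with UN
#' sub-regions assigned round-robin from a fixed label set; pass `metadata`
#' to model sub-regions, territories and associated states.
#'
#' @param spec a [world_spec()].
#' @param metadata optional data.frame overriding columns of the default
#'   feature table (matched by `region_id`; e.g. `country_id`,
#'   `territory_class`, `parent_country_for_grouping`, `un_subregion`).
#' @return list with `regions` (an `eez_regions`), `grid` (assigned grid) and
#'   `seeds` (the Voronoi seed points).
#' @export
gen_eez_mosaic <- function(spec, metadata = NULL) {
  stopifnot(inherits(spec, "world_spec"))
  grid <- build_grid(spec$bbox, spec$grid_resolution)
  n <- spec$n_regions
  if (n > nrow(grid)) stop("n_regions exceeds number of grid cells")
  res <- spec$grid_resolution
  ids <- sprintf("R%02d", seq_len(n))

  assign_v <- NULL; seeds <- NULL
  with_seed(spec$seed, {
    for (try in 1:100) {
      seeds <- cbind(stats::runif(n, spec$bbox[1], spec$bbox[3]),
                      stats::runif(n, spec$bbox[2], spec$bbox[4]))
      d2 <- outer(grid$lon, seeds[, 1], "-")^2 + outer(grid$lat, seeds[, 2], "-")^2
      assign_v <- max.col(-d2, ties.method = "first")
      if (length(unique(assign_v)) == n) break
    }
  })
  if (length(unique(assign_v)) != n) {
    stop("could not draw a mosaic with all regions nonempty")
  }
  grid[, region_id := ids[assign_v]]

  geoms <- lapply(ids, function(rid) region_cells_to_multipolygon(
    grid[region_id == rid], res))
  names(geoms) <- ids

  subs <- c("Northern America", "South America", "Northern Europe",
            "Eastern Asia", "Western Africa", "Oceania", "Southern Asia",
            "Eastern Africa")
  feats <- data.table::data.table(
    region_id = ids,
    name = sprintf("Synthetic EEZ %02d", seq_len(n)),
    country_id = sprintf("C%02d", seq_len(n)),
    country_name = sprintf("Country %02d", seq_len(n)),
    un_subregion = subs[(seq_len(n) - 1L) %% length(subs) + 1L],
    territory_class = "continental"
  )
  feats[, parent_country_for_grouping := country_id]
  if (!is.null(metadata)) {
    md <- data.table::as.data.table(metadata)
    if (!"region_id" %in% names(md)) stop("metadata needs region_id")
    idx <- match(feats$region_id, md$region_id)
    for (col in setdiff(names(md), "region_id")) {
      repl <- md[[col]][idx]
      data.table::set(feats, i = which(!is.na(idx)), j = col,
                      value = repl[!is.na(idx)])
    }
    # re-derive grouping default for overridden countries unless given
    if (!"parent_country_for_grouping" %in% names(md)) {
      feats[, parent_country_for_grouping := country_id]
    }
  }
  areas <- grid[, .(area_km2 = sum(area_km2)), by = region_id]
  feats[, area_km2 := areas$area_km2[match(region_id, areas$region_id)]]

  list(regions = eez_regions(feats, geoms), grid = grid[], seeds = seeds)
}

# Convert a set of grid cells (lon/lat centers) into a MultiPolygon of
# row-run rectangles aligned to the lattice.
region_cells_to_multipolygon <- function(cells, res) {
  polys <- list()
  for (la in sort(unique(cells$lat))) {
    lons <- sort(cells[lat == la, lon])
    idx <- round((lons - lons[1]) / res)
    brk <- c(0L, which(diff(idx) != 1L), length(lons))
    for (k in seq_len(length(brk) - 1L)) {
      run <- lons[(brk[k] + 1L):brk[k + 1L]]
      x0 <- min(run) - res / 2; x1 <- max(run) + res / 2
      y0 <- la - res / 2; y1 <- la + res / 2
      ring <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
      polys[[length(polys) + 1L]] <- list(ring)
    }
  }
  polys
}
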