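# EEZ region container and GeoJSON I/O.
#
# An `eez_regions` object bundles:
#   $features : data.table with one row per region —
#       region_id, name, country_id, country_name, un_subregion,
#       territory_class, parent_country_for_grouping, area_km2
#   $geoms    : named list (by region_id) of multipolygon geometries
#       (list of polygons, each a list of closed n x 2 ring matrices)

TERRITORY_CLASSES <- c("continental", "subregion_of_country",
                       "territory_same_nation", "territory_other_nation",
                       "associated_state")

#' Construct an eez_regions object
#'
#' @param features data.frame/data.table of region metadata; requires
#'   `region_id` and `country_id`. Missing optional columns are filled:
#'   `name = region_id`, `country_name = country_id`,
#'   `un_subregion = "Unassigned"`, `territory_class = "continental"`,
#'   `parent_country_for_grouping = country_id`.
#' @param geoms named list of multipolygon geometries keyed by `region_id`.
#' @return an object of class `eez_regions`.
#' @export
eez_regions <- function(features, geoms) {
  f <- data.table::as.data.table(features)
  if (!all(c("region_id", "country_id") %in% names(f))) {
    stop("features must have region_id and country_id")
  }
  if (anyDuplicated(f$region_id)) stop("duplicate region_id in features")
  if (is.null(f$name)) f[, name := region_id]
  if (is.null(f$country_name)) f[, country_name := country_id]
  if (is.null(f$un_subregion)) f[, un_subregion := "Unassigned"]
  if (is.null(f$territory_class)) f[, territory_class := "continental"]
  bad <- setdiff(unique(f$territory_class), TERRITORY_CLASSES)
  if (length(bad)) stop("unknown territory_class: ", paste(bad, collapse = ", "))
  if (is.null(f$parent_country_for_grouping)) {
    f[, parent_country_for_grouping := country_id]
  }
  if (is.null(f$area_km2)) f[, area_km2 := NA_real_]
  missing_geom <- setdiff(f$region_id, names(geoms))
  if (length(missing_geom)) {
    stop("missing geometry for region(s): ", paste(missing_geom, collapse = ", "))
  }
  structure(list(features = f[], geoms = geoms[f$region_id]),
            class = "eez_regions")
}

#' @export
print.eez_regions <- function(x, ...) {
  cat("<eez_regions> ", nrow(x$features), " regions, ",
      length(unique(x$features$parent_country_for_grouping)),
      " grouping countries\n", sep = "")
  print(x$features, nrows = 10)
  invisible(x)
}

#' Effective (grouping) country of each region
#'
#' Associated states inherit their parent country identity before any
#' neighbor-edge evaluation (e.g. a Puerto-Rico-like region groups with its
#' USA-like parent); all other classes group under
#' `parent_country_for_grouping`, which defaults to the region's own country.
#'
#' @param regions an `eez_regions` object.
#' @return named character vector, region_id -> grouping country id.
#' @export
grouping_country <- function(regions) {
  f <- regions$features
  stats::setNames(f$parent_country_for_grouping, f$region_id)
}

#' Write regions to GeoJSON
#'
#' One Feature per region (MultiPolygon, WGS84 lon/lat) with properties
#' region_id, name, country_id, country_name, un_subregion, territory_class,
#' parent_country_for_grouping.
#'
#' @param regions an `eez_regions` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_regions_geojson <- function(regions, path) {
  f <- regions$features
  feats <- lapply(seq_len(nrow(f)), function(i) {
    rid <- f$region_id[i]
    coords <- lapply(regions$geoms[[rid]], function(poly) {
      lapply(poly, function(ring) {
        lapply(seq_len(nrow(ring)), function(r) c(ring[r, 1], ring[r, 2]))
      })
    })
    list(
      type = "Feature",
      properties = list(
        region_id = rid, name = f$name[i],
        country_id = f$country_id[i], country_name = f$country_name[i],
        un_subregion = f$un_subregion[i],
        territory_class = f$territory_class[i],
        parent_country_for_grouping = f$parent_country_for_grouping[i]
      ),
      geometry = list(type = "MultiPolygon", coordinates = coords)
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read regions from GeoJSON
#'
#' Accepts Polygon or MultiPolygon features carrying the property schema
#' written by [write_regions_geojson()]; unknown properties are ignored and
#' missing optional ones default as in [eez_regions()].
#'
#' @param path GeoJSON file path.
#' @return an `eez_regions` object.
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  rows <- list(); geoms <- list()
  for (ft in gj$features) {
    p <- ft$properties
    if (is.null(p$region_id)) stop("feature without region_id property")
    geom <- ft$geometry
    polys <- switch(
      geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type)
    )
    parsed <- lapply(polys, function(poly) {
      lapply(poly, function(ring) {
        m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
        if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
        m
      })
    })
    geoms[[p$region_id]] <- parsed
    rows[[length(rows) + 1L]] <- data.table::data.table(
      region_id = p$region_id,
      name = p$name %||% p$region_id,
      country_id = p$country_id %||% stop("feature ", p$region_id,
                                          " without country_id"),
      country_name = p$country_name %||% p$country_id,
      un_subregion = p$un_subregion %||% "Unassigned",
      territory_class = p$territory_class %||% "continental",
      parent_country_for_grouping = p$parent_country_for_grouping %||% p$country_id
    )
  }
  eez_regions(data.table::rbindlist(rows), geoms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
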