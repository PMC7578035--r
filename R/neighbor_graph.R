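# Neighboring-EEZ graph with country/territory collapsing rules.
#
# Geometric adjacency: two regions are neighbors when their polygons touch.
# Touching along a shared boundary segment always counts; touching at a single
# point (a "corner") is configurable because the source procedure does not
# pin that case down.
#
# Usability of an edge follows the collapsing rules:
#   * associated states inherit their parent country identity first
#     (Puerto-Rico-like regions group with their USA-like parent);
#   * edges between two regions of the same grouping country are unusable —
#     reason "same-nation-territory" when a non-continental territory of that
#     nation is involved, otherwise "same-country-subregion" (e.g. a USA Gulf
#     / USA Atlantic split);
#   * a nation bordering ANOTHER nation's territory stays usable (an
#     Argentina / Falklands-like pair).

#' Build the neighboring-EEZ graph
#'
#' @param regions an `eez_regions` object.
#' @param corner_touch should regions touching at a single point count as
#'   neighbors? Default `TRUE` (any polygon intersection is a neighbor).
#' @return object of class `neighbor_graph`: list with `nodes` (region ids)
#'   and `edges`, a `data.table` of unordered pairs
#'   (`region_a < region_b` lexically) with `touch` (`"edge"`/`"corner"`),
#'   `usable` and `reason` (`NA` for usable edges).
#' @export
build_neighbor_graph <- function(regions, corner_touch = TRUE) {
  f <- regions$features
  need <- c("country_id", "territory_class", "parent_country_for_grouping")
  for (col in need) {
    miss <- f$region_id[is.na(f[[col]])]
    if (length(miss)) stop("missing ", col, " for region(s): ",
                           paste(miss, collapse = ", "))
  }
  ids <- f$region_id
  segs <- lapply(regions$geoms, geom_segments)
  grp <- grouping_country(regions)
  tclass <- stats::setNames(f$territory_class, ids)

  rows <- list()
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq(i + 1L, length(ids))) {
        a <- ids[i]; b <- ids[j]
        tt <- segments_touch(segs[[a]], segs[[b]])
        if (!tt$point) next
        touch <- if (tt$edge) "edge" else "corner"
        if (touch == "corner" && !corner_touch) next
        pa <- sort(c(a, b))
        same_nation <- grp[[a]] == grp[[b]]
        terr <- c("territory_same_nation") %in% c(tclass[[a]], tclass[[b]])
        reason <- if (!same_nation) NA_character_
          else if (terr) "same-nation-territory" else "same-country-subregion"
        rows[[length(rows) + 1L]] <- data.table::data.table(
          region_a = pa[1], region_b = pa[2], touch = touch,
          usable = !same_nation, reason = reason
        )
      }
    }
  }
  edges <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(region_a = character(), region_b = character(),
                           touch = character(), usable = logical(),
                           reason = character())
  structure(list(nodes = ids, edges = edges[]), class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("<neighbor_graph> ", length(x$nodes), " regions, ",
      nrow(x$edges), " edges (", sum(x$edges$usable), " usable)\n", sep = "")
  print(x$edges, nrows = 10)
  invisible(x)
}

#' Usable edges of a neighbor graph
#'
#' @param graph a `neighbor_graph`.
#' @return `data.table` of usable unordered pairs (`region_a`, `region_b`).
#' @export
usable_edges <- function(graph) {
  graph$edges[usable == TRUE, .(region_a, region_b)]
}

#' Write the edge list as CSV
#'
#' @param graph a `neighbor_graph`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_edges_csv <- function(graph, path) {
  data.table::fwrite(graph$edges, path)
  invisible(path)
}
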