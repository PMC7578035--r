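# Four-source presence consensus with the catch-positivity filter.
#
# A cell belongs to a species' consensus range only when the occurrence
# layer, both distribution-model layers AND the spatialized catch data agree:
# unanimous presence plus strictly positive catch in at least one year of the
# reference window. Unanimity is deliberate — the estimate is conservative.

#' Consensus range of one species
#'
#' @param species_id species identifier.
#' @param layers named list of cell-id vectors for sources `occurrence`,
#'   `enm`, `sdm`, and optionally `catch`. When no `catch` layer is given it
#'   is derived from `catch_by_cell` as the cells with strictly positive
#'   catch in at least one window year. All four sources must be resolvable;
#'   a species lacking any source is an error (only commercially fished
#'   species with data from all four sources are analyzable).
#' @param catch_by_cell `data.table` (species_id, cell_id, year, tonnes) of
#'   spatialized catch; required when `layers$catch` is absent.
#' @param window reference years for catch positivity, default `c(2005, 2014)`.
#' @return list of class `consensus_range`: `species_id`, `cells` (sorted
#'   cell ids), `support` (`data.table` cell_id / n_supporting_sources over
#'   the union of all layers). Empty consensus returns zero cells with a
#'   warning — such species drop out downstream.
#' @export
consensus <- function(species_id, layers, catch_by_cell = NULL,
                      window = c(2005, 2014)) {
  need <- c("occurrence", "enm", "sdm")
  miss <- setdiff(need, names(layers))
  if (length(miss)) {
    stop("species ", species_id, " missing source layer(s): ",
         paste(miss, collapse = ", "))
  }
  if (is.null(layers$catch)) {
    if (is.null(catch_by_cell)) {
      stop("species ", species_id,
           " has no catch layer and no catch_by_cell table")
    }
    cbc <- data.table::as.data.table(catch_by_cell)
    sp <- species_id
    layers$catch <- sort(unique(
      cbc[species_id == sp & year >= window[1] & year <= window[2] &
            tonnes > 0, cell_id]))
  }
  four <- layers[PRESENCE_SOURCES]
  cells <- sort(Reduce(intersect, four))
  all_cells <- sort(unique(unlist(four)))
  support <- data.table::data.table(cell_id = all_cells)
  support[, n_supporting_sources := rowSums(
    vapply(four, function(l) all_cells %in% l, logical(length(all_cells))))]
  if (!length(cells)) {
    warning("species ", species_id, ": empty consensus range; ",
            "excluded downstream")
  }
  structure(list(species_id = species_id, cells = cells, support = support[]),
            class = "consensus_range")
}

#' Consensus ranges for every species in a presence table
#'
#' @param presence long `data.table` (species_id, source, cell_id) with the
#'   four sources per species.
#' @param catch_by_cell spatialized catch table (see [consensus()]); optional
#'   when a `catch` source is present for every species.
#' @param window reference years for catch positivity.
#' @return named list of `consensus_range` objects (species with empty
#'   consensus are kept, cells length 0).
#' @export
consensus_all <- function(presence, catch_by_cell = NULL,
                          window = c(2005, 2014)) {
  p <- data.table::as.data.table(presence)
  out <- list()
  for (sp in sort(unique(p$species_id))) {
    sub <- p[species_id == sp]
    layers <- split(sub$cell_id, sub$source)
    out[[sp]] <- consensus(sp, layers, catch_by_cell = catch_by_cell,
                           window = window)
  }
  out
}

#' Write consensus ranges as CSV
#'
#' One row per consensus cell: species_id, cell_id, n_supporting_sources
#' (always 4 for consensus cells by construction).
#'
#' @param ranges list of `consensus_range` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_consensus_csv <- function(ranges, path) {
  rows <- lapply(ranges, function(r) {
    if (!length(r$cells)) return(NULL)
    data.table::data.table(species_id = r$species_id, cell_id = r$cells,
                           n_supporting_sources = 4L)
  })
  data.table::fwrite(data.table::rbindlist(rows), path)
  invisible(path)
}
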