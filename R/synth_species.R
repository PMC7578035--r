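# Synthetic species ranges and four-source presence layers.

PRESENCE_SOURCES <- c("occurrence", "enm", "sdm", "catch")

#' Generate a species range with target per-region shares
#'
#' Samples grid cells so the realized per-region cell-count proportions match
#' `target_shares` to within one cell (largest-remainder apportionment of
#' `n_cells`). Realized shares — by count and by km2 — are returned for
#' ground-truth bookkeeping.
#'
#' @param assignment grid `data.table` with `region_id` filled
#'   (see [assign_cells()] or [gen_eez_mosaic()]).
#' @param target_shares named numeric vector (region_id -> proportion),
#'   summing to 1.
#' @param n_cells total number of range cells to draw.
#' @return list with `cells` (cell_id vector), `target_shares`,
#'   `realized_count_shares`, `realized_area_shares`.
#' @export
gen_species_range <- function(assignment, target_shares, n_cells = 60L) {
  if (abs(sum(target_shares) - 1) > 1e-9) stop("target_shares must sum to 1")
  if (is.null(names(target_shares))) stop("target_shares must be named by region_id")
  want <- apportion(n_cells, target_shares)
  names(want) <- names(target_shares)
  cells <- integer(0)
  for (rid in names(target_shares)) {
    avail <- assignment[region_id == rid, cell_id]
    if (want[[rid]] > length(avail)) {
      stop("region ", rid, " too small: needs ", want[[rid]],
           " cells, has ", length(avail))
    }
    if (want[[rid]] > 0L) {
      cells <- c(cells, avail[sample.int(length(avail), want[[rid]])])
    }
  }
  sub <- assignment[cell_id %in% cells]
  cnt <- sub[, .N, by = region_id]
  ar <- sub[, .(a = sum(area_km2)), by = region_id]
  list(
    cells = sort(cells),
    target_shares = target_shares,
    realized_count_shares = stats::setNames(cnt$N / sum(cnt$N), cnt$region_id),
    realized_area_shares = stats::setNames(ar$a / sum(ar$a), ar$region_id)
  )
}

#' Generate the four presence-source layers for a species
#'
#' The three model/observation layers (occurrence, niche model, trait-based
#' distribution model) each reproduce a range cell with probability
#' `agreement_rate` and add each out-of-range cell with probability
#' `1 - agreement_rate` (independent Bernoulli noise). The catch layer is the
#' range itself — the generator spatializes positive catch onto exactly the
#' range cells, so with `agreement_rate = 1` all four layers coincide.
#'
#' @param range_cells cell ids of the true range.
#' @param agreement_rate probability in `[0, 1]`.
#' @param all_cells all grid cell ids (universe for added noise cells).
#' @return list of four cell-id vectors named `occurrence`, `enm`, `sdm`,
#'   `catch`, plus `consensus` — the intersection of the four layers.
#' @export
gen_presence_sources <- function(range_cells, agreement_rate, all_cells) {
  if (agreement_rate < 0 || agreement_rate > 1) {
    stop("agreement_rate must be in [0, 1]")
  }
  outside <- setdiff(all_cells, range_cells)
  noisy <- function() {
    keep <- range_cells[stats::runif(length(range_cells)) <= agreement_rate]
    add <- outside[stats::runif(length(outside)) <= (1 - agreement_rate)]
    sort(c(keep, add))
  }
  layers <- list(occurrence = noisy(), enm = noisy(), sdm = noisy(),
                 catch = sort(range_cells))
  layers$consensus <- sort(Reduce(intersect, layers[PRESENCE_SOURCES]))
  layers
}
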