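# Transboundary classification: pairwise Area Index over the usable neighbor
# graph, stock labels per species x EEZ and a species-level label.
#
# The Area Index of a neighboring pair (a, b) is the proportion of the
# species' joint shared distribution (its consensus cells inside a union b)
# that each side encloses; a pair passes when BOTH sides enclose strictly
# more than the threshold (default 25%). A species is transboundary when at
# least one usable pair passes anywhere; its stocks in regions touched by no
# passing pair are "excluded" stocks (the Ecuador-anchoveta situation).

#' Pairwise Area Index for one species and one usable neighbor edge
#'
#' @param range a `consensus_range` (or any list with `cells`).
#' @param pair character length-2, the two region ids; must be a usable edge
#'   of `graph`.
#' @param assignment grid `data.table` with cell areas and `region_id`.
#' @param graph a `neighbor_graph`; supplying a non-usable or non-existent
#'   edge is an error.
#' @param threshold pass threshold on the smaller share (strict `>`).
#' @param weighting `"km2"` (latitude-corrected areas, default) or `"count"`
#'   (raw cell counts).
#' @return one-row `data.table`: region_a, region_b, area_a_km2, area_b_km2,
#'   ai_a, ai_b, passes. Zero joint area yields `NA` indices and
#'   `passes = FALSE`.
#' @export
area_index <- function(range, pair, assignment, graph, threshold = 0.25,
                       weighting = c("km2", "count")) {
  weighting <- match.arg(weighting)
  pr <- sort(pair)
  ue <- usable_edges(graph)
  if (!nrow(ue[region_a == pr[1] & region_b == pr[2]])) {
    stop("pair ", pr[1], "/", pr[2], " is not a usable neighbor edge")
  }
  sub <- assignment[cell_id %in% range$cells & region_id %in% pair]
  w <- if (weighting == "km2") sub$area_km2 else rep(1, nrow(sub))
  a_a <- sum(w[sub$region_id == pair[1]])
  a_b <- sum(w[sub$region_id == pair[2]])
  joint <- a_a + a_b
  if (joint <= 0) {
    ai_a <- NA_real_; ai_b <- NA_real_; passes <- FALSE
  } else {
    ai_a <- a_a / joint; ai_b <- a_b / joint
    passes <- min(ai_a, ai_b) > threshold
  }
  data.table::data.table(region_a = pair[1], region_b = pair[2],
                         area_a_km2 = a_a, area_b_km2 = a_b,
                         ai_a = ai_a, ai_b = ai_b, passes = passes)
}

#' Classify one species' stocks as transboundary / excluded / discrete
#'
#' Evaluates the Area Index on every usable neighbor edge with positive joint
#' area, then labels each region holding consensus cells: `transboundary` if
#' any incident pair passes; `excluded_stock` if the species passes elsewhere
#' but no incident pair does; `discrete_stock` when the species passes
#' nowhere. The species label is `transboundary` iff any pair passes.
#'
#' @param species_id species identifier.
#' @param range a `consensus_range`; an empty range is an error (the species
#'   is absent from all regions).
#' @param graph a `neighbor_graph`.
#' @param assignment assigned grid `data.table`.
#' @param threshold Area Index threshold in (0, 0.5]; strict `>` to pass.
#' @param weighting area weighting, `"km2"` or `"count"`.
#' @return list of class `stock_classification`: `species_id`,
#'   `species_label`, `ai` (per-pair table), `stocks` (per-region table with
#'   stock_label, species_label, best_pair, best_min_ai).
#' @export
classify_species <- function(species_id, range, graph, assignment,
                             threshold = 0.25, weighting = c("km2", "count")) {
  weighting <- match.arg(weighting)
  if (threshold <= 0 || threshold > 0.5) stop("threshold must be in (0, 0.5]")
  sub <- assignment[cell_id %in% range$cells & !is.na(region_id)]
  if (!nrow(sub)) stop("species ", species_id, " absent from all regions")
  present <- sort(unique(sub$region_id))
  ue <- usable_edges(graph)

  ai_rows <- list()
  if (nrow(ue)) {
    for (e in seq_len(nrow(ue))) {
      pair <- c(ue$region_a[e], ue$region_b[e])
      if (!any(pair %in% present)) next
      ai_rows[[length(ai_rows) + 1L]] <- area_index(
        range, pair, assignment, graph, threshold, weighting)
    }
  }
  ai <- if (length(ai_rows)) data.table::rbindlist(ai_rows) else
    data.table::data.table(region_a = character(), region_b = character(),
                           area_a_km2 = numeric(), area_b_km2 = numeric(),
                           ai_a = numeric(), ai_b = numeric(),
                           passes = logical())
  sp_id <- species_id
  ai[, species_id := sp_id]
  data.table::setcolorder(ai, "species_id")

  passing <- ai[passes == TRUE]
  passing_regions <- unique(c(passing$region_a, passing$region_b))
  sp_label <- if (length(passing_regions)) "transboundary" else "discrete"

  stocks <- data.table::data.table(species_id = species_id,
                                   region_id = present)
  stocks[, stock_label := ifelse(
    region_id %in% passing_regions, "transboundary",
    ifelse(sp_label == "transboundary", "excluded_stock", "discrete_stock"))]
  stocks[, species_label := sp_label]

  # best incident pair per region (largest min-share among positive-joint pairs)
  stocks[, `:=`(best_pair = NA_character_, best_min_ai = NA_real_)]
  pos <- ai[!is.na(ai_a)]
  if (nrow(pos)) {
    for (i in seq_len(nrow(stocks))) {
      rid <- stocks$region_id[i]
      inc <- pos[region_a == rid | region_b == rid]
      if (nrow(inc)) {
        m <- pmin(inc$ai_a, inc$ai_b)
        b <- which.max(m)
        data.table::set(stocks, i, "best_pair",
                        paste(inc$region_a[b], inc$region_b[b], sep = "|"))
        data.table::set(stocks, i, "best_min_ai", m[b])
      }
    }
  }
  structure(list(species_id = species_id, species_label = sp_label,
                 ai = ai[], stocks = stocks[]),
            class = "stock_classification")
}

#' Classify every species in a set of consensus ranges
#'
#' Species with empty consensus ranges are skipped (they were excluded by the
#' data-agreement criterion).
#'
#' @param ranges named list of `consensus_range` objects.
#' @inheritParams classify_species
#' @return list with `ai` (all pairwise indices), `stocks` (per species x
#'   region classification) and `species` (species_id, species_label).
#' @export
classify_all <- function(ranges, graph, assignment, threshold = 0.25,
                         weighting = c("km2", "count")) {
  weighting <- match.arg(weighting)
  ai <- list(); stocks <- list()
  for (r in ranges) {
    if (!length(r$cells)) next
    cl <- classify_species(r$species_id, r, graph, assignment,
                           threshold, weighting)
    ai[[length(ai) + 1L]] <- cl$ai
    stocks[[length(stocks) + 1L]] <- cl$stocks
  }
  stocks <- data.table::rbindlist(stocks)
  list(
    ai = data.table::rbindlist(ai),
    stocks = stocks,
    species = stocks[, .(species_label = species_label[1]), by = species_id]
  )
}

#' Count transboundary species across a set of thresholds
#'
#' The count is non-increasing in the threshold, and is forced to zero at
#' 0.5: the two shares of a pair sum to 1, so both cannot strictly exceed
#' one half.
#'
#' @param ranges named list of `consensus_range` objects.
#' @param graph,assignment as in [classify_species()].
#' @param thresholds ascending thresholds in (0, 0.5].
#' @param weighting area weighting.
#' @return `data.table` with `threshold` and `n_transboundary`.
#' @export
threshold_sweep <- function(ranges, graph, assignment,
                            thresholds = seq(0.05, 0.5, by = 0.05),
                            weighting = c("km2", "count")) {
  weighting <- match.arg(weighting)
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  if (any(thresholds <= 0 | thresholds > 0.5)) {
    stop("thresholds must lie in (0, 0.5]")
  }
  # one pass: per species, the best (largest) min-share over usable pairs
  best <- vapply(ranges, function(r) {
    if (!length(r$cells)) return(NA_real_)
    cl <- classify_species(r$species_id, r, graph, assignment,
                           threshold = 0.5, weighting = weighting)
    pos <- cl$ai[!is.na(ai_a)]
    if (!nrow(pos)) return(NA_real_)
    max(pmin(pos$ai_a, pos$ai_b))
  }, numeric(1))
  data.table::data.table(
    threshold = thresholds,
    n_transboundary = vapply(thresholds,
                             function(t) sum(best > t, na.rm = TRUE),
                             numeric(1))
  )
}
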