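# End-to-end pipeline: synth/load -> spatial -> consensus -> classify ->
# trends -> accounting, with a manifest for reproducibility.

#' Pipeline run configuration
#'
#' Either `world` (a [world_spec()]; inputs are generated) or `input_dir` (a
#' directory written by [write_world()] or following the same layout) must be
#' supplied. Defaults mirror the reference procedure: 25% Area Index
#' threshold, 0.5 degree grid, 2005-2014 window, 2019 target USD.
#'
#' @param out_dir output directory.
#' @param world optional `world_spec` for synthetic input generation.
#' @param input_dir optional directory of pre-made inputs.
#' @param threshold Area Index threshold (default 0.25).
#' @param window reference window, default `c(2005, 2014)`.
#' @param area_weighting `"km2"` or `"count"`.
#' @param usd_target_year target real-USD year (default 2019).
#' @param price_base_year base year of price table (default 2010).
#' @param corner_touch do corner-touching regions count as neighbors?
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, world = NULL, input_dir = NULL,
                       threshold = 0.25, window = c(2005, 2014),
                       area_weighting = c("km2", "count"),
                       usd_target_year = 2019, price_base_year = 2010,
                       corner_touch = TRUE) {
  if (is.null(world) && is.null(input_dir)) {
    stop("run_config needs either a world spec or an input_dir")
  }
  if (threshold <= 0 || threshold > 0.5) stop("threshold must be in (0, 0.5]")
  if (length(window) != 2 || window[2] < window[1]) stop("bad window")
  structure(list(out_dir = out_dir, world = world, input_dir = input_dir,
                 threshold = threshold, window = window,
                 area_weighting = match.arg(area_weighting),
                 usd_target_year = usd_target_year,
                 price_base_year = price_base_year,
                 corner_touch = corner_touch),
            class = "run_config")
}

#' Read pipeline inputs from a directory
#'
#' Expects the [write_world()] layout: `regions.geojson`, `grid.csv`,
#' `presence.csv`, `catch.csv`, `catch_by_cell.csv`, `prices.csv`, `cpi.csv`.
#'
#' @param dir input directory.
#' @return list of parsed inputs.
#' @export
read_world_inputs <- function(dir) {
  fr <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing input file: ", p)
    data.table::fread(p)
  }
  gj <- file.path(dir, "regions.geojson")
  if (!file.exists(gj)) stop("missing input file: ", gj)
  list(regions = read_regions_geojson(gj),
       grid = fr("grid.csv"), presence = fr("presence.csv"),
       catch = fr("catch.csv"), catch_by_cell = fr("catch_by_cell.csv"),
       prices = fr("prices.csv"), cpi = fr("cpi.csv"))
}

#' Run the full pipeline
#'
#' Stages: input generation/loading, neighbor graph, presence consensus,
#' transboundary classification, threshold sweep, catch-trend assessment,
#' revenue and stock-class accounting, regional rollup. All stage outputs are
#' written under `config$out_dir` together with `manifest.json` (config, md5
#' checksums, row counts) and a plain-text summary. Reruns with the same
#' config and inputs are bitwise identical.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with all in-memory stage artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$world)) {
    world <- gen_world(config$world, threshold = config$threshold)
    input_dir <- file.path(out, "inputs")
    write_world(world, input_dir)
    regions <- world$regions; assignment <- world$grid
    presence <- world$presence; catch <- world$catch
    catch_by_cell <- world$catch_by_cell
    prices <- world$prices; cpi <- world$cpi
  } else {
    input_dir <- config$input_dir
    inp <- read_world_inputs(input_dir)
    regions <- inp$regions
    assignment <- inp$grid
    if (!"region_id" %in% names(assignment) ||
        all(is.na(assignment$region_id))) {
      assignment <- assign_cells(assignment, regions)
    }
    presence <- inp$presence; catch <- inp$catch
    catch_by_cell <- inp$catch_by_cell; prices <- inp$prices; cpi <- inp$cpi
    world <- NULL
  }

  graph <- build_neighbor_graph(regions, corner_touch = config$corner_touch)
  ranges <- suppressWarnings(
    consensus_all(presence, catch_by_cell, window = config$window))
  cls <- classify_all(ranges, graph, assignment,
                      threshold = config$threshold,
                      weighting = config$area_weighting)
  sweep <- threshold_sweep(ranges, graph, assignment,
                           weighting = config$area_weighting)
  trends <- assess_trends(catch, window = config$window)
  rev <- revenue(catch, prices, cpi, grouping_country(regions),
                 window = config$window,
                 price_base_year = config$price_base_year,
                 usd_target_year = config$usd_target_year)

  # stocks present in catch but absent from the classification (e.g. dropped
  # by the consensus under noisy sources) cannot be partitioned
  wm <- rev$window_mean[cls$stocks[, .(species_id, region_id)],
                        on = c("species_id", "region_id"), nomatch = NULL]
  n_unclassified <- nrow(rev$window_mean) - nrow(wm)
  part <- partition_by_stock_class(cls$stocks, wm)
  rollup <- regional_rollup(wm, cls$stocks, regions$features)

  # ---- write artifacts ----
  fw <- function(x, f) { data.table::fwrite(x, file.path(out, f)); f }
  files <- c(
    fw(graph$edges, "edges.csv"),
    fw(assignment, "cell_assignment.csv"),
    local({ write_consensus_csv(ranges, file.path(out, "consensus.csv"))
            "consensus.csv" }),
    fw(cls$ai, "area_index.csv"),
    fw(cls$stocks, "stock_classification.csv"),
    fw(cls$species, "species_labels.csv"),
    fw(sweep, "threshold_sweep.csv"),
    fw(trends, "trend_assessment.csv"),
    fw(rev$window_mean, "revenue_window_mean.csv"),
    fw(part, "stock_class_accounts.csv"),
    fw(rollup$country, "account_country.csv"),
    fw(rollup$subregion, "account_subregion.csv")
  )

  summary_lines <- c(
    sprintf("species analyzed: %d", nrow(cls$species)),
    sprintf("transboundary species: %d",
            sum(cls$species$species_label == "transboundary")),
    sprintf("discrete species: %d",
            sum(cls$species$species_label == "discrete")),
    sprintf("threshold: %.2f  window: %d-%d", config$threshold,
            config$window[1], config$window[2]),
    sprintf("stock-class mean annual catch (t): %s",
            paste(sprintf("%s=%.1f", part$stock_class,
                          part$mean_annual_catch), collapse = "  ")),
    sprintf("stock-class mean annual revenue (%d USD): %s",
            config$usd_target_year,
            paste(sprintf("%s=%.0f", part$stock_class,
                          part$mean_annual_revenue), collapse = "  ")),
    sprintf("top-5 countries by transboundary revenue: %s",
            paste(utils::head(
              rollup$country[order(-revenue), country_id], 5), collapse = ", ")),
    sprintf("unclassified catch stocks dropped: %d", n_unclassified)
  )
  writeLines(summary_lines, file.path(out, "summary.txt"))
  files <- c(files, "summary.txt")

  input_files <- list.files(input_dir, full.names = TRUE)
  manifest <- list(
    config = config_to_list(config),
    inputs = as.list(stats::setNames(tools::md5sum(input_files),
                                     basename(input_files))),
    outputs = as.list(stats::setNames(
      tools::md5sum(file.path(out, files)), files)),
    row_counts = list(
      edges = nrow(graph$edges), species = nrow(cls$species),
      stocks = nrow(cls$stocks), area_index = nrow(cls$ai),
      trends = nrow(trends), window_mean = nrow(rev$window_mean),
      unclassified_dropped = n_unclassified)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(config = config, world = world, regions = regions,
                 assignment = assignment, graph = graph, ranges = ranges,
                 classification = cls, sweep = sweep, trends = trends,
                 revenue = rev, partition = part, rollup = rollup,
                 manifest = manifest))
}

config_to_list <- function(config) {
  lst <- unclass(config)
  if (!is.null(lst$world)) lst$world <- unclass(lst$world)
  lst
}
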