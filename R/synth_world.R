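# Full synthetic world: mosaic + species + presence sources + catch + prices,
# with recorded ground truth for every downstream stage.

#' Generate a complete synthetic world
#'
#' Builds the EEZ mosaic and its neighbor graph, then for each species draws a
#' target share vector over regions (favoring usable neighbor pairs so
#' transboundary configurations actually occur), realizes a range, emits the
#' four presence-source layers at the spec's agreement rate, constructs a
#' catch series per species x region realizing a drawn (or supplied) trend
#' category, spatializes window catch onto the range cells, and generates
#' prices and a CPI table. Ground truth (pairwise Area Indices from realized
#' shares, stock/species labels at `threshold`, intended trend categories) is
#' recorded for recovery testing.
#'
#' @param spec a [world_spec()].
#' @param metadata optional mosaic metadata override (see [gen_eez_mosaic()]).
#' @param trend_categories optional `data.table` (species_id, region_id,
#'   category) fixing intended trend categories; missing combinations are
#'   drawn at random.
#' @param threshold Area Index threshold used for ground-truth labels
#'   (default 0.25).
#' @param n_cells range size per species (default 60 cells).
#' @return object of class `synthetic_world`.
#' @export
gen_world <- function(spec, metadata = NULL, trend_categories = NULL,
                      threshold = 0.25, n_cells = 60L) {
  stopifnot(inherits(spec, "world_spec"))
  mosaic <- gen_eez_mosaic(spec, metadata = metadata)
  regions <- mosaic$regions
  assignment <- mosaic$grid
  graph <- build_neighbor_graph(regions)
  uedges <- usable_edges(graph)
  rids <- regions$features$region_id
  sp_ids <- sprintf("S%03d", seq_len(spec$n_species))
  grp <- grouping_country(regions)
  years <- 1951:2014
  window <- c(2005, 2014)

  world <- with_seed(spec$seed + 1L, {
    species <- list()
    presence <- list(); catch_rows <- list(); cbc_rows <- list()
    gt_pairs <- list(); gt_stocks <- list(); gt_trends <- list()

    region_sizes <- assignment[, .N, by = region_id]
    sizes <- stats::setNames(region_sizes$N, region_sizes$region_id)

    for (si in seq_along(sp_ids)) {
      sp <- sp_ids[si]
      shares <- if (!is.null(spec$share_fractions)) {
        spec$share_fractions[[si]]
      } else {
        draw_target_shares(rids, uedges, sizes, n_cells)
      }
      rng <- gen_species_range(assignment, shares, n_cells = n_cells)
      layers <- gen_presence_sources(rng$cells, spec$source_agreement_rate,
                                     assignment$cell_id)
      species[[sp]] <- c(rng, list(layers = layers))
      for (src in PRESENCE_SOURCES) {
        if (length(layers[[src]])) {
          presence[[length(presence) + 1L]] <- data.table::data.table(
            species_id = sp, source = src, cell_id = layers[[src]])
        }
      }

      present_regions <- sort(unique(
        assignment[cell_id %in% rng$cells, region_id]))

      # trend categories per species x region
      for (rid in present_regions) {
        cat_i <- NULL
        if (!is.null(trend_categories)) {
          tc <- data.table::as.data.table(trend_categories)
          hit <- tc[species_id == sp & region_id == rid]
          if (nrow(hit)) cat_i <- hit$category[1]
        }
        if (is.null(cat_i)) {
          cat_i <- sample(TREND_CATEGORIES, 1, prob = c(0.25, 0.35, 0.3, 0.1))
        }
        ser <- gen_catch_series(cat_i, years = years, window = window)
        catch_rows[[length(catch_rows) + 1L]] <- data.table::data.table(
          species_id = sp, region_id = rid, year = ser$year, tonnes = ser$catch)
        gt_trends[[length(gt_trends) + 1L]] <- data.table::data.table(
          species_id = sp, region_id = rid, category = cat_i)

        # spatialize positive window catch equally over the region's range cells
        rc <- assignment[cell_id %in% rng$cells & region_id == rid, cell_id]
        wy <- ser[year >= window[1] & year <= window[2] & catch > 0]
        if (nrow(wy) && length(rc)) {
          cbc_rows[[length(cbc_rows) + 1L]] <- data.table::CJ(
            species_id = sp, cell_id = rc, year = wy$year
          )[, tonnes := wy$catch[match(year, wy$year)] / length(rc)]
        }
      }

      # ground-truth Area Indices and labels from realized km2 shares
      areas <- assignment[cell_id %in% rng$cells,
                          .(a = sum(area_km2)), by = region_id]
      av <- stats::setNames(areas$a, areas$region_id)
      passing_regions <- character(0)
      if (nrow(uedges)) {
        for (e in seq_len(nrow(uedges))) {
          ra <- uedges$region_a[e]; rb <- uedges$region_b[e]
          aa <- av[ra]; ab <- av[rb]
          aa <- if (is.na(aa)) 0 else aa; ab <- if (is.na(ab)) 0 else ab
          if (aa + ab <= 0) next
          ai_a <- aa / (aa + ab)
          pass <- min(ai_a, 1 - ai_a) > threshold
          gt_pairs[[length(gt_pairs) + 1L]] <- data.table::data.table(
            species_id = sp, region_a = ra, region_b = rb,
            ai_a = ai_a, ai_b = 1 - ai_a, passes = pass)
          if (pass) passing_regions <- union(passing_regions, c(ra, rb))
        }
      }
      sp_label <- if (length(passing_regions)) "transboundary" else "discrete"
      gt_stocks[[length(gt_stocks) + 1L]] <- data.table::data.table(
        species_id = sp, region_id = present_regions,
        stock_label = ifelse(present_regions %in% passing_regions,
                             "transboundary",
                             ifelse(sp_label == "transboundary",
                                    "excluded_stock", "discrete_stock")),
        species_label = sp_label)
    }

    countries <- sort(unique(grp))
    price_tabs <- gen_prices(sp_ids, countries, years)

    list(
      species = species,
      presence = data.table::rbindlist(presence),
      catch = data.table::rbindlist(catch_rows),
      catch_by_cell = data.table::rbindlist(cbc_rows),
      prices = price_tabs$prices, cpi = price_tabs$cpi,
      ground_truth = list(
        pairs = data.table::rbindlist(gt_pairs),
        stocks = data.table::rbindlist(gt_stocks),
        species = data.table::rbindlist(gt_stocks)[
          , .(species_label = species_label[1]), by = species_id],
        trends = data.table::rbindlist(gt_trends)
      )
    )
  })

  structure(c(list(spec = spec, regions = regions, grid = assignment,
                   graph = graph, threshold = threshold, window = window),
              world),
            class = "synthetic_world")
}

# Draw a target share vector: mostly 2-region splits along a usable edge (the
# transboundary-capable configuration), some single-region endemics, some
# 3-region chains. Shares are drawn so both failing (<= threshold) and
# passing pairs occur.
draw_target_shares <- function(rids, uedges, sizes, n_cells) {
  k <- sample(1:3, 1, prob = c(0.3, 0.5, 0.2))
  feasible <- function(sh) {
    want <- apportion(n_cells, sh)
    all(want <= sizes[names(sh)])
  }
  for (attempt in 1:50) {
    if (k == 1L || nrow(uedges) == 0L) {
      rid <- rids[sample.int(length(rids), 1)]
      sh <- stats::setNames(1, rid)
    } else {
      e <- sample.int(nrow(uedges), 1)
      pair <- c(uedges$region_a[e], uedges$region_b[e])
      u <- stats::runif(1, 0.05, 0.5)
      if (k == 2L || length(setdiff(rids, pair)) == 0L) {
        sh <- stats::setNames(c(1 - u, u), pair)
      } else {
        third <- setdiff(rids, pair)
        rid3 <- third[sample.int(length(third), 1)]
        w <- stats::runif(1, 0.05, 0.3)
        sh <- stats::setNames(c((1 - u) * (1 - w), u * (1 - w), w),
                              c(pair, rid3))
      }
    }
    if (feasible(sh)) return(sh)
  }
  # fallback: proportional-to-size shares over all regions
  sh <- sizes[rids] / sum(sizes[rids])
  stats::setNames(as.numeric(sh), rids)
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> seed=", x$spec$seed, " regions=",
      nrow(x$regions$features), " species=", length(x$species),
      " agreement=", x$spec$source_agreement_rate, "\n", sep = "")
  gt <- x$ground_truth$species
  cat("  ground truth: ", sum(gt$species_label == "transboundary"),
      " transboundary / ", sum(gt$species_label == "discrete"),
      " discrete species\n", sep = "")
  invisible(x)
}

#' Write a synthetic world to a directory
#'
#' Regions as GeoJSON; grid, presence layers, catch (per region and per
#' cell), prices, CPI, UN sub-region lookup and ground truth as CSV.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fw <- function(x, f) data.table::fwrite(x, file.path(dir, f))
  write_regions_geojson(world$regions, file.path(dir, "regions.geojson"))
  fw(world$grid, "grid.csv")
  fw(world$presence, "presence.csv")
  fw(world$catch, "catch.csv")
  fw(world$catch_by_cell, "catch_by_cell.csv")
  fw(world$prices, "prices.csv")
  fw(world$cpi, "cpi.csv")
  fw(unique(world$regions$features[
    , .(country_id = parent_country_for_grouping, un_subregion)]),
    "un_subregions.csv")
  fw(world$ground_truth$pairs, "ground_truth_pairs.csv")
  fw(world$ground_truth$stocks, "ground_truth_stocks.csv")
  fw(world$ground_truth$trends, "ground_truth_trends.csv")
  invisible(dir)
}
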