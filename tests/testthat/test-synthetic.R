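# Synthetic world generator: mosaic, ranges, presence sources, catch, prices.

test_that("world_spec validates its fields", {
  expect_error(world_spec(1, n_regions = 1), "n_regions")
  expect_error(world_spec(1, 4, bbox = c(10, 0, 0, 10)), "degenerate")
  expect_error(world_spec(1, 4, grid_resolution = 0.3), "divide")
  expect_error(world_spec(1, 4, source_agreement_rate = 1.2), "agreement")
  expect_error(world_spec(1, 4, n_species = 2,
                          share_fractions = list(c(A = 0.5))), "per species")
  expect_error(world_spec(1, 4, n_species = 1,
                          share_fractions = list(c(A = 0.6, B = 0.6))),
               "sum to 1")
})

test_that("mosaic is deterministic, partitions the bbox, and is connected", {
  spec <- world_spec(seed = 99, n_regions = 5, n_species = 1)
  m1 <- gen_eez_mosaic(spec)
  m2 <- gen_eez_mosaic(spec)
  expect_identical(m1$geoms, m2$geoms)
  expect_identical(m1$grid, m2$grid)
  expect_identical(m1$regions$features, m2$regions$features)

  # partition: polygon areas (shoelace, deg^2) sum to the bbox area
  areas <- vapply(m1$regions$geoms, transbound:::geom_area_deg2, numeric(1))
  bbox_area <- (spec$bbox[3] - spec$bbox[1]) * (spec$bbox[4] - spec$bbox[2])
  expect_equal(sum(areas), bbox_area, tolerance = 1e-6)

  # every cell assigned, every region nonempty
  expect_false(anyNA(m1$grid$region_id))
  expect_equal(length(unique(m1$grid$region_id)), 5L)

  # at least one pair of regions shares a boundary segment
  gr <- build_neighbor_graph(m1$regions)
  expect_gte(nrow(gr$edges[touch == "edge"]), 1L)
})

test_that("a two-region mosaic yields exactly one country pair edge; same-country sub-regions yield none usable", {
  spec <- world_spec(seed = 3, n_regions = 2, n_species = 1)
  m <- gen_eez_mosaic(spec)
  gr <- build_neighbor_graph(m$regions)
  expect_equal(nrow(usable_edges(gr)), 1L)

  md <- data.frame(region_id = c("R01", "R02"),
                   country_id = "C01",
                   territory_class = "subregion_of_country",
                   parent_country_for_grouping = "C01")
  m2 <- gen_eez_mosaic(spec, metadata = md)
  gr2 <- build_neighbor_graph(m2$regions)
  expect_equal(nrow(usable_edges(gr2)), 0L)
  expect_gte(nrow(gr2$edges), 1L)  # geometric edge still present, unusable
})

test_that("species ranges realize target shares within one cell", {
  w <- make_strip_world(widths = c(8, 8, 8))  # 32 cells per region
  set.seed(1)
  r <- gen_species_range(w$assignment, c(E = 0.6, P = 0.4), n_cells = 10L)
  expect_equal(unname(r$realized_count_shares[c("E", "P")]), c(0.6, 0.4))
  expect_equal(length(r$cells), 10L)
  # near-equator strips: area shares within one cell of target
  expect_lt(max(abs(r$realized_area_shares[c("E", "P")] - c(0.6, 0.4))),
            1 / 10)

  r1 <- gen_species_range(w$assignment, c(P = 1.0), n_cells = 12L)
  expect_true(all(w$assignment[cell_id %in% r1$cells, region_id] == "P"))

  expect_error(gen_species_range(w$assignment, c(E = 1.0), n_cells = 33L),
               "region E too small")
  expect_error(gen_species_range(w$assignment, c(E = 0.7, P = 0.7)), "sum to 1")
})

test_that("presence sources honor the agreement rate", {
  w <- make_strip_world(widths = c(8, 8, 8))
  set.seed(42)
  rng <- gen_species_range(w$assignment, c(E = 0.5, P = 0.5), n_cells = 20L)

  s1 <- gen_presence_sources(rng$cells, 1, w$assignment$cell_id)
  for (src in c("occurrence", "enm", "sdm", "catch")) {
    expect_identical(s1[[src]], sort(rng$cells))
  }
  expect_identical(s1$consensus, sort(rng$cells))

  # recorded consensus equals an independent intersection of emitted layers
  set.seed(7)
  s2 <- gen_presence_sources(rng$cells, 0.9, w$assignment$cell_id)
  manual <- sort(intersect(intersect(s2$occurrence, s2$enm),
                           intersect(s2$sdm, s2$catch)))
  expect_identical(s2$consensus, manual)

  # zero agreement: model layers are (almost surely) disjoint from the range
  set.seed(8)
  s0 <- gen_presence_sources(rng$cells, 0, w$assignment$cell_id)
  expect_length(s0$consensus, 0L)

  expect_error(gen_presence_sources(rng$cells, 1.5, w$assignment$cell_id),
               "agreement_rate")
})

test_that("catch series realize their intended category", {
  set.seed(11)
  b <- gen_catch_series("B")
  expect_true(all(b$catch > 0.5 * max(b$catch)))
  expect_identical(predominant_category(b)$predominant, "B")

  nc <- gen_catch_series("NoCategory")
  expect_equal(nrow(nc), 8L)
  expect_identical(predominant_category(nc)$predominant, "NoCategory")
  expect_false(predominant_category(nc)$eligible)
  # at least one positive window year (keeps the catch filter satisfied)
  expect_gte(nrow(nc[year >= 2005 & year <= 2014 & catch > 0]), 1L)

  # modest recovery check here; the 200-draw experiment runs in acceptance
  for (cat_i in c("A", "C")) {
    hits <- vapply(1:25, function(i) {
      predominant_category(gen_catch_series(cat_i))$predominant == cat_i
    }, logical(1))
    expect_gte(mean(hits), 0.95)
  }
})

test_that("prices are positive, CPI covers the standardization years, and gaps are fillable", {
  set.seed(5)
  p <- gen_prices(c("S1", "S2"), c("C1", "C2"), 2005:2014)
  expect_true(all(p$prices$price > 0))
  expect_true(all(c(2010, 2019) %in% p$cpi$year))

  # drop a whole pair; the country-mean rule must cover it (the other
  # country keeps every year, so all gaps are fillable)
  set.seed(6)
  p2 <- gen_prices(c("S1", "S2"), c("C1", "C2"), 2005:2014,
                   missing_pair_frac = 0.25)
  needed <- data.table::CJ(species_id = c("S1", "S2"),
                           country_id = c("C1", "C2"), year = 2005:2014)
  filled <- fill_prices(p2$prices, needed)
  expect_false(any(filled$filled == "unfillable"))
  expect_true(all(filled$price > 0))
})

test_that("gen_world is deterministic and records coherent ground truth", {
  spec <- world_spec(seed = 21, n_regions = 5, n_species = 8,
                     source_agreement_rate = 1)
  w1 <- gen_world(spec)
  w2 <- gen_world(spec)
  expect_identical(w1$presence, w2$presence)
  expect_identical(w1$catch, w2$catch)
  expect_identical(w1$prices, w2$prices)
  expect_identical(w1$ground_truth, w2$ground_truth)

  gt <- w1$ground_truth
  # every species appears exactly once in the species table
  expect_setequal(gt$species$species_id, sprintf("S%03d", 1:8))
  expect_equal(anyDuplicated(gt$species$species_id), 0L)
  # stock labels consistent with the species label
  merged <- gt$stocks[gt$species, on = "species_id"]
  expect_true(all(merged[species_label == "discrete",
                         stock_label == "discrete_stock"]))
  expect_true(all(merged[stock_label == "transboundary",
                         species_label == "transboundary"]))
})

test_that("share_fractions in the spec drive the generated ranges", {
  spec <- world_spec(seed = 13, n_regions = 2, n_species = 1,
                     share_fractions = list(c(R01 = 0.93, R02 = 0.07)))
  w <- gen_world(spec, n_cells = 100L)
  sh <- w$species$S001$realized_count_shares
  expect_equal(unname(sh[c("R01", "R02")]), c(0.93, 0.07))
  # the small-share pair must fail the default threshold
  expect_false(any(w$ground_truth$pairs$passes))
  expect_identical(w$ground_truth$species$species_label, "discrete")
})

test_that("write_world emits a re-loadable directory", {
  spec <- world_spec(seed = 31, n_regions = 4, n_species = 5)
  w <- gen_world(spec)
  dir <- withr::local_tempdir()
  write_world(w, dir)
  inp <- read_world_inputs(dir)
  expect_equal(nrow(inp$grid), nrow(w$grid))
  expect_identical(sort(inp$regions$features$region_id),
                   sort(w$regions$features$region_id))
  expect_equal(nrow(inp$catch), nrow(w$catch))
  # geometry round-trips exactly
  expect_equal(inp$regions$geoms, w$regions$geoms)
})
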