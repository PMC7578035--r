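# CPI standardization, price filling, revenue, stock-class partition, rollups.

test_that("cpi_adjust is the index ratio, an identity at equal years, and invertible", {
  cpi <- data.table::data.table(year = c(2010, 2019), cpi = c(100, 120))
  expect_equal(cpi_adjust(100, 2010, 2019, cpi), 120)
  expect_equal(cpi_adjust(100, 2010, 2010, cpi), 100)
  v <- cpi_adjust(cpi_adjust(1234.5, 2010, 2019, cpi), 2019, 2010, cpi)
  expect_equal(v, 1234.5, tolerance = 1e-9)
  expect_error(cpi_adjust(1, 2009, 2019, cpi), "missing year 2009")
  expect_error(cpi_adjust(1, 2010, 2021, cpi), "missing year 2021")
})

test_that("price gaps fill by nearest year, then country mean, else flagged", {
  # 3 species x 3 years toy table with hand-computable fills
  pr <- data.table::data.table(
    species_id = c("s1", "s1", "s1", "s1", "s2"),
    country_id = c("c1", "c1", "c2", "c2", "c1"),
    year = c(2010L, 2013L, 2010L, 2011L, 2011L),
    price = c(100, 130, 200, 210, 50))
  needed <- data.table::data.table(
    species_id = c("s1", "s1", "s1", "s3"),
    country_id = c("c1", "c3", "c1", "c1"),
    year = c(2011L, 2011L, 2012L, 2011L))
  f <- fill_prices(pr, needed)
  # (s1,c1,2011): nearest year within s1xc1 is 2010 (tie rule: earlier) -> 100
  expect_equal(f[country_id == "c1" & year == 2011 & species_id == "s1", price], 100)
  expect_identical(f[country_id == "c1" & year == 2011 & species_id == "s1", filled],
                   "nearest_year")
  # (s1,c1,2012): 2013 is nearer than 2010 -> 130
  expect_equal(f[country_id == "c1" & year == 2012, price], 130)
  # (s1,c3,2011): no c3 prices; country mean of s1 at 2011 = 210 (only c2)
  expect_equal(f[country_id == "c3", price], 210)
  expect_identical(f[country_id == "c3", filled], "country_mean")
  # (s3,c1,2011): species unseen anywhere -> unfillable
  expect_identical(f[species_id == "s3", filled], "unfillable")
})

test_that("revenue closed forms hold", {
  cpi <- data.table::data.table(year = c(2010, 2019), cpi = c(100, 100))
  catch <- data.table::data.table(species_id = "s", region_id = "R",
                                  year = 2005:2014, tonnes = 10)
  prices <- data.table::data.table(species_id = "s", country_id = "C",
                                   year = 2005:2014, price = 1000)
  r <- revenue(catch, prices, cpi, c(R = "C"))
  expect_equal(r$window_mean$mean_revenue, 10 * 1000)
  expect_equal(r$window_mean$mean_catch, 10)
  expect_equal(r$n_dropped, 0L)

  # zero catch years contribute zero revenue
  catch2 <- data.table::copy(catch)[year %in% 2010:2014, tonnes := 0]
  r2 <- revenue(catch2, prices, cpi, c(R = "C"))
  expect_equal(r2$annual[year == 2012, revenue], 0)
  expect_equal(r2$window_mean$mean_revenue, 5 * 10 * 1000 / 10)

  # CPI standardization scales revenue by the index ratio
  cpi3 <- data.table::data.table(year = c(2010, 2019), cpi = c(100, 125))
  r3 <- revenue(catch, prices, cpi3, c(R = "C"))
  expect_equal(r3$window_mean$mean_revenue, 10 * 1000 * 1.25)

  # currency invariance: adjusting the summed 2010-USD total equals
  # summing per-year adjusted revenue
  tot_2010 <- r$window_mean$mean_revenue
  expect_equal(cpi_adjust(tot_2010, 2010, 2019, cpi3),
               r3$window_mean$mean_revenue, tolerance = 1e-12)
})

test_that("unfillable prices drop rows with a warning, not an error", {
  cpi <- data.table::data.table(year = c(2010, 2019), cpi = c(100, 120))
  catch <- data.table::data.table(species_id = c("s", "zz"),
                                  region_id = "R", year = 2010L, tonnes = 5)
  prices <- data.table::data.table(species_id = "s", country_id = "C",
                                   year = 2010L, price = 10)
  expect_warning(r <- revenue(catch, prices, cpi, c(R = "C")), "dropped")
  expect_equal(r$n_dropped, 1L)
  expect_equal(nrow(r$annual), 1L)
})

test_that("stock-class partition conserves totals and routes excluded stocks", {
  stocks <- data.table::data.table(
    species_id = c("anch", "anch", "anch", "loner"),
    region_id = c("P", "C", "E", "X"),
    stock_label = c("transboundary", "transboundary", "excluded_stock",
                    "discrete_stock"))
  wm <- data.table::data.table(
    species_id = c("anch", "anch", "anch", "loner"),
    region_id = c("P", "C", "E", "X"),
    mean_catch = c(100, 50, 30, 7), mean_revenue = c(1000, 500, 300, 70))
  part <- partition_by_stock_class(stocks, wm)
  expect_equal(part[stock_class == "transboundary", mean_annual_catch], 150)
  expect_equal(part[stock_class == "excluded_stock", mean_annual_catch], 30)
  expect_equal(part[stock_class == "excluded_stock", mean_annual_revenue], 300)
  expect_equal(part[stock_class == "discrete", mean_annual_catch], 7)
  expect_equal(sum(part$mean_annual_catch), sum(wm$mean_catch))
  expect_equal(sum(part$mean_annual_revenue), sum(wm$mean_revenue))

  # a world with only discrete species reports zero elsewhere
  part2 <- partition_by_stock_class(stocks[4], wm[4])
  expect_equal(part2[stock_class == "transboundary", mean_annual_catch], 0)
  expect_equal(part2[stock_class == "excluded_stock", mean_annual_revenue], 0)

  # unclassified stock is an error
  expect_error(partition_by_stock_class(stocks[1:3], wm), "unclassified stock")
})

test_that("regional rollup matches hand arithmetic on a 3-country toy", {
  rf <- data.table::data.table(
    region_id = c("R1", "R2", "R3"),
    parent_country_for_grouping = c("c1", "c2", "c3"),
    un_subregion = c("North", "North", "South"),
    area_km2 = c(1000, 4000, 500))
  stocks <- data.table::data.table(
    species_id = "s", region_id = c("R1", "R2", "R3"),
    stock_label = c("transboundary", "transboundary", "transboundary"))
  wm <- data.table::data.table(
    species_id = "s", region_id = c("R1", "R2", "R3"),
    mean_catch = c(10, 40, 5), mean_revenue = c(100, 400, 50))
  roll <- regional_rollup(wm, stocks, rf)
  co <- roll$country[order(country_id)]
  expect_equal(co$catch_per_km2, c(10 / 1000, 40 / 4000, 5 / 500))
  expect_equal(co$revenue_per_km2, c(0.1, 0.1, 0.1))
  sr <- roll$subregion[order(un_subregion)]
  expect_equal(sr[un_subregion == "North", mean_catch], 25)
  expect_equal(sr[un_subregion == "North", sd_catch], stats::sd(c(10, 40)))
  expect_equal(sr[un_subregion == "North", n_countries], 2L)
  # one-country sub-region: sd collapses to 0 and is flagged degenerate
  expect_equal(sr[un_subregion == "South", sd_catch], 0)
  expect_true(sr[un_subregion == "South", degenerate])

  # linearity: doubling every country revenue doubles the sub-region mean
  wm2 <- data.table::copy(wm)[, mean_revenue := mean_revenue * 2]
  roll2 <- regional_rollup(wm2, stocks, rf)
  expect_equal(roll2$subregion[un_subregion == "North", mean_revenue],
               2 * sr[un_subregion == "North", mean_revenue])

  # missing sub-region labels are an error
  rf_bad <- data.table::copy(rf)[1, un_subregion := NA_character_]
  expect_error(regional_rollup(wm, stocks, rf_bad), "un_subregion")
})

test_that("per-km2 denominators only count regions hosting the stock class", {
  rf <- data.table::data.table(
    region_id = c("R1", "R2"),
    parent_country_for_grouping = c("c1", "c1"),
    un_subregion = "North", area_km2 = c(1000, 9000))
  stocks <- data.table::data.table(species_id = "s", region_id = "R1",
                                   stock_label = "transboundary")
  wm <- data.table::data.table(species_id = "s", region_id = "R1",
                               mean_catch = 10, mean_revenue = 100)
  roll <- regional_rollup(wm, stocks, rf)
  # R2 hosts no transboundary stock: denominator is 1000, not 10000
  expect_equal(roll$country$area_km2, 1000)
  expect_equal(roll$country$catch_per_km2, 0.01)
})

test_that("synthetic-world totals equal a brute-force summation oracle", {
  spec <- world_spec(seed = 37, n_regions = 5, n_species = 10)
  w <- gen_world(spec)
  r <- revenue(w$catch, w$prices, w$cpi, grouping_country(w$regions))
  # brute force: loop over all species x region x window-year triples
  cp <- as.data.frame(w$prices); ct <- as.data.frame(w$catch)
  grp <- grouping_country(w$regions)
  factor <- w$cpi$cpi[w$cpi$year == 2019] / w$cpi$cpi[w$cpi$year == 2010]
  tot <- 0
  for (i in seq_len(nrow(ct))) {
    if (ct$year[i] < 2005 || ct$year[i] > 2014) next
    pri <- cp$price[cp$species_id == ct$species_id[i] &
                      cp$country_id == grp[[ct$region_id[i]]] &
                      cp$year == ct$year[i]]
    tot <- tot + ct$tonnes[i] * pri * factor
  }
  expect_equal(sum(r$window_mean$mean_revenue) * 10, tot, tolerance = 1e-9)
})
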