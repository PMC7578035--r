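# Catch and ex-vessel revenue accounting: CPI standardization, price-gap
# filling, partition by stock class, and country / UN sub-region rollups with
# per-km2 weighting.

#' CPI-standardize a dollar value between reference years
#'
#' @param value numeric value(s) in `from_year` real USD.
#' @param from_year,to_year reference years; both must appear in `cpi`.
#' @param cpi `data.table`/data.frame with `year` and `cpi` columns (annual
#'   mean index).
#' @return `value * cpi[to_year] / cpi[from_year]`.
#' @export
cpi_adjust <- function(value, from_year, to_year, cpi) {
  cp <- data.table::as.data.table(cpi)
  f <- cp$cpi[match(from_year, cp$year)]
  t <- cp$cpi[match(to_year, cp$year)]
  if (anyNA(f)) stop("CPI table missing year ", from_year)
  if (anyNA(t)) stop("CPI table missing year ", to_year)
  value * t / f
}

#' Fill gaps in an ex-vessel price table
#'
#' Three-step fill for each required (species, country, year): the observed
#' price; else the nearest observed year within the same species x country
#' (ties to the earlier year); else the mean observed price across countries
#' for that species and year. Rows still missing are flagged unfillable and
#' dropped by [revenue()].
#'
#' @param prices observed prices (`species_id`, `country_id`, `year`, `price`).
#' @param needed `data.table` of required (species_id, country_id, year).
#' @return `data.table` `needed` plus `price` and `filled` in
#'   `{"observed", "nearest_year", "country_mean", "unfillable"}`.
#' @export
fill_prices <- function(prices, needed) {
  pr <- data.table::as.data.table(prices)
  nd <- unique(data.table::as.data.table(needed)[
    , .(species_id, country_id, year)])
  out <- pr[nd, on = c("species_id", "country_id", "year")]
  out[, filled := ifelse(is.na(price), NA_character_, "observed")]
  todo <- which(is.na(out$price))
  if (length(todo)) {
    # nearest year within species x country
    for (i in todo) {
      cand <- pr[species_id == out$species_id[i] &
                   country_id == out$country_id[i]]
      if (nrow(cand)) {
        d <- abs(cand$year - out$year[i])
        best <- cand[order(d, year)][1]
        data.table::set(out, i, "price", best$price)
        data.table::set(out, i, "filled", "nearest_year")
      }
    }
  }
  todo <- which(is.na(out$price))
  if (length(todo)) {
    cm <- pr[, .(cmean = mean(price)), by = .(species_id, year)]
    for (i in todo) {
      hit <- cm[species_id == out$species_id[i] & year == out$year[i]]
      if (nrow(hit)) {
        data.table::set(out, i, "price", hit$cmean)
        data.table::set(out, i, "filled", "country_mean")
      }
    }
  }
  out[is.na(price), filled := "unfillable"]
  out[]
}

#' Annual fishing revenue and window means per species x region
#'
#' Revenue(year) = catch(year) x ex-vessel price(species, country, year),
#' CPI-standardized from `price_base_year` real USD to `usd_target_year`.
#' The window mean divides by the number of window years (missing years count
#' as zero), matching an "annual average over the window" reading.
#'
#' @param catch `data.table` (species_id, region_id, year, tonnes).
#' @param prices observed price table (2010 real USD per tonne).
#' @param cpi CPI table covering `price_base_year` and `usd_target_year`.
#' @param region_countries named vector region_id -> country_id used to look
#'   prices up (grouping countries; see [grouping_country()]).
#' @param window averaging window, default `c(2005, 2014)`.
#' @param price_base_year base year of the price table (default 2010).
#' @param usd_target_year target real-USD year (default 2019).
#' @return list: `annual` (species_id, region_id, year, tonnes, revenue),
#'   `window_mean` (species_id, region_id, mean_catch, mean_revenue),
#'   `n_dropped` (rows excluded for unfillable prices).
#' @export
revenue <- function(catch, prices, cpi, region_countries,
                    window = c(2005, 2014), price_base_year = 2010,
                    usd_target_year = 2019) {
  ct <- data.table::as.data.table(catch)
  ct[, country_id := region_countries[region_id]]
  if (anyNA(ct$country_id)) {
    stop("regions without a country mapping: ",
         paste(unique(ct$region_id[is.na(ct$country_id)]), collapse = ", "))
  }
  filled <- fill_prices(prices, ct[, .(species_id, country_id, year)])
  ct <- filled[ct, on = c("species_id", "country_id", "year")]
  n_dropped <- sum(ct$filled == "unfillable")
  if (n_dropped > 0) {
    warning(n_dropped, " catch rows dropped: unfillable prices")
    ct <- ct[filled != "unfillable"]
  }
  factor <- cpi_adjust(1, price_base_year, usd_target_year, cpi)
  ct[, revenue := tonnes * price * factor]
  nwin <- window[2] - window[1] + 1
  wm <- ct[year >= window[1] & year <= window[2],
           .(mean_catch = sum(tonnes) / nwin,
             mean_revenue = sum(revenue) / nwin),
           by = .(species_id, region_id)]
  list(annual = ct[, .(species_id, region_id, year, tonnes, revenue)],
       window_mean = wm[], n_dropped = n_dropped)
}

#' Partition window-mean catch and revenue by stock class
#'
#' Every species x region lands in exactly one of: `transboundary` stocks,
#' `excluded_stock`s of transboundary species, or `discrete` species; class
#' totals conserve the grand totals exactly.
#'
#' @param stocks classification table (species_id, region_id, stock_label)
#'   from [classify_all()].
#' @param window_mean per species x region window means from [revenue()].
#' @return `data.table` with one row per stock class: mean annual catch and
#'   revenue plus `n_stocks`; classes absent from the data report zeros.
#' @export
partition_by_stock_class <- function(stocks, window_mean) {
  st <- data.table::as.data.table(stocks)
  wm <- data.table::as.data.table(window_mean)
  merged <- st[, .(species_id, region_id, stock_label)][
    wm, on = c("species_id", "region_id")]
  if (anyNA(merged$stock_label)) {
    bad <- merged[is.na(stock_label)][1]
    stop("unclassified stock encountered: ", bad$species_id, " in ",
         bad$region_id)
  }
  merged[, stock_class := data.table::fcase(
    stock_label == "transboundary", "transboundary",
    stock_label == "excluded_stock", "excluded_stock",
    stock_label == "discrete_stock", "discrete")]
  out <- merged[, .(mean_annual_catch = sum(mean_catch),
                    mean_annual_revenue = sum(mean_revenue),
                    n_stocks = .N), by = stock_class]
  all_classes <- data.table::data.table(
    stock_class = c("transboundary", "excluded_stock", "discrete"))
  out <- out[all_classes, on = "stock_class"]
  out[is.na(mean_annual_catch), `:=`(mean_annual_catch = 0,
                                     mean_annual_revenue = 0, n_stocks = 0L)]
  out[]
}

#' Roll catch/revenue up to countries and UN sub-regions with per-km2 weights
#'
#' Country rows aggregate the country's regions; the per-km2 denominator is
#' the summed area of the country's EEZ regions hosting at least one stock of
#' the selected class. Sub-region rows report mean and sd across member
#' countries (sample sd; a one-country group reports sd 0 and is flagged).
#'
#' @param window_mean per species x region window means from [revenue()].
#' @param stocks classification table with `stock_label`.
#' @param region_features the `features` table of an `eez_regions` (needs
#'   region_id, parent_country_for_grouping, un_subregion, area_km2).
#' @param stock_class which class to roll up (default `"transboundary"`).
#' @return list: `country` (`data.table` per country: catch, revenue,
#'   area_km2, catch_per_km2, revenue_per_km2, un_subregion) and `subregion`
#'   (`data.table` per UN sub-region: means and sds across countries,
#'   n_countries, degenerate flag).
#' @export
regional_rollup <- function(window_mean, stocks, region_features,
                            stock_class = "transboundary") {
  rf <- data.table::as.data.table(region_features)
  if (anyNA(rf$un_subregion)) {
    stop("un_subregion missing for region(s): ",
         paste(rf$region_id[is.na(rf$un_subregion)], collapse = ", "))
  }
  st <- data.table::as.data.table(stocks)
  wanted <- if (stock_class == "discrete") "discrete_stock" else stock_class
  sel <- st[stock_label == wanted, .(species_id, region_id)]
  wm <- data.table::as.data.table(window_mean)[
    sel, on = c("species_id", "region_id"), nomatch = NULL]
  wm[, `:=`(country_id = rf$parent_country_for_grouping[
              match(region_id, rf$region_id)],
            un_subregion = rf$un_subregion[match(region_id, rf$region_id)])]

  # per-km2 denominator: area of regions hosting >= 1 stock of the class
  host <- rf[region_id %in% unique(sel$region_id)]
  host_area <- host[, .(area_km2 = sum(area_km2)),
                    by = .(country_id = parent_country_for_grouping)]

  country <- wm[, .(catch = sum(mean_catch), revenue = sum(mean_revenue),
                    un_subregion = un_subregion[1]), by = country_id]
  country[, area_km2 := host_area$area_km2[match(country_id,
                                                 host_area$country_id)]]
  country[, `:=`(catch_per_km2 = catch / area_km2,
                 revenue_per_km2 = revenue / area_km2)]

  subregion <- country[, .(
    mean_catch = mean(catch), sd_catch = stats::sd(catch),
    mean_revenue = mean(revenue), sd_revenue = stats::sd(revenue),
    mean_catch_per_km2 = mean(catch_per_km2),
    sd_catch_per_km2 = stats::sd(catch_per_km2),
    mean_revenue_per_km2 = mean(revenue_per_km2),
    sd_revenue_per_km2 = stats::sd(revenue_per_km2),
    area_km2 = sum(area_km2),
    n_countries = .N), by = un_subregion]
  subregion[, degenerate := n_countries == 1L]
  sdcols <- grep("^sd_", names(subregion), value = TRUE)
  for (cl in sdcols) subregion[is.na(get(cl)), (cl) := 0]
  list(country = country[], subregion = subregion[])
}
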