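# Shared helpers.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Largest-remainder apportionment of N items to proportions p (sums to 1).
apportion <- function(N, p) {
  base <- floor(p * N)
  rem <- N - sum(base)
  if (rem > 0) {
    frac <- p * N - base
    take <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1L
  }
  as.integer(base)
}

# Longest run of consecutive calendar years in an integer year vector.
max_consecutive_years <- function(years) {
  if (!length(years)) return(0L)
  y <- sort(unique(as.integer(years)))
  if (length(y) == 1L) return(1L)
  runs <- rle(diff(y) == 1L)
  best <- if (any(runs$values)) max(runs$lengths[runs$values]) + 1L else 1L
  best
}

utils::globalVariables(c(
  ".", ".N", "area_km2", "best_min_ai", "best_pair", "catch", "cell_id",
  "country_id", "country_name", "lat", "lon", "n_years", "name",
  "parent_country_for_grouping", "passes", "predominant", "price", "reason",
  "region_a", "region_b", "region_id", "revenue", "species_id", "stock_label",
  "territory_class", "tonnes", "un_subregion", "usable", "year", "min_ai",
  "species_label", "source", "cpi", "filled", "eligible", "stock_class",
  "ai_a", "ai_b", "n_supporting_sources", "J", "value",
  "mean_catch", "mean_revenue", "mean_annual_catch", "mean_annual_revenue",
  "catch_per_km2", "revenue_per_km2", "n_countries", "degenerate", "category",
  "cmean", "i.price", "n_stocks"
))
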