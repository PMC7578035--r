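# Synthetic catch series realizing a chosen trend category, plus ex-vessel
# prices and a CPI table.

TREND_CATEGORIES <- c("A", "B", "C", "NoCategory")

#' Generate a catch series realizing a chosen trend category
#'
#' Inverts the per-year categorization rules: the emitted series, when
#' assessed over the reference window, yields the requested predominant
#' category.
#'
#' Shapes: \strong{B} (constant) draws every year above 55% of the series
#' maximum, so all years clear the `> 0.5 * max` rule. \strong{C}
#' (decreasing) peaks mid-series and declines so window years fall in
#' (12%, 45%) of the maximum with the post-peak minimum kept above 10% (the
#' rebuilding clause must not fire). \strong{A} (increasing) draws one of two
#' shapes: a late-peak series whose maximum is the final data year, or an
#' early-peak collapse (post-peak minimum below 10%) followed by a rebuild
#' into the window. \strong{NoCategory} emits 8 scattered data years, below
#' the 10-year eligibility floor (with at least one positive window year so
#' the species still passes the catch-positivity presence filter).
#'
#' @param category one of `"A"`, `"B"`, `"C"`, `"NoCategory"`.
#' @param years candidate data years (default 1951:2014).
#' @param window reference window for the predominant category
#'   (default `c(2005, 2014)`).
#' @param magnitude optional series scale (tonnes); drawn lognormal if `NULL`.
#' @return `data.table` with `year`, `catch` (tonnes).
#' @export
gen_catch_series <- function(category = c("A", "B", "C", "NoCategory"),
                             years = 1951:2014, window = c(2005, 2014),
                             magnitude = NULL) {
  category <- match.arg(category)
  years <- sort(unique(as.integer(years)))
  M <- magnitude %||% exp(stats::rnorm(1, log(5e4), 0.8))
  n <- length(years)
  in_win <- years >= window[1] & years <= window[2]
  if (!any(in_win)) in_win <- years %in% utils::tail(years, 10)

  if (category == "NoCategory") {
    # 8 scattered years, spaced >= 2 apart -> never 5 consecutive, and < 10
    # total; force one window year so the catch-positivity filter still sees
    # positive catch.
    cand <- years[seq(1, n, by = 2)]
    win_cand <- cand[cand >= window[1] & cand <= window[2]]
    if (!length(win_cand)) win_cand <- utils::tail(cand, 1)
    rest <- setdiff(cand, win_cand)
    pick <- sort(c(win_cand[sample.int(length(win_cand), 1)],
                   rest[sample.int(length(rest), 7)]))
    return(data.table::data.table(year = pick,
                                  catch = M * stats::runif(8, 0.2, 1)))
  }

  catch <- numeric(n)
  if (category == "B") {
    catch <- M * stats::runif(n, 0.55, 1)
  } else if (category == "C") {
    pre_win <- which(!in_win)
    i_peak <- pre_win[max(2L, floor(length(pre_win) * 0.4))]
    ramp_up <- seq(0.2, 0.9, length.out = i_peak)
    catch[seq_len(i_peak)] <- M * pmin(ramp_up * stats::runif(i_peak, 0.85, 1.05), 0.95)
    catch[i_peak] <- M
    mid <- seq(i_peak + 1L, n)[!in_win[seq(i_peak + 1L, n)]]
    if (length(mid)) {
      decl <- seq(0.9, 0.45, length.out = length(mid))
      catch[mid] <- M * pmax(pmin(decl * stats::runif(length(mid), 0.9, 1.1), 0.95), 0.13)
    }
    catch[in_win] <- M * stats::runif(sum(in_win), 0.12, 0.45)
  } else { # A
    if (stats::runif(1) < 0.5) {
      # late peak: maximum in the final data year
      catch <- M * (seq(0.10, 0.42, length.out = n) * stats::runif(n, 0.85, 1.05))
      catch <- pmin(catch, 0.45 * M)
      catch[n] <- M
    } else {
      # early peak, collapse below 10%, rebuild through the window
      i_peak <- max(3L, floor(n * 0.25))
      i_min <- floor(n * 0.6)  # well before the window
      catch[seq_len(i_peak)] <- M * seq(0.3, 0.9, length.out = i_peak) *
        stats::runif(i_peak, 0.9, 1.05)
      catch[seq_len(i_peak - 1L)] <- pmin(catch[seq_len(i_peak - 1L)], 0.95 * M)
      catch[i_peak] <- M
      decl_idx <- seq(i_peak + 1L, i_min - 1L)
      catch[decl_idx] <- M * pmax(seq(0.8, 0.12, length.out = length(decl_idx)) *
                                    stats::runif(length(decl_idx), 0.9, 1.1), 0.11)
      catch[i_min] <- M * stats::runif(1, 0.02, 0.08)
      reb_idx <- seq(i_min + 1L, n)
      catch[reb_idx] <- M * pmax(pmin(
        seq(0.13, 0.42, length.out = length(reb_idx)) *
          stats::runif(length(reb_idx), 0.9, 1.1), 0.45), 0.12)
      catch[in_win] <- M * stats::runif(sum(in_win), 0.12, 0.45)
    }
  }
  data.table::data.table(year = years, catch = catch)
}

#' Generate ex-vessel prices and a CPI table
#'
#' Prices are per species x country x year in 2010 real USD per tonne:
#' a lognormal species base price, a country multiplier and a mild year
#' drift. Fractions of rows or whole species-country pairs can be knocked out
#' to exercise the price-filling rules downstream. The CPI table is a smooth
#' annual index (2.1%/yr, 2010 = 100) covering 1950-2020.
#'
#' @param species_ids,country_ids,years identifiers to cover.
#' @param missing_year_frac fraction of price rows dropped at random.
#' @param missing_pair_frac fraction of species-country pairs dropped whole.
#' @return list with `prices` (`data.table`: species_id, country_id, year,
#'   price) and `cpi` (`data.table`: year, cpi).
#' @export
gen_prices <- function(species_ids, country_ids, years,
                       missing_year_frac = 0, missing_pair_frac = 0) {
  base <- stats::setNames(exp(stats::rnorm(length(species_ids), log(1500), 0.5)),
                          species_ids)
  mult <- stats::setNames(stats::runif(length(country_ids), 0.7, 1.3),
                          country_ids)
  p <- data.table::CJ(species_id = species_ids, country_id = country_ids,
                      year = as.integer(years))
  p[, price := base[species_id] * mult[country_id] *
      (1 + 0.01 * (year - 2010)) * stats::runif(.N, 0.95, 1.05)]
  p[price <= 0, price := 1]
  if (missing_pair_frac > 0) {
    pairs <- unique(p[, .(species_id, country_id)])
    k <- floor(nrow(pairs) * missing_pair_frac)
    if (k > 0) {
      drop <- pairs[sample(.N, k)]
      p <- p[!drop, on = c("species_id", "country_id")]
    }
  }
  if (missing_year_frac > 0) {
    keep <- stats::runif(nrow(p)) > missing_year_frac
    p <- p[keep]
  }
  list(prices = p[], cpi = gen_cpi())
}

#' Synthetic annual CPI table
#'
#' @param years years to cover (default 1950:2020, includes 2010 and 2019).
#' @return `data.table` with `year` and `cpi` (2010 = 100).
#' @export
gen_cpi <- function(years = 1950:2020) {
  data.table::data.table(year = as.integer(years),
                         cpi = 100 * 1.021^(years - 2010))
}
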