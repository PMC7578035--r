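# Catch-trend categorization per species x EEZ.
#
# Per-year rules relative to the series' historical maximum (precedence
# B -> A -> C; all comparisons strict unless noted):
#   B (constant):    catch > 0.50 * max
#   A (increasing):  the year of maximum catch is the last data year; OR the
#                    year precedes the maximum and catch <= 0.50 * max
#                    (non-strict as printed in the source rule set); OR a
#                    post-peak collapse occurred (post-max minimum < 0.10 *
#                    max), the year follows that minimum, and catch lies in
#                    (0.10, 0.50) * max — the "rebuilding" clause;
#   C (decreasing):  the year follows the maximum and catch < 0.10 * max or
#                    lies in (0.10, 0.50) * max.
# A series is eligible only with >= 10 data years in 1951-2014 and >= 5
# consecutive data years; ineligible series get predominant = NoCategory.
# The predominant category is the modal per-year category over window years
# (unassigned years do not vote); ties break to the category of the latest
# categorized window year among the tied set.

#' Derive max/min statistics of a catch series
#'
#' @param series `data.table`/data.frame with `year` and `catch` columns.
#' @return list: `max_catch`, `year_of_max` (earliest year attaining the
#'   maximum), `post_max_min` and `year_of_post_max_min` (earliest, over
#'   years strictly after `year_of_max`; `NA` when none exist), `last_year`,
#'   `degenerate` (`TRUE` for an all-zero series).
#' @export
derive_stats <- function(series) {
  s <- data.table::as.data.table(series)
  if (!nrow(s)) stop("empty catch series")
  if (any(s$catch < 0)) stop("negative catch")
  s <- s[order(year)]
  mx <- max(s$catch)
  ymax <- s$year[which.max(s$catch)]  # earliest year attaining the max
  post <- s[year > ymax]
  if (nrow(post)) {
    pmin_v <- min(post$catch)
    ypmin <- post$year[which.min(post$catch)]
  } else {
    pmin_v <- NA_real_; ypmin <- NA_integer_
  }
  list(max_catch = mx, year_of_max = ymax,
       post_max_min = pmin_v, year_of_post_max_min = ypmin,
       last_year = max(s$year), degenerate = mx == 0)
}

#' Categorize one year of a catch series
#'
#' @param year data year.
#' @param catch catch in that year (tonnes).
#' @param stats statistics from [derive_stats()].
#' @return one of `"A"`, `"B"`, `"C"`, `"unassigned"`.
#' @export
categorize_year <- function(year, catch, stats) {
  categorize_years(year, catch, stats)
}

# Vectorized over years/catches.
categorize_years <- function(years, catches, stats) {
  n <- length(years)
  out <- rep("unassigned", n)
  if (stats$degenerate) return(out)
  mx <- stats$max_catch
  b <- catches > 0.5 * mx
  a1 <- stats$year_of_max == stats$last_year
  a2 <- years < stats$year_of_max & catches <= 0.5 * mx
  a3 <- if (!is.na(stats$post_max_min)) {
    years > stats$year_of_post_max_min &
      stats$post_max_min < 0.1 * mx &
      catches > 0.1 * mx & catches < 0.5 * mx
  } else rep(FALSE, n)
  a <- a1 | a2 | a3
  cc <- years > stats$year_of_max &
    (catches < 0.1 * mx | (catches > 0.1 * mx & catches < 0.5 * mx))
  out[cc] <- "C"
  out[a] <- "A"
  out[b] <- "B"   # precedence B over A over C
  out
}

#' Eligibility of a catch series for trend assessment
#'
#' @param years data years of the series.
#' @param span assessable period, default `c(1951, 2014)`.
#' @return `TRUE` when >= 10 data years fall in the span and >= 5 of them are
#'   consecutive calendar years.
#' @export
eligible_series <- function(years, span = c(1951, 2014)) {
  y <- years[years >= span[1] & years <= span[2]]
  length(unique(y)) >= 10L && max_consecutive_years(y) >= 5L
}

#' Predominant trend category of a catch series
#'
#' @param series `data.table` with `year`, `catch`.
#' @param window reference window, default `c(2005, 2014)`.
#' @param span eligibility period, default `c(1951, 2014)`.
#' @return list of class `trend_assessment`: derived stats, `eligible`,
#'   per-year categories over the window (`year_categories`), `predominant`
#'   (`"A"/"B"/"C"/"NoCategory"`) and `reason` (`"ok"`, `"ineligible"`, or
#'   `"no_categorized_window_years"`).
#' @export
predominant_category <- function(series, window = c(2005, 2014),
                                 span = c(1951, 2014)) {
  s <- data.table::as.data.table(series)[order(year)]
  out <- list(n_years = nrow(s), eligible = eligible_series(s$year, span))
  if (!out$eligible) {
    out <- c(out, list(stats = NULL, year_categories = NULL,
                       predominant = "NoCategory", reason = "ineligible"))
    return(structure(out, class = "trend_assessment"))
  }
  st <- derive_stats(s)
  win <- s[year >= window[1] & year <= window[2]]
  cats <- categorize_years(win$year, win$catch, st)
  names(cats) <- win$year
  voting <- cats[cats != "unassigned"]
  if (!length(voting)) {
    pred <- "NoCategory"; reason <- "no_categorized_window_years"
  } else {
    tab <- table(voting)
    topk <- names(tab)[tab == max(tab)]
    if (length(topk) == 1L) {
      pred <- topk
    } else {
      # latest categorized window year whose category is among the tied set
      late <- rev(voting[voting %in% topk])
      pred <- late[[1]]
    }
    reason <- "ok"
  }
  structure(c(out, list(stats = st, year_categories = cats,
                        predominant = pred, reason = reason)),
            class = "trend_assessment")
}

#' @export
print.trend_assessment <- function(x, ...) {
  cat("<trend_assessment> predominant=", x$predominant,
      " (", x$reason, "), n_years=", x$n_years, "\n", sep = "")
  invisible(x)
}

#' Assess trends for every species x region series in a catch table
#'
#' @param catch `data.table` (species_id, region_id, year, tonnes).
#' @param window,span as in [predominant_category()].
#' @return `data.table` per species x region: max_catch, year_of_max,
#'   post_max_min, predominant, n_years, eligible, reason, year_categories
#'   (window categories packed as a string).
#' @export
assess_trends <- function(catch, window = c(2005, 2014), span = c(1951, 2014)) {
  ct <- data.table::as.data.table(catch)
  keys <- unique(ct[, .(species_id, region_id)])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sp <- keys$species_id[i]; rid <- keys$region_id[i]
    s <- ct[species_id == sp & region_id == rid, .(year, catch = tonnes)]
    a <- predominant_category(s, window, span)
    data.table::data.table(
      species_id = sp, region_id = rid,
      max_catch = if (is.null(a$stats)) NA_real_ else a$stats$max_catch,
      year_of_max = if (is.null(a$stats)) NA_integer_ else a$stats$year_of_max,
      post_max_min = if (is.null(a$stats)) NA_real_ else a$stats$post_max_min,
      predominant = a$predominant, n_years = a$n_years,
      eligible = a$eligible, reason = a$reason,
      year_categories = if (is.null(a$year_categories)) "" else
        paste(paste0(names(a$year_categories), ":",
                     substr(a$year_categories, 1, 1)), collapse = ",")
    )
  })
  data.table::rbindlist(rows)
}
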