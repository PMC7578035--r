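# Specification object for a synthetic world.

#' Define a synthetic world
#'
#' A `world_spec` captures every knob of the synthetic generator: the bounding
#' box and grid resolution of the mosaic, the number of EEZ regions and
#' species, the per-cell agreement rate of the presence sources, and optional
#' per-species target shares of range across regions. Identical specs (same
#' seed included) regenerate bitwise-identical worlds.
#'
#' @param seed integer RNG seed; every stochastic choice derives from it.
#' @param n_regions number of EEZ regions in the mosaic (>= 2).
#' @param bbox `c(lon_min, lat_min, lon_max, lat_max)` in degrees; default a
#'   20 x 10 degree low-latitude window so cell areas are near-equatorial.
#' @param grid_resolution cell edge in degrees (default 0.5, the standard
#'   marine analysis grid); must divide both bbox extents.
#' @param n_species number of species to generate.
#' @param source_agreement_rate probability in `[0, 1]` that a presence source
#'   reproduces a range cell faithfully; 1 means all four sources agree
#'   exactly (the noise-free world).
#' @param share_fractions optional list (length `n_species`) of named numeric
#'   vectors (region_id -> target proportion of range, summing to 1). `NULL`
#'   draws shares at generation time.
#' @return object of class `world_spec`.
#' @export
world_spec <- function(seed, n_regions, bbox = c(0, -5, 20, 5),
                       grid_resolution = 0.5, n_species = 10,
                       source_agreement_rate = 1, share_fractions = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (n_regions < 2) stop("n_regions must be >= 2")
  check_bbox(bbox)
  nx <- (bbox[3] - bbox[1]) / grid_resolution
  ny <- (bbox[4] - bbox[2]) / grid_resolution
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9) {
    stop("grid_resolution must divide bbox extents")
  }
  if (source_agreement_rate < 0 || source_agreement_rate > 1) {
    stop("source_agreement_rate must be in [0, 1]")
  }
  if (!is.null(share_fractions)) {
    if (length(share_fractions) != n_species) {
      stop("share_fractions must have one entry per species")
    }
    for (s in share_fractions) {
      if (abs(sum(s) - 1) > 1e-9) stop("share_fractions entries must sum to 1")
      if (any(s < 0)) stop("share_fractions must be non-negative")
    }
  }
  structure(list(
    seed = as.integer(seed), n_regions = as.integer(n_regions), bbox = bbox,
    grid_resolution = grid_resolution, n_species = as.integer(n_species),
    source_agreement_rate = source_agreement_rate,
    share_fractions = share_fractions
  ), class = "world_spec")
}

#' @export
print.world_spec <- function(x, ...) {
  cat("<world_spec> seed=", x$seed, " regions=", x$n_regions,
      " species=", x$n_species, " agreement=", x$source_agreement_rate,
      " bbox=[", paste(x$bbox, collapse = ", "), "] res=",
      x$grid_resolution, "\n", sep = "")
  invisible(x)
}
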