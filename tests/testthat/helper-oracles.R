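# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain vectors, loops and literal rule transcriptions.

# Winding-number point-in-polygon (different algorithm from the package's
# even-odd ray cast; agrees for simple non-self-intersecting rings).
oracle_point_in_ring <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring) - 1
  wn <- 0
  for (i in 1:n) {
    if (y[i] <= py) {
      if (y[i + 1] > py && (x[i + 1] - x[i]) * (py - y[i]) -
          (px - x[i]) * (y[i + 1] - y[i]) > 0) wn <- wn + 1
    } else {
      if (y[i + 1] <= py && (x[i + 1] - x[i]) * (py - y[i]) -
          (px - x[i]) * (y[i + 1] - y[i]) < 0) wn <- wn - 1
    }
  }
  wn != 0
}

oracle_point_in_geom <- function(px, py, geom) {
  for (poly in geom) for (ring in poly) {
    if (oracle_point_in_ring(px, py, ring)) return(TRUE)
  }
  FALSE
}

# Cell-based adjacency oracle for lattice mosaics: two regions touch along an
# edge iff they own rook-neighboring cells; at a corner iff only
# queen-neighboring cells. Works directly off the assigned grid, independent
# of the polygon/segment machinery.
oracle_adjacency <- function(grid, res) {
  g <- as.data.frame(grid)
  key <- paste(floor(g$lon / res), floor(g$lat / res))
  reg <- setNames(g$region_id, key)
  edge_pairs <- character(0); corner_pairs <- character(0)
  for (i in seq_len(nrow(g))) {
    cx <- floor(g$lon[i] / res); cy <- floor(g$lat[i] / res)
    for (d in list(c(1, 0), c(0, 1))) {
      nb <- reg[paste(cx + d[1], cy + d[2])]
      if (!is.na(nb) && nb != g$region_id[i]) {
        edge_pairs <- c(edge_pairs,
                        paste(sort(c(g$region_id[i], nb)), collapse = "|"))
      }
    }
    for (d in list(c(1, 1), c(1, -1))) {
      nb <- reg[paste(cx + d[1], cy + d[2])]
      if (!is.na(nb) && nb != g$region_id[i]) {
        corner_pairs <- c(corner_pairs,
                          paste(sort(c(g$region_id[i], nb)), collapse = "|"))
      }
    }
  }
  edge_pairs <- unique(edge_pairs)
  corner_pairs <- setdiff(unique(corner_pairs), edge_pairs)
  list(edge = sort(edge_pairs), corner = sort(corner_pairs))
}

# Brute-force transboundary classification: enumerate every usable pair and
# every cell with plain loops.
oracle_classify <- function(cells, usable_pairs, grid, threshold = 0.25,
                            weighting = "km2") {
  g <- as.data.frame(grid)
  idx <- match(cells, g$cell_id)
  creg <- g$region_id[idx]
  cw <- if (weighting == "km2") g$area_km2[idx] else rep(1, length(idx))
  present <- sort(unique(creg[!is.na(creg)]))
  passing_regions <- character(0)
  ai_rows <- list()
  for (k in seq_len(nrow(usable_pairs))) {
    a <- usable_pairs$region_a[k]; b <- usable_pairs$region_b[k]
    wa <- sum(cw[which(creg == a)]); wb <- sum(cw[which(creg == b)])
    if (wa + wb <= 0) next
    ai_a <- wa / (wa + wb)
    pass <- min(ai_a, 1 - ai_a) > threshold
    ai_rows[[length(ai_rows) + 1]] <-
      data.frame(region_a = a, region_b = b, ai_a = ai_a, passes = pass)
    if (pass) passing_regions <- union(passing_regions, c(a, b))
  }
  sp_label <- if (length(passing_regions)) "transboundary" else "discrete"
  stock <- vapply(present, function(r) {
    if (r %in% passing_regions) "transboundary"
    else if (sp_label == "transboundary") "excluded_stock" else "discrete_stock"
  }, character(1))
  list(species_label = sp_label,
       stocks = data.frame(region_id = present, stock_label = unname(stock)),
       ai = if (length(ai_rows)) do.call(rbind, ai_rows) else NULL)
}

# Literal per-year transcription of the trend rules (B, then A, then C).
oracle_categorize <- function(years, catches) {
  mx <- max(catches)
  if (mx == 0) return(rep("unassigned", length(years)))
  ymax <- years[which(catches == mx)[1]]
  post <- which(years > ymax)
  has_post <- length(post) > 0
  if (has_post) {
    pmm <- min(catches[post])
    ypmm <- years[post[which(catches[post] == pmm)[1]]]
  }
  last_year <- max(years)
  out <- character(length(years))
  for (i in seq_along(years)) {
    y <- years[i]; ct <- catches[i]
    if (ct > mx * 0.5) { out[i] <- "B"; next }
    a <- (ymax == last_year) ||
      (y < ymax && ct <= mx * 0.5) ||
      (has_post && y > ypmm && pmm < mx * 0.1 && ct > mx * 0.1 && ct < mx * 0.5)
    if (a) { out[i] <- "A"; next }
    if (y > ymax && (ct < mx * 0.1 || (ct > mx * 0.1 && ct < mx * 0.5))) {
      out[i] <- "C"; next
    }
    out[i] <- "unassigned"
  }
  out
}

# A hand-built 3-region strip mosaic (west|middle|east), each its own
# country: the Ecuador|Peru|Chile analogue. 12 x 4 cells at 0.5 degrees.
make_strip_world <- function(widths = c(4, 4, 4), names_ = c("E", "P", "C"),
                             rows = 4) {
  res <- 0.5
  bbox <- c(0, 0, sum(widths) * res, rows * res)
  grid <- build_grid(bbox, res)
  brks <- cumsum(c(0, widths)) * res
  geoms <- list(); rows <- list()
  for (i in seq_along(widths)) {
    x0 <- brks[i]; x1 <- brks[i + 1]
    ring <- rbind(c(x0, 0), c(x1, 0), c(x1, bbox[4]), c(x0, bbox[4]), c(x0, 0))
    geoms[[names_[i]]] <- list(list(ring))
    rows[[i]] <- data.frame(region_id = names_[i],
                            country_id = paste0("cty_", names_[i]))
  }
  regions <- eez_regions(do.call(rbind, rows), geoms)
  assignment <- assign_cells(grid, regions)
  graph <- build_neighbor_graph(regions)
  list(bbox = bbox, res = res, grid = grid, regions = regions,
       assignment = assignment, graph = graph)
}

# Wrap a cell-id vector as a consensus_range-like object.
as_range <- function(species_id, cells) {
  structure(list(species_id = species_id, cells = cells, support = NULL),
            class = "consensus_range")
}
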