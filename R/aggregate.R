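# Aggregation of site GVIs to street segments and to blocks.
#
# Blocks are the contiguous areas left when class-dependent street buffers
# are removed from the study area. Delineation is performed on a fine
# raster: cells within a segment's buffer half-width are street space, the
# remaining free cells are labeled into connected components (4-neighbor,
# run-based union-find), and components touching the study-area boundary
# are discarded -- they are not "confined by streets". Block area is cell
# count x cell area; boundary polygons come from marching squares.

#' Segment-level GVI statistics
#'
#' @param sites_gvi Site tibble carrying `segment_id` and `gvi` (e.g. the
#'   `sites` element of [gvi_table()]).
#' @param streets Street table providing segment lengths.
#' @param sample Use sample (n-1) instead of population sd.
#' @return Tibble: `segment_id`, `n_sites`, `gvi_mean`, `gvi_sd`,
#'   `length_m`, `sites_per_km`, `category` (of the mean).
#' @export
aggregate_segments <- function(sites_gvi, streets, sample = FALSE) {
  streets <- check_streets(streets)
  out <- sites_gvi %>%
    group_by(.data$segment_id) %>%
    summarise(n_sites = dplyr::n(), gvi_mean = mean(.data$gvi),
              gvi_sd = pop_sd(.data$gvi, sample = sample), .groups = "drop") %>%
    left_join(streets %>% select("segment_id", "length_m"), by = "segment_id") %>%
    mutate(sites_per_km = .data$n_sites / (.data$length_m / 1000),
           category = classify_gvi(.data$gvi_mean))
  out
}

#' Class-dependent street buffer half-widths
#'
#' Street space width varies with street type; half-widths span
#' `[min_width, max_width]` meters, linearly from the highest road class
#' (class 1, widest) to the lowest (narrowest). Override per class by
#' passing a named vector straight to [delineate_blocks()].
#'
#' @param classes Integer road classes present in the network.
#' @param min_width,max_width Half-width bounds in meters (defaults 2, 30).
#' @return Named numeric vector: class -> half-width (m).
#' @export
buffer_scheme <- function(classes, min_width = 2, max_width = 30) {
  cls <- sort(unique(as.integer(classes)))
  w <- if (length(cls) == 1L) max_width else
    seq(max_width, min_width, length.out = length(cls))
  setNames(w, cls)
}

#' Delineate blocks by subtracting street buffers from the study area
#'
#' @param streets Street table in projected meters.
#' @param scheme Named numeric vector class -> buffer half-width (m), or a
#'   single number applied to every class. Widths must cover all classes
#'   present.
#' @param area Optional [study_area()]; defaults to the street bounding box
#'   padded by the widest buffer.
#' @param resolution Raster cell size in meters. Default: fine enough for
#'   ~2000 cells across the extent, never coarser than 4 m nor finer than
#'   0.25 m.
#' @return Block tibble: `block_id`, `area_ha`, `centroid_x`, `centroid_y`,
#'   `n_cells`, `boundary` (list of closed ring matrices),
#'   `boundary_cells` (list of boundary cell-center coordinates, used for
#'   nearest-block assignment). The raster itself travels along as the
#'   `grid` attribute.
#' @export
#' @examples
#' loop <- streets(
#'   c("s", "e", "n", "w"), 3L,
#'   list(cbind(x = c(0, 200), y = c(0, 0)), cbind(x = c(200, 200), y = c(0, 200)),
#'        cbind(x = c(200, 0), y = c(200, 200)), cbind(x = c(0, 0), y = c(200, 0)))
#' )
#' delineate_blocks(loop, scheme = 5, resolution = 0.25)$area_ha  # 3.61
delineate_blocks <- function(streets, scheme, area = NULL, resolution = NULL) {
  streets <- check_streets(streets)
  if (nrow(streets) > 0) check_projected(streets)

  if (nrow(streets) == 0) {
    warn("empty street network: the whole study area is one block")
    if (is.null(area)) abort("an empty network needs an explicit study area")
    th <- seq(0, 2 * pi, length.out = 181)
    ring <- cbind(x = area$center[1] + area$radius_m * cos(th),
                  y = area$center[2] + area$radius_m * sin(th))
    return(tibble(block_id = 1L, area_ha = pi * area$radius_m^2 / 1e4,
                  centroid_x = area$center[1], centroid_y = area$center[2],
                  n_cells = NA_integer_, boundary = list(ring),
                  boundary_cells = list(ring)))
  }

  if (length(scheme) == 1L && is.null(names(scheme))) {
    scheme <- setNames(rep(scheme, length(unique(streets$road_class))),
                       sort(unique(streets$road_class)))
  }
  missing_cls <- setdiff(unique(streets$road_class), as.integer(names(scheme)))
  if (length(missing_cls) > 0) {
    abort(sprintf("buffer scheme misses road classes: %s",
                  paste(missing_cls, collapse = ", ")))
  }
  wmax <- max(scheme)

  allm <- do.call(rbind, streets$geometry)
  if (is.null(area)) {
    xr <- range(allm[, 1]) + c(-1, 1) * (wmax + 2)
    yr <- range(allm[, 2]) + c(-1, 1) * (wmax + 2)
  } else {
    xr <- area$center[1] + c(-1, 1) * area$radius_m
    yr <- area$center[2] + c(-1, 1) * area$radius_m
  }
  extent <- max(diff(xr), diff(yr))
  if (is.null(resolution)) {
    resolution <- min(4, max(0.25, extent / 2000))
  }
  res <- resolution
  # snap origin to the resolution grid so axis-aligned geometry rasters cleanly
  x0 <- floor(xr[1] / res) * res
  y0 <- floor(yr[1] / res) * res
  nx <- ceiling((xr[2] - x0) / res) + 1L
  ny <- ceiling((yr[2] - y0) / res) + 1L
  xc <- x0 + (seq_len(nx) - 0.5) * res
  yc <- y0 + (seq_len(ny) - 0.5) * res

  street_mask <- matrix(FALSE, nrow = ny, ncol = nx)
  for (i in seq_len(nrow(streets))) {
    w <- scheme[[as.character(streets$road_class[i])]]
    m <- streets$geometry[[i]]
    for (e in seq_len(nrow(m) - 1L)) {
      a <- m[e, ]; b <- m[e + 1L, ]
      ci <- which(xc >= min(a[1], b[1]) - w - res & xc <= max(a[1], b[1]) + w + res)
      ri <- which(yc >= min(a[2], b[2]) - w - res & yc <= max(a[2], b[2]) + w + res)
      if (length(ci) == 0 || length(ri) == 0) next
      px <- rep(xc[ci], each = length(ri))
      py <- rep(yc[ri], times = length(ci))
      d <- point_segment_distance(px, py, a[1], a[2], b[1], b[2])
      hit <- matrix(d <= w, nrow = length(ri))
      street_mask[ri, ci] <- street_mask[ri, ci] | hit
    }
  }

  inside <- matrix(TRUE, nrow = ny, ncol = nx)
  if (!is.null(area)) {
    dx2 <- (xc - area$center[1])^2
    dy2 <- (yc - area$center[2])^2
    inside <- outer(dy2, dx2, `+`) <= area$radius_m^2
  }
  free <- !street_mask & inside
  lab <- label_components(free)

  # components in contact with the study-area boundary are not blocks
  edge_labels <- unique(c(
    lab[1, ], lab[ny, ], lab[, 1], lab[, nx],
    lab[cbind(which(touches_outside(free, inside), arr.ind = TRUE))]
  ))
  edge_labels <- setdiff(edge_labels, 0L)
  keep <- setdiff(sort(unique(as.vector(lab))), c(0L, edge_labels))
  if (length(keep) == 0) {
    warn("street buffers cover the study area: zero blocks delineated")
    return(tibble(block_id = integer(), area_ha = numeric(),
                  centroid_x = numeric(), centroid_y = numeric(),
                  n_cells = integer(), boundary = list(),
                  boundary_cells = list()))
  }

  bnd_mask <- component_boundaries(lab)
  blocks <- purrr::map_dfr(seq_along(keep), function(k) {
    lk <- keep[k]
    cells <- which(lab == lk, arr.ind = TRUE)
    bcells <- which(lab == lk & bnd_mask, arr.ind = TRUE)
    ring <- trace_component_ring(lab, lk, xc, yc)
    tibble(block_id = k,
           area_ha = nrow(cells) * res^2 / 1e4,
           centroid_x = mean(xc[cells[, 2]]),
           centroid_y = mean(yc[cells[, 1]]),
           n_cells = nrow(cells),
           boundary = list(ring),
           boundary_cells = list(cbind(x = xc[bcells[, 2]], y = yc[bcells[, 1]])))
  })
  attr(blocks, "grid") <- list(x0 = x0, y0 = y0, res = res,
                               labels = lab, keep = keep)
  blocks
}

# Run-based 4-connected component labeling via union-find.
label_components <- function(free) {
  ny <- nrow(free); nx <- ncol(free)
  parent <- integer(0)
  uf_find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  uf_union <- function(a, b) {
    ra <- uf_find(a); rb <- uf_find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  run_id <- matrix(0L, nrow = ny, ncol = nx)  # per-cell run index
  prev_runs <- NULL  # tibble-ish: list(start, end, id) for previous column
  for (j in seq_len(nx)) {
    col <- free[, j]
    if (!any(col)) { prev_runs <- NULL; next }
    r <- rle(col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values)
    ids <- integer(length(sel))
    for (s in seq_along(sel)) {
      parent[length(parent) + 1L] <- length(parent) + 1L
      ids[s] <- length(parent)
      run_id[starts[sel[s]]:ends[sel[s]], j] <- ids[s]
    }
    if (!is.null(prev_runs)) {
      for (s in seq_along(sel)) {
        a <- starts[sel[s]]; b <- ends[sel[s]]
        ov <- which(prev_runs$start <= b & prev_runs$end >= a)
        for (o in ov) uf_union(ids[s], prev_runs$id[o])
      }
    }
    prev_runs <- list(start = starts[sel], end = ends[sel], id = ids)
  }
  if (length(parent) == 0) return(matrix(0L, ny, nx))
  roots <- vapply(seq_along(parent), uf_find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  lab <- matrix(0L, ny, nx)
  nz <- run_id != 0L
  lab[nz] <- relabel[run_id[nz]]
  lab
}

# TRUE for free cells 4-adjacent to a cell outside the study area.
touches_outside <- function(free, inside) {
  out <- !inside
  ny <- nrow(free); nx <- ncol(free)
  nb <- matrix(FALSE, ny, nx)
  nb[-1, ] <- nb[-1, ] | out[-ny, ]
  nb[-ny, ] <- nb[-ny, ] | out[-1, ]
  nb[, -1] <- nb[, -1] | out[, -nx]
  nb[, -nx] <- nb[, -nx] | out[, -1]
  free & nb
}

# TRUE where a labeled cell has a 4-neighbor with a different label.
component_boundaries <- function(lab) {
  ny <- nrow(lab); nx <- ncol(lab)
  diffn <- matrix(FALSE, ny, nx)
  diffn[-1, ] <- diffn[-1, ] | (lab[-1, ] != lab[-ny, ])
  diffn[-ny, ] <- diffn[-ny, ] | (lab[-ny, ] != lab[-1, ])
  diffn[, -1] <- diffn[, -1] | (lab[, -1] != lab[, -nx])
  diffn[, -nx] <- diffn[, -nx] | (lab[, -nx] != lab[, -1])
  diffn[1, ] <- diffn[ny, ] <- TRUE
  diffn[, 1] <- TRUE; diffn[, nx] <- TRUE
  diffn & lab != 0L
}

# Outer boundary ring of one component (marching squares; largest ring).
trace_component_ring <- function(lab, lk, xc, yc) {
  z <- (lab == lk) * 1
  cl <- grDevices::contourLines(x = xc, y = yc, z = t(z), levels = 0.5)
  if (length(cl) == 0) {
    cells <- which(lab == lk, arr.ind = TRUE)
    return(cbind(x = range(xc[cells[, 2]])[c(1, 2, 2, 1, 1)],
                 y = range(yc[cells[, 1]])[c(1, 1, 2, 2, 1)]))
  }
  areas <- vapply(cl, function(cc) ring_area(cbind(cc$x, cc$y)), numeric(1))
  best <- cl[[which.max(areas)]]
  ring <- cbind(x = best$x, y = best$y)
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

#' Assign GVI sites to their nearest block
#'
#' Every site is assigned to exactly one block: the block at minimum
#' Euclidean distance (0 when the site falls inside a block; sites on
#' streets normally fall in the street space and are assigned to the
#' closest block boundary). Exact ties go to the smallest `block_id`.
#'
#' @param sites_gvi Site tibble with `x`, `y`, `gvi`.
#' @param blocks Block table from [delineate_blocks()].
#' @return The block table with `n_sites`, `gvi_mean`, `gvi_sd` and
#'   `category` added (blocks with no sites carry `NA`); the per-site
#'   assignment is available via [block_assignments()].
#' @export
assign_sites_to_blocks <- function(sites_gvi, blocks) {
  if (nrow(blocks) == 0) abort("no blocks to assign sites to")
  grid <- attr(blocks, "grid")
  nb <- nrow(blocks)
  ns <- nrow(sites_gvi)
  assigned <- integer(ns)
  for (i in seq_len(ns)) {
    p <- c(sites_gvi$x[i], sites_gvi$y[i])
    d <- vapply(seq_len(nb), function(b) {
      if (!is.null(grid)) {
        ci <- floor((p[1] - grid$x0) / grid$res) + 1L
        ri <- floor((p[2] - grid$y0) / grid$res) + 1L
        if (ri >= 1 && ri <= nrow(grid$labels) && ci >= 1 &&
            ci <= ncol(grid$labels) &&
            grid$labels[ri, ci] == grid$keep[blocks$block_id[b]]) {
          return(0)
        }
      }
      bc <- blocks$boundary_cells[[b]]
      min(sqrt((bc[, 1] - p[1])^2 + (bc[, 2] - p[2])^2))
    }, numeric(1))
    assigned[i] <- blocks$block_id[which.min(d)]  # first minimum = lowest id
  }
  asg <- tibble(site_id = sites_gvi$site_id, block_id = assigned,
                gvi = sites_gvi$gvi)
  stats <- asg %>%
    group_by(.data$block_id) %>%
    summarise(n_sites = dplyr::n(), gvi_mean = mean(.data$gvi),
              gvi_sd = pop_sd(.data$gvi), .groups = "drop")
  out <- blocks %>% left_join(stats, by = "block_id")
  out$n_sites[is.na(out$n_sites)] <- 0L
  out$category <- factor(NA, levels = levels(classify_gvi(0)))
  has <- !is.na(out$gvi_mean)
  out$category[has] <- classify_gvi(out$gvi_mean[has])
  out$sites_per_ha <- out$n_sites / out$area_ha
  attr(out, "grid") <- grid
  attr(out, "assignments") <- asg
  out
}

#' @rdname assign_sites_to_blocks
#' @export
block_assignments <- function(blocks) attr(blocks, "assignments")

#' Apply the location-density filters to segments and blocks
#'
#' Units with too few sample locations give unstable GVI means and are
#' dropped before analysis: street segments need more than
#' `min_sites_per_km` locations per km, and blocks must exceed
#' `min_area_ha` hectares with more than `min_sites_per_ha` locations per
#' hectare. Both density cuts are strict inequalities.
#'
#' @param segment_stats From [aggregate_segments()].
#' @param blocks From [assign_sites_to_blocks()].
#' @param min_sites_per_km Segment density threshold (default 13, the mean
#'   density over all segments in the reference analysis).
#' @param min_area_ha,min_sites_per_ha Block thresholds (defaults 1 and 1).
#' @return List with filtered `segments` and `blocks`; dropped counts are
#'   messaged.
#' @export
filter_units <- function(segment_stats, blocks, min_sites_per_km = 13,
                         min_area_ha = 1, min_sites_per_ha = 1) {
  keep_seg <- segment_stats$sites_per_km > min_sites_per_km
  keep_blk <- blocks$area_ha > min_area_ha &
    blocks$sites_per_ha > min_sites_per_ha
  inform(sprintf("filter_units: kept %d/%d segments, %d/%d blocks",
                 sum(keep_seg), length(keep_seg),
                 sum(keep_blk), length(keep_blk)))
  list(segments = segment_stats[keep_seg, ], blocks = blocks[keep_blk, ])
}

#' Plot delineated blocks colored by GVI category
#'
#' @param blocks Block table (after [assign_sites_to_blocks()] for colors).
#' @return A ggplot.
#' @export
plot_blocks <- function(blocks) {
  df <- purrr::map_dfr(seq_len(nrow(blocks)), function(i) {
    ring <- blocks$boundary[[i]]
    tibble(block_id = blocks$block_id[i],
           category = if ("category" %in% names(blocks))
             as.character(blocks$category[i]) else NA_character_,
           x = ring[, 1], y = ring[, 2])
  })
  ggplot(df, aes(.data$x, .data$y, group = .data$block_id,
                 fill = .data$category)) +
    geom_polygon(color = "grey30", linewidth = 0.2) +
    coord_equal() +
    scale_fill_manual(values = c(not_green = "#d9d9d9",
                                 somewhat_green = "#a1d99b",
                                 green = "#41ab5d", very_green = "#006d2c"),
                      na.value = "white") +
    theme_minimal() +
    labs(x = "x (m)", y = "y (m)", fill = "GVI")
}
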