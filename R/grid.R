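# Synthetic street networks: regular grids with the defects real centerline
# datasets carry -- dual carriageways (divided roads digitized as parallel
# line pairs), dangling stubs, and pseudo-nodes splitting continuous streets.

#' Specify a synthetic street grid
#'
#' @param grid_rows,grid_cols Number of node rows/columns (>= 2 each).
#' @param spacing Node spacing in meters.
#' @param dual_carriageway_fraction Fraction of grid streets replaced by a
#'   parallel same-class line pair (divided-road emulation).
#' @param carriageway_offset Separation between the two lines of a dual pair,
#'   meters; must be < `spacing / 2`.
#' @param dangle_count Number of short degree-1 stub segments to attach.
#' @param dangle_length Stub length, meters (default 40, well under the usual
#'   100 m dangle-removal threshold).
#' @param pseudo_node_count Number of streets split in two at an interior
#'   degree-2 node.
#' @param road_class Either a single integer class for every street or
#'   `"random"` to draw classes 2-5 per street.
#' @param seed Integer RNG seed.
#' @return A `gv_network_spec` list.
#' @export
network_spec <- function(grid_rows = 4L, grid_cols = 4L, spacing = 200,
                         dual_carriageway_fraction = 0,
                         carriageway_offset = 10,
                         dangle_count = 0L, dangle_length = 40,
                         pseudo_node_count = 0L,
                         road_class = 3L, seed = 1L) {
  if (grid_rows < 2 || grid_cols < 2) {
    abort("degenerate grid: grid_rows and grid_cols must both be >= 2")
  }
  stopifnot_scalar_num(spacing, "spacing", 1e-6, Inf)
  stopifnot_scalar_num(dual_carriageway_fraction, "dual_carriageway_fraction", 0, 1)
  if (carriageway_offset >= spacing / 2) {
    abort("`carriageway_offset` must be smaller than spacing / 2")
  }
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         spacing = spacing,
         dual_carriageway_fraction = dual_carriageway_fraction,
         carriageway_offset = carriageway_offset,
         dangle_count = as.integer(dangle_count),
         dangle_length = dangle_length,
         pseudo_node_count = as.integer(pseudo_node_count),
         road_class = road_class, seed = as.integer(seed)),
    class = "gv_network_spec")
}

#' Generate a synthetic street grid
#'
#' A `grid_rows` x `grid_cols` lattice of nodes yields
#' `grid_rows * (grid_cols - 1) + grid_cols * (grid_rows - 1)` streets.
#' Selected streets become dual carriageways (two parallel lines offset by
#' half the carriageway separation on each side); others are split by a
#' pseudo-node; dangling stubs are attached diagonally at random nodes.
#'
#' @param spec A [network_spec()].
#' @return A street table (see [streets()]); dual members carry ids
#'   `<id>/a`, `<id>/b`, pseudo-split halves `<id>#1`, `<id>#2`, dangles
#'   `dangle<k>`.
#' @export
#' @examples
#' nrow(make_street_grid(network_spec(3, 3, spacing = 200)))  # 12 streets
make_street_grid <- function(spec) {
  stopifnot(inherits(spec, "gv_network_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  s <- spec$spacing
  edges <- list()
  for (r in seq_len(spec$grid_rows)) {
    for (c in seq_len(spec$grid_cols - 1L)) {
      edges[[length(edges) + 1L]] <- list(
        id = sprintf("h_%d_%d", r, c),
        geom = cbind(x = c((c - 1) * s, c * s), y = c((r - 1) * s, (r - 1) * s)))
    }
  }
  for (c in seq_len(spec$grid_cols)) {
    for (r in seq_len(spec$grid_rows - 1L)) {
      edges[[length(edges) + 1L]] <- list(
        id = sprintf("v_%d_%d", r, c),
        geom = cbind(x = c((c - 1) * s, (c - 1) * s), y = c((r - 1) * s, r * s)))
    }
  }
  n_edge <- length(edges)
  classes <- if (identical(spec$road_class, "random")) {
    sample(2:5, n_edge, replace = TRUE)
  } else rep(as.integer(spec$road_class), n_edge)

  n_dual <- round(spec$dual_carriageway_fraction * n_edge)
  dual_idx <- if (n_dual > 0) sort(sample.int(n_edge, n_dual)) else integer()
  split_pool <- setdiff(seq_len(n_edge), dual_idx)
  if (spec$pseudo_node_count > length(split_pool)) {
    abort("not enough single-line streets to host the requested pseudo-nodes")
  }
  split_idx <- if (spec$pseudo_node_count > 0) {
    sort(sample(split_pool, spec$pseudo_node_count))
  } else integer()

  ids <- character(); geoms <- list(); cls <- integer()
  add <- function(id, geom, class) {
    ids[[length(ids) + 1L]] <<- id
    geoms[[length(geoms) + 1L]] <<- geom
    cls[[length(cls) + 1L]] <<- class
  }
  for (i in seq_len(n_edge)) {
    g <- edges[[i]]$geom
    id <- edges[[i]]$id
    if (i %in% dual_idx) {
      d <- g[2, ] - g[1, ]
      d <- d / sqrt(sum(d^2))
      nvec <- c(-d[2], d[1]) * spec$carriageway_offset / 2
      add(paste0(id, "/a"), sweep(g, 2, nvec, `+`), classes[i])
      add(paste0(id, "/b"), sweep(g, 2, nvec, `-`), classes[i])
    } else if (i %in% split_idx) {
      t <- runif(1, 0.35, 0.65)
      mid <- g[1, ] + t * (g[2, ] - g[1, ])
      add(paste0(id, "#1"), rbind(g[1, ], mid), classes[i])
      add(paste0(id, "#2"), rbind(mid, g[2, ]), classes[i])
    } else {
      add(id, g, classes[i])
    }
  }
  if (spec$dangle_count > 0) {
    nodes <- tidyr::expand_grid(r = seq_len(spec$grid_rows),
                                c = seq_len(spec$grid_cols))
    pick <- nodes[sample.int(nrow(nodes), spec$dangle_count, replace = FALSE), ]
    for (k in seq_len(nrow(pick))) {
      x0 <- (pick$c[k] - 1) * s; y0 <- (pick$r[k] - 1) * s
      dl <- spec$dangle_length / sqrt(2)
      add(sprintf("dangle%d", k),
          cbind(x = c(x0, x0 + dl), y = c(y0, y0 + dl)),
          if (identical(spec$road_class, "random")) 5L else as.integer(spec$road_class))
    }
  }
  streets(ids, cls, geoms)
}
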