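# Street-network simplification: merge divided roads, drop unsuitable
# classes, enforce topology (no dangles / no pseudo-nodes), clip to the
# study area. All functions take and return the street table of [streets()].

#' Define a circular study area
#'
#' @param center `c(x, y)` in projected meters (typically the projected city
#'   center, i.e. `c(0, 0)` under the local azimuthal-equidistant CRS).
#' @param radius_m Radius in meters; the default 3000 m disc around a city
#'   center is the conventional downtown proxy.
#' @return A `gv_study_area` list.
#' @export
study_area <- function(center = c(0, 0), radius_m = 3000) {
  stopifnot_scalar_num(radius_m, "radius_m", 1e-9, Inf)
  structure(list(center = as.numeric(center), radius_m = radius_m),
            class = "gv_study_area")
}

#' Merge divided roads into single centerlines
#'
#' Candidate pairs are segments of the same road class that are generally
#' parallel (principal directions within `max_angle` degrees) and mutually
#' within `merge_distance` (symmetric Hausdorff distance, and not
#' coincident). Matched pairs are replaced by the midline: each vertex of
#' the more densely vertexed member is averaged with its perpendicular foot
#' point on the partner. Pairing is greedy by increasing Hausdorff distance;
#' each segment merges at most once; unmatched segments pass through.
#'
#' @param streets Street table in projected meters.
#' @param merge_distance Maximum separation of a divided pair, meters.
#' @param max_angle "Generally parallel" tolerance, degrees (default 15).
#' @return Street table with each merged pair replaced by one centerline
#'   (id `<a>+<b>`, class preserved).
#' @export
merge_divided_roads <- function(streets, merge_distance, max_angle = 15) {
  streets <- check_streets(streets)
  check_projected(streets)
  stopifnot_scalar_num(merge_distance, "merge_distance", 1e-9, Inf)
  n <- nrow(streets)
  if (n < 2) return(streets)

  dirs <- vapply(streets$geometry, polyline_direction, numeric(1))
  # bounding boxes for cheap candidate rejection
  bbs <- t(vapply(streets$geometry, function(m)
    c(min(m[, 1]), min(m[, 2]), max(m[, 1]), max(m[, 2])), numeric(4)))
  cand <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (streets$road_class[i] != streets$road_class[j]) next
      if (direction_diff(dirs[i], dirs[j]) > max_angle) next
      if (bbs[j, 1] - bbs[i, 3] > merge_distance ||
          bbs[i, 1] - bbs[j, 3] > merge_distance ||
          bbs[j, 2] - bbs[i, 4] > merge_distance ||
          bbs[i, 2] - bbs[j, 4] > merge_distance) next
      hd <- hausdorff_distance(streets$geometry[[i]], streets$geometry[[j]])
      if (hd > 1e-9 && hd <= merge_distance) {
        cand[[length(cand) + 1L]] <- c(i, j, hd)
      }
    }
  }
  if (length(cand) == 0) return(streets)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 3]), , drop = FALSE]

  used <- rep(FALSE, n)
  keep_id <- character(); keep_cls <- integer(); keep_geom <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    a <- streets$geometry[[i]]; b <- streets$geometry[[j]]
    ref <- if (nrow(a) >= nrow(b)) a else b
    oth <- if (nrow(a) >= nrow(b)) b else a
    mid <- t(vapply(seq_len(nrow(ref)), function(v) {
      (ref[v, ] + closest_point_on_polyline(ref[v, ], oth)$point) / 2
    }, numeric(2)))
    colnames(mid) <- c("x", "y")
    keep_id <- c(keep_id, paste0(streets$segment_id[i], "+", streets$segment_id[j]))
    keep_cls <- c(keep_cls, streets$road_class[i])
    keep_geom <- c(keep_geom, list(mid))
  }
  merged <- streets(keep_id, keep_cls, keep_geom)
  dplyr::bind_rows(streets[!used, ], merged)
}

#' Remove unsuitable street classes (and flagged bridges)
#'
#' Street-level photographs taken on highways or bridges do not depict
#' walkable street space; segments of excluded classes, and segments whose
#' bridge flag is set, are dropped.
#'
#' @param streets Street table.
#' @param excluded_classes Integer vector of road classes to remove.
#' @param drop_bridges Also drop rows with `bridge == TRUE` (default TRUE;
#'   when the dataset has no bridge attribute nothing extra is removed).
#' @return Filtered street table; the number of removals is messaged.
#' @export
remove_unsuitable <- function(streets, excluded_classes = 1L,
                              drop_bridges = TRUE) {
  streets <- check_streets(streets)
  drop <- streets$road_class %in% excluded_classes
  if (drop_bridges) drop <- drop | streets$bridge
  out <- streets[!drop, ]
  inform(sprintf("remove_unsuitable: dropped %d of %d segments",
                 sum(drop), nrow(streets)))
  if (nrow(out) == 0 && nrow(streets) > 0) {
    warn("all street segments were excluded; downstream stages get an empty network")
  }
  out
}

#' Enforce network topology: no dangles, no pseudo-nodes
#'
#' Degree-1 stub segments shorter than `dangle_threshold` are removed
#' (iteratively, so chains of stubs unwind). Degree-2 nodes joining two
#' same-class segments whose directions deflect by at most `collinear_angle`
#' are dissolved by concatenating the segments, preserving total length.
#' Crossing streets are left un-split (the "must not intersect" rule keeps
#' whole streets as units).
#'
#' @param streets Street table in projected meters.
#' @param dangle_threshold Maximum length of a stub to delete, meters
#'   (default 100).
#' @param collinear_angle Maximum deflection (degrees) for dissolving a
#'   degree-2 node; 90-degree grid corners are never dissolved at the
#'   default 45.
#' @return Cleaned street table. Idempotent on a clean network.
#' @export
enforce_topology <- function(streets, dangle_threshold = 100,
                             collinear_angle = 45) {
  streets <- check_streets(streets)
  check_projected(streets)
  # Pseudo-nodes are dissolved before dangle removal (a continuous street
  # split by a pseudo-node must not be mistaken for two short stubs); the
  # two passes repeat until the network is stable, since removing a stub at
  # a three-way node leaves a new degree-2 node behind.
  repeat {
    n_before <- nrow(streets)
    len_before <- if (n_before > 0) sum(streets$length_m) else 0
    streets <- dissolve_pseudo_nodes(streets, collinear_angle)
    streets <- remove_dangles(streets, dangle_threshold)
    if (nrow(streets) == n_before &&
        isTRUE(all.equal(sum(streets$length_m), len_before))) break
    if (nrow(streets) == 0) break
  }
  streets
}

remove_dangles <- function(streets, dangle_threshold) {
  repeat {
    if (nrow(streets) == 0) return(streets)
    nd <- street_nodes(streets)
    deg <- setNames(nd$nodes$degree, nd$nodes$node_id)
    ends <- nd$ends
    seg_nodes <- split(ends$node_id, ends$segment_id)
    is_dangle <- vapply(streets$segment_id, function(id) {
      nids <- seg_nodes[[id]]
      any(deg[as.character(nids)] == 1L)
    }, logical(1)) & streets$length_m < dangle_threshold
    if (!any(is_dangle)) return(streets)
    streets <- streets[!is_dangle, ]
  }
}

# Dissolve near-collinear degree-2 nodes of same-class segment pairs.
dissolve_pseudo_nodes <- function(streets, collinear_angle) {
  if (nrow(streets) == 0) return(streets)
  repeat {
    nd <- street_nodes(streets)
    two <- nd$nodes$node_id[nd$nodes$degree == 2L]
    merged_any <- FALSE
    for (node in two) {
      rows <- which(nd$ends$node_id == node)
      if (length(rows) != 2L) next
      sa <- nd$ends$segment_id[rows[1]]; ea <- nd$ends$end[rows[1]]
      sb <- nd$ends$segment_id[rows[2]]; eb <- nd$ends$end[rows[2]]
      if (sa == sb) next  # closed loop onto itself
      ia <- match(sa, streets$segment_id); ib <- match(sb, streets$segment_id)
      if (streets$road_class[ia] != streets$road_class[ib]) next
      ga <- streets$geometry[[ia]]; gb <- streets$geometry[[ib]]
      if (ea == 1L) ga <- ga[rev(seq_len(nrow(ga))), , drop = FALSE]
      if (eb == 2L) gb <- gb[rev(seq_len(nrow(gb))), , drop = FALSE]
      # ga now ends at the node, gb starts at it
      din <- ga[nrow(ga), ] - ga[nrow(ga) - 1L, ]
      dout <- gb[2L, ] - gb[1L, ]
      defl <- direction_diff(azimuth_deg(din[1], din[2]) %% 180,
                             azimuth_deg(dout[1], dout[2]) %% 180)
      if (defl > collinear_angle) next
      geom <- rbind(ga, gb[-1L, , drop = FALSE])
      streets$geometry[[ia]] <- geom
      streets$length_m[ia] <- polyline_length(geom)
      streets <- streets[-ib, ]
      merged_any <- TRUE
      break  # node table is stale; rebuild
    }
    if (!merged_any) break
  }
  streets
}

#' Clip a street network to a circular study area
#'
#' Segment parts outside the disc are discarded; edges crossing the boundary
#' are cut at the circle. A segment crossing in and out repeatedly yields
#' one clipped part per inside run (ids suffixed `@1`, `@2`, ...).
#'
#' @param streets Street table in projected meters.
#' @param area A [study_area()].
#' @return Clipped street table.
#' @export
clip_to_study_area <- function(streets, area) {
  streets <- check_streets(streets)
  check_projected(streets)
  stopifnot(inherits(area, "gv_study_area"))
  ctr <- area$center; r <- area$radius_m
  out_id <- character(); out_cls <- integer(); out_geom <- list()

  for (i in seq_len(nrow(streets))) {
    m <- streets$geometry[[i]]
    pieces <- clip_polyline_to_disc(m, ctr, r)
    if (length(pieces) == 0) next
    for (j in seq_along(pieces)) {
      id <- if (length(pieces) == 1L) streets$segment_id[i] else
        paste0(streets$segment_id[i], "@", j)
      out_id <- c(out_id, id)
      out_cls <- c(out_cls, streets$road_class[i])
      out_geom <- c(out_geom, pieces[j])
    }
  }
  streets(out_id, out_cls, out_geom)
}

# Split one polyline into its maximal sub-polylines inside the disc.
clip_polyline_to_disc <- function(m, ctr, r) {
  inside <- sqrt((m[, 1] - ctr[1])^2 + (m[, 2] - ctr[2])^2) <= r + 1e-9
  pieces <- list()
  current <- NULL
  push_pt <- function(p) {
    if (is.null(current)) current <<- matrix(p, ncol = 2)
    else if (sum((current[nrow(current), ] - p)^2) > 1e-18)
      current <<- rbind(current, p)
  }
  flush <- function() {
    if (!is.null(current) && nrow(current) >= 2) {
      dimnames(current) <<- list(NULL, c("x", "y"))
      pieces[[length(pieces) + 1L]] <<- current
    }
    current <<- NULL
  }
  for (e in seq_len(nrow(m) - 1L)) {
    a <- m[e, ]; b <- m[e + 1L, ]
    ts <- segment_circle_params(a, b, ctr, r)
    if (inside[e]) push_pt(a)
    for (t in ts) push_pt(a + t * (b - a))
    if (!inside[e + 1L]) flush()
  }
  if (inside[nrow(m)]) push_pt(m[nrow(m), ])
  flush()
  pieces
}

# Parameters t in (0,1) where segment a-b crosses the circle.
segment_circle_params <- function(a, b, ctr, r) {
  d <- b - a; f <- a - ctr
  A <- sum(d^2); B <- 2 * sum(f * d); C <- sum(f^2) - r^2
  disc <- B^2 - 4 * A * C
  if (A == 0 || disc <= 0) return(numeric())
  sq <- sqrt(disc)
  ts <- c((-B - sq) / (2 * A), (-B + sq) / (2 * A))
  sort(ts[ts > 1e-12 & ts < 1 - 1e-12])
}
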