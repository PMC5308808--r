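# Street network container: a tibble with one row per street segment.

#' Build a street-segment table
#'
#' The package-wide representation of a street network is an ordinary tibble
#' with one row per segment and a list-column of coordinate matrices, so it
#' pipes through dplyr verbs like any other data frame.
#'
#' @param segment_id Character vector of unique segment ids.
#' @param road_class Integer road class, 1 = highest (e.g. highway) to
#'   n = lowest (e.g. lane).
#' @param geometry List of n x 2 numeric matrices (projected x, y in meters),
#'   each with at least two vertices.
#' @param bridge Logical bridge flag (optional attribute-based removal).
#' @return A tibble with columns `segment_id`, `road_class`, `bridge`,
#'   `geometry` and derived `length_m`.
#' @export
#' @examples
#' streets(
#'   "a", 3L,
#'   list(cbind(x = c(0, 100), y = c(0, 0)))
#' )
streets <- function(segment_id, road_class, geometry, bridge = FALSE) {
  stopifnot(length(segment_id) == length(geometry))
  geometry <- lapply(geometry, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y")
    if (nrow(m) < 2L) abort("every segment needs at least 2 vertices")
    m
  })
  if (anyDuplicated(segment_id)) abort("segment ids must be unique")
  tibble(
    segment_id = as.character(segment_id),
    road_class = as.integer(road_class),
    bridge = as.logical(bridge),
    geometry = geometry,
    length_m = vapply(geometry, polyline_length, numeric(1))
  )
}

check_streets <- function(x, arg = "streets") {
  need <- c("segment_id", "road_class", "geometry")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort(sprintf("`%s` must be a street table with columns %s.",
                  arg, paste(need, collapse = ", ")))
  }
  if (!"length_m" %in% names(x)) {
    x$length_m <- vapply(x$geometry, polyline_length, numeric(1))
  }
  if (!"bridge" %in% names(x)) x$bridge <- FALSE
  as_tibble(x)
}

# Error if the network is in raw lon/lat degrees.
check_projected <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  allm <- do.call(rbind, x$geometry)
  if (looks_geographic(allm)) {
    abort(paste0(
      "Street coordinates look geographic (lon/lat degrees). Metric ",
      "operations need projected meters; reproject first, e.g. with ",
      "`project_streets(streets, center = c(lon, lat))`."))
  }
  invisible(x)
}

#' Reproject a lon/lat street table to local planar meters
#'
#' @param streets Street table with geographic coordinates.
#' @param center `c(lon, lat)` projection center (typically the city center).
#' @return The street table with projected geometry and recomputed lengths.
#' @export
project_streets <- function(streets, center) {
  streets <- check_streets(streets)
  streets$geometry <- lapply(streets$geometry, function(m) {
    p <- aeqd_project(m[, 1], m[, 2], center)
    colnames(p) <- c("x", "y")
    p
  })
  streets$length_m <- vapply(streets$geometry, polyline_length, numeric(1))
  streets
}

#' Total network length in meters
#' @param streets Street table.
#' @return A single number (meters).
#' @export
network_length <- function(streets) {
  streets <- check_streets(streets)
  sum(streets$length_m)
}

# Node table: endpoints snapped to `tol` meters, with node degree.
# Returns list(nodes = tibble(node_id, x, y, degree),
#              ends  = tibble(segment_id, end (1|2), node_id)).
street_nodes <- function(streets, tol = 0.01) {
  ends <- purrr::map_dfr(seq_len(nrow(streets)), function(i) {
    m <- streets$geometry[[i]]
    tibble(
      segment_id = streets$segment_id[i],
      end = c(1L, 2L),
      x = c(m[1, 1], m[nrow(m), 1]),
      y = c(m[1, 2], m[nrow(m), 2])
    )
  })
  key <- paste(round(ends$x / tol), round(ends$y / tol))
  ends$node_id <- match(key, unique(key))
  nodes <- ends %>%
    group_by(.data$node_id) %>%
    summarise(x = .data$x[1], y = .data$y[1], degree = dplyr::n(),
              .groups = "drop")
  list(nodes = nodes, ends = ends)
}
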