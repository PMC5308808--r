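# GeoJSON and CSV input/output.
#
# GeoJSON handling is written directly on jsonlite: line layers in or out,
# point and polygon layers out. Coordinates are written as stored; pass
# `center` to convert between planar meters and lon/lat.

#' Read a GeoJSON line layer as a street table
#'
#' Reads `LineString`/`MultiLineString` features. Attribute names are mapped
#' via arguments so datasets with differing schemas (class field, bridge
#' flag) can be ingested. If the file is in lon/lat and `center` is given the
#' geometry is projected to local azimuthal-equidistant meters.
#'
#' @param path GeoJSON file.
#' @param id_field,class_field,bridge_field Property names holding the
#'   segment id, ordinal road class and (optionally) a bridge flag.
#' @param center Optional `c(lon, lat)` projection center.
#' @param default_class Road class used when `class_field` is absent.
#' @return A street table (see [streets()]).
#' @export
read_streets_geojson <- function(path, id_field = "id", class_field = "class",
                                 bridge_field = NULL, center = NULL,
                                 default_class = 3L) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features %||% list()
  rows <- list()
  k <- 0L
  for (f in feats) {
    geom <- f$geometry
    if (is.null(geom)) next
    parts <- switch(geom$type,
      LineString = list(geom$coordinates),
      MultiLineString = geom$coordinates,
      NULL)
    if (is.null(parts)) next
    props <- f$properties %||% list()
    base_id <- as.character(props[[id_field]] %||% paste0("f", k + 1L))
    cls <- as.integer(props[[class_field]] %||% default_class)
    brg <- if (!is.null(bridge_field)) isTRUE(as.logical(props[[bridge_field]])) else FALSE
    for (j in seq_along(parts)) {
      m <- do.call(rbind, lapply(parts[[j]], function(p) c(p[[1]], p[[2]])))
      k <- k + 1L
      rows[[k]] <- list(
        segment_id = if (length(parts) > 1L) paste0(base_id, ".", j) else base_id,
        road_class = cls, bridge = brg, geometry = m)
    }
  }
  if (length(rows) == 0) {
    return(streets(character(), integer(), list()))
  }
  st <- streets(
    segment_id = vapply(rows, `[[`, character(1), "segment_id"),
    road_class = vapply(rows, `[[`, integer(1), "road_class"),
    geometry = lapply(rows, `[[`, "geometry"),
    bridge = vapply(rows, `[[`, logical(1), "bridge")
  )
  if (!is.null(center) && nrow(st) > 0 &&
      looks_geographic(do.call(rbind, st$geometry))) {
    st <- project_streets(st, center)
  }
  st
}

#' Write a street table as GeoJSON
#'
#' @param streets Street table.
#' @param path Output file.
#' @param center Optional `c(lon, lat)`; when given, planar coordinates are
#'   inverse-projected so the file holds standard lon/lat GeoJSON.
#' @param extra_properties Optional data frame of additional per-segment
#'   properties (matched by `segment_id`).
#' @return `path`, invisibly.
#' @export
write_streets_geojson <- function(streets, path, center = NULL,
                                  extra_properties = NULL) {
  streets <- check_streets(streets)
  feats <- purrr::map(seq_len(nrow(streets)), function(i) {
    m <- streets$geometry[[i]]
    if (!is.null(center)) m <- aeqd_inverse(m[, 1], m[, 2], center)
    props <- list(id = streets$segment_id[i],
                  class = streets$road_class[i],
                  length_m = round(streets$length_m[i], 3))
    if (!is.null(extra_properties)) {
      j <- match(streets$segment_id[i], extra_properties$segment_id)
      if (!is.na(j)) {
        extras <- as.list(extra_properties[j, setdiff(names(extra_properties),
                                                      "segment_id")])
        props <- c(props, extras)
      }
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "LineString",
                         coordinates = unname(apply(m, 1, as.list, simplify = FALSE))))
  })
  write_geojson_collection(feats, path)
}

#' Write point features (e.g. sample sites) as GeoJSON
#'
#' @param df Data frame with `x`, `y` columns; remaining columns become
#'   feature properties.
#' @param path Output file.
#' @param center Optional `c(lon, lat)` for inverse projection.
#' @return `path`, invisibly.
#' @export
write_points_geojson <- function(df, path, center = NULL) {
  cols <- setdiff(names(df), c("x", "y"))
  feats <- purrr::map(seq_len(nrow(df)), function(i) {
    xy <- c(df$x[i], df$y[i])
    if (!is.null(center)) xy <- drop(aeqd_inverse(xy[1], xy[2], center))
    list(type = "Feature",
         properties = lapply(as.list(df[i, cols, drop = FALSE]), unname),
         geometry = list(type = "Point", coordinates = as.list(unname(xy))))
  })
  write_geojson_collection(feats, path)
}

#' Write block polygons as GeoJSON
#'
#' @param blocks Block table from [delineate_blocks()] (optionally with GVI
#'   columns from [assign_sites_to_blocks()]).
#' @param path Output file.
#' @param center Optional `c(lon, lat)` for inverse projection.
#' @return `path`, invisibly.
#' @export
write_blocks_geojson <- function(blocks, path, center = NULL) {
  feats <- purrr::map(seq_len(nrow(blocks)), function(i) {
    ring <- blocks$boundary[[i]]
    if (!is.null(center)) ring <- aeqd_inverse(ring[, 1], ring[, 2], center)
    props <- list(block_id = blocks$block_id[i],
                  area_ha = blocks$area_ha[i])
    for (nm in intersect(c("n_sites", "gvi_mean", "category"), names(blocks))) {
      props[[nm]] <- if (is.factor(blocks[[nm]])) as.character(blocks[[nm]][i]) else blocks[[nm]][i]
    }
    list(type = "Feature", properties = props,
         geometry = list(
           type = "Polygon",
           coordinates = list(unname(apply(ring, 1, as.list, simplify = FALSE)))))
  })
  write_geojson_collection(feats, path)
}

write_geojson_collection <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Write sample sites as CSV
#'
#' Columns: site_id, segment_id, lon, lat, x, y, chainage, azimuth, h_front,
#' h_back, h_left, h_right. lon/lat are filled when `center` is supplied.
#'
#' @param sites Site table from [sample_points()].
#' @param path Output file.
#' @param center Optional `c(lon, lat)` projection center.
#' @return `path`, invisibly.
#' @export
write_sites_csv <- function(sites, path, center = NULL) {
  ll <- if (!is.null(center)) {
    aeqd_inverse(sites$x, sites$y, center)
  } else {
    cbind(lon = rep(NA_real_, nrow(sites)), lat = NA_real_)
  }
  out <- tibble(
    site_id = sites$site_id, segment_id = sites$segment_id,
    lon = ll[, 1], lat = ll[, 2], x = sites$x, y = sites$y,
    chainage = sites$chainage, azimuth = sites$azimuth,
    h_front = sites$h_front, h_back = sites$h_back,
    h_left = sites$h_left, h_right = sites$h_right
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a sample-site CSV written by [write_sites_csv()]
#' @param path CSV file.
#' @return A site tibble.
#' @export
read_sites_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
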