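# Sample-site placement along processed street segments.

#' Place sample sites every `interval` meters along each segment
#'
#' Sites sit at chainages 0, interval, 2*interval, ... so every segment gets
#' `floor(length / interval) + 1` sites, guaranteeing at least one site (the
#' segment start) even on short segments. The forward azimuth at a site is
#' the direction of the polyline edge containing its chainage; at a vertex
#' the following edge is used, and the last edge for the terminal site. The
#' four view headings are front = azimuth, back = azimuth + 180,
#' left = azimuth + 90 and right = azimuth + 270 (mod 360).
#'
#' @param streets Street table in projected meters.
#' @param interval Sampling interval in meters (default 50).
#' @return A site tibble: `site_id`, `segment_id`, `x`, `y`, `chainage`,
#'   `azimuth`, `h_front`, `h_back`, `h_left`, `h_right`.
#' @export
#' @examples
#' st <- streets("a", 3L, list(cbind(x = c(0, 200), y = c(0, 0))))
#' sample_points(st)  # 5 sites at chainage 0, 50, 100, 150, 200
sample_points <- function(streets, interval = 50) {
  streets <- check_streets(streets)
  check_projected(streets)
  if (!is.numeric(interval) || length(interval) != 1L || interval <= 0) {
    abort("`interval` must be a single positive number of meters")
  }
  purrr::map_dfr(seq_len(nrow(streets)), function(i) {
    m <- streets$geometry[[i]]
    L <- streets$length_m[i]
    k <- floor(L / interval + 1e-9)
    ch <- (0:k) * interval
    ch[ch > L] <- L
    pts <- lapply(ch, function(c0) interpolate_along(m, c0))
    az <- vapply(pts, function(p) {
      e <- p$edge
      d <- m[e + 1L, ] - m[e, ]
      azimuth_deg(d[1], d[2])
    }, numeric(1))
    tibble(
      site_id = sprintf("%s:%d", streets$segment_id[i], seq_along(ch)),
      segment_id = streets$segment_id[i],
      x = vapply(pts, function(p) p$point[1], numeric(1)),
      y = vapply(pts, function(p) p$point[2], numeric(1)),
      chainage = ch,
      azimuth = az,
      h_front = az,
      h_back = (az + 180) %% 360,
      h_left = (az + 90) %% 360,
      h_right = (az + 270) %% 360
    )
  })
}

#' Run the full street preprocessing chain
#'
#' Convenience wrapper: class/bridge removal, divided-road merging, topology
#' enforcement, and study-area clipping, in that order.
#'
#' @param streets Raw street table in projected meters.
#' @param area Optional [study_area()]; skipped when `NULL`.
#' @param excluded_classes Road classes to remove (default highway class 1).
#' @param merge_distance Divided-road merge distance, meters.
#' @param dangle_threshold See [enforce_topology()].
#' @return Processed street table.
#' @export
preprocess_streets <- function(streets, area = NULL, excluded_classes = 1L,
                               merge_distance = 30, dangle_threshold = 100) {
  streets <- remove_unsuitable(streets, excluded_classes)
  streets <- merge_divided_roads(streets, merge_distance)
  streets <- enforce_topology(streets, dangle_threshold)
  if (!is.null(area)) streets <- clip_to_study_area(streets, area)
  streets
}

#' Plot a street network with optional sample sites
#'
#' @param streets Street table.
#' @param sites Optional site tibble from [sample_points()].
#' @return A ggplot.
#' @export
plot_network <- function(streets, sites = NULL) {
  streets <- check_streets(streets)
  seg_df <- purrr::map_dfr(seq_len(nrow(streets)), function(i) {
    m <- streets$geometry[[i]]
    tibble(segment_id = streets$segment_id[i],
           road_class = streets$road_class[i], x = m[, 1], y = m[, 2])
  })
  p <- ggplot(seg_df, aes(.data$x, .data$y, group = .data$segment_id)) +
    geom_path(aes(color = factor(.data$road_class))) +
    coord_equal() +
    labs(color = "road class", x = "x (m)", y = "y (m)") +
    theme_minimal()
  if (!is.null(sites)) {
    p <- p + geom_point(data = sites, aes(.data$x, .data$y),
                        inherit.aes = FALSE, size = 0.6)
  }
  p
}
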