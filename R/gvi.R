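# Green View Index from hue composition.
#
# An image's pixels are converted RGB -> HSV; the hue channel (degrees,
# 0-360) is binned at 1-degree resolution into a 360-bin distribution that
# sums to 1. The GVI of the image is the summed fraction of bins inside the
# green hue range, 60-180 degrees by default. Achromatic pixels (saturation
# 0: gray, white, black) have hue 0 by convention and so never count as
# green. No saturation or value gating is applied by default -- the index is
# a pure hue classification, with dark-green vehicles and signs counted just
# like foliage; optional thresholds are exposed for sensitivity analysis.

#' Define a green hue range
#'
#' Half-open degree interval `[lo, hi)`: bin `hi` is excluded, so adjacent
#' ranges partition cleanly. Bounds must be whole degrees, which keeps
#' histogram-based and per-pixel GVI computation exactly equal.
#'
#' @param lo,hi Degree bounds, `0 <= lo < hi <= 360`; defaults 60 and 180.
#' @return A `gv_green_range`.
#' @export
green_range <- function(lo = 60, hi = 180) {
  if (lo != round(lo) || hi != round(hi)) {
    abort("green range bounds must be whole degrees")
  }
  if (!(lo >= 0 && lo < hi && hi <= 360)) {
    abort("need 0 <= lo < hi <= 360")
  }
  structure(list(lo = as.integer(lo), hi = as.integer(hi)),
            class = "gv_green_range")
}

# Per-pixel hue in degrees [0, 360). Input: h x w x 3 array, 0-255 or [0,1].
pixel_hues <- function(image, min_saturation = 0, min_value = 0) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] < 3L) {
    abort("`image` must be a height x width x 3 RGB array")
  }
  if (d[1] * d[2] == 0L) abort("zero-pixel image")
  mx <- max(image)
  scale <- if (mx <= 1) 1 else 255
  r <- as.vector(image[, , 1]) / scale
  g <- as.vector(image[, , 2]) / scale
  b <- as.vector(image[, , 3]) / scale
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 1)
  hue <- hsv[1, ] * 360
  hue[hue >= 360] <- 0
  if (min_saturation > 0) hue[hsv[2, ] < min_saturation] <- NA_real_
  if (min_value > 0) hue[hsv[3, ] < min_value] <- NA_real_
  hue
}

#' Hue histogram of an image
#'
#' 360 one-degree bins; bin `d` covers hue in `[d, d+1)`. Fractions sum to 1
#' over counted pixels.
#'
#' @param image RGB array (height x width x 3), 8-bit 0-255 or [0, 1].
#' @param min_saturation,min_value Optional gates: pixels below either
#'   threshold are excluded from the histogram (defaults 0 = pure hue
#'   analysis, the standard behavior).
#' @return A `gv_hue_histogram`: list with `fractions` (length 360, named
#'   "0".."359") and `counted_pixels`.
#' @export
#' @examples
#' img <- array(0L, dim = c(2, 2, 3)); img[, , 2] <- 255L  # pure green
#' hue_histogram(img)$fractions[["120"]]
hue_histogram <- function(image, min_saturation = 0, min_value = 0) {
  hue <- pixel_hues(image, min_saturation, min_value)
  hue <- hue[!is.na(hue)]
  counts <- tabulate(pmin(floor(hue), 359) + 1L, nbins = 360L)
  n <- length(hue)
  if (n == 0L) abort("no pixels left to count after gating")
  structure(list(fractions = setNames(counts / n, as.character(0:359)),
                 counts = setNames(as.integer(counts), as.character(0:359)),
                 counted_pixels = n),
            class = "gv_hue_histogram")
}

#' @export
print.gv_hue_histogram <- function(x, ...) {
  cat(sprintf("<hue histogram: %d pixels, green [60,180) share %.4f>\n",
              x$counted_pixels, sum(x$fractions[61:180])))
  invisible(x)
}

#' @method as_tibble gv_hue_histogram
#' @export
as_tibble.gv_hue_histogram <- function(x, ...) {
  tibble(hue = 0:359, fraction = unname(x$fractions))
}

#' Green View Index of one image
#'
#' `picture_gvi()` sums the hue-histogram fractions falling inside the green
#' range; `image_gvi()` is the convenience composition
#' `picture_gvi(hue_histogram(image), range)`.
#'
#' @param hist A [hue_histogram()].
#' @param range A [green_range()] (default 60-180 degrees).
#' @return GVI in [0, 1].
#' @export
picture_gvi <- function(hist, range = green_range()) {
  stopifnot(inherits(hist, "gv_hue_histogram"), inherits(range, "gv_green_range"))
  bins <- seq.int(range$lo, range$hi - 1L)
  # summing integer counts first keeps this bit-identical to a per-pixel count
  unname(sum(hist$counts[bins + 1L])) / hist$counted_pixels
}

#' @rdname picture_gvi
#' @param image RGB array.
#' @param ... Passed to [hue_histogram()].
#' @export
image_gvi <- function(image, range = green_range(), ...) {
  picture_gvi(hue_histogram(image, ...), range)
}

#' Site GVI: average over the directional views
#'
#' A street site generally has four views (front, back, left, right); when
#' the provider returned fewer, the mean is taken over what exists, down to
#' `min_images`. A site with no images is an error -- exclude it upstream.
#'
#' @param per_heading_gvis Numeric vector of per-image GVIs (length 1-4).
#' @param min_images Minimum number of views required (default 1).
#' @return The arithmetic mean.
#' @export
site_gvi <- function(per_heading_gvis, min_images = 1L) {
  g <- per_heading_gvis[!is.na(per_heading_gvis)]
  if (length(g) < min_images || length(g) == 0L) {
    abort("site has fewer images than `min_images`; exclude it upstream")
  }
  if (length(g) > 4L) abort("a site has at most 4 directional views")
  mean(g)
}

#' Classify GVI into the four greenness categories
#'
#' Thresholds: not green (<= 0.2), somewhat green (0.2, 0.4], green
#' (0.4, 0.5], very green (> 0.5).
#'
#' @param g Numeric vector of GVI values in [0, 1].
#' @return Factor with levels `not_green`, `somewhat_green`, `green`,
#'   `very_green`.
#' @export
#' @examples
#' classify_gvi(c(0.1, 0.2, 0.45, 0.9))
classify_gvi <- function(g) {
  if (any(is.na(g)) || any(g < 0 | g > 1)) {
    abort("GVI values must lie in [0, 1]")
  }
  cut(g, breaks = c(-Inf, 0.2, 0.4, 0.5, Inf),
      labels = c("not_green", "somewhat_green", "green", "very_green"),
      right = TRUE)
}

#' Calibrate the green hue range against ground truth
#'
#' Given images with known true green fractions (e.g. manually interpreted
#' photographs, or synthetic scenes with exact masks), computes each
#' candidate range's Pearson correlation between its hue-range GVI and the
#' truth, and returns the maximizing range. This reproduces the procedure
#' that selects 60-180 degrees as the green range.
#'
#' @param images List of RGB arrays.
#' @param truth Numeric vector of ground-truth green fractions (same
#'   length); must not be constant.
#' @param candidate_ranges List of [green_range()]s (>= 2).
#' @return A list: `range` (winner), `correlation`, and `table` (tibble of
#'   all candidates with their correlations).
#' @export
calibrate_green_range <- function(images, truth, candidate_ranges) {
  if (length(images) < 10) abort("need at least 10 image/truth pairs")
  if (length(images) != length(truth)) abort("images and truth lengths differ")
  if (length(candidate_ranges) < 2) abort("need at least 2 candidate ranges")
  if (sd(truth) == 0) abort("constant truth vector: correlation undefined")
  hists <- lapply(images, hue_histogram)
  tab <- purrr::map_dfr(candidate_ranges, function(r) {
    gvis <- vapply(hists, picture_gvi, numeric(1), range = r)
    tibble(lo = r$lo, hi = r$hi,
           correlation = if (sd(gvis) == 0) -Inf else cor(gvis, truth))
  })
  best <- which.max(tab$correlation)
  list(range = green_range(tab$lo[best], tab$hi[best]),
       correlation = tab$correlation[best],
       table = tab)
}

#' Compute per-image and per-site GVI for an inventory
#'
#' Reads each `status == "ok"` image of a crawl inventory, appends `gvi` and
#' `counted_pixels` columns, and summarizes per-site GVI (mean over the
#' available views) with its four-level category.
#'
#' @param inventory Inventory tibble from [build_inventory()].
#' @param image_dir Directory holding the inventory's image files.
#' @param range A [green_range()].
#' @param min_images Minimum views for a site to be scored.
#' @return A list: `images` (inventory with per-image GVI) and `sites`
#'   (tibble `site_id`, `segment_id`, `x`, `y`, `n_images`, `gvi`,
#'   `category`); sites with fewer than `min_images` views are excluded.
#' @export
gvi_table <- function(inventory, image_dir, range = green_range(),
                      min_images = 1L) {
  inv <- as_tibble(inventory)
  inv$gvi <- NA_real_
  inv$counted_pixels <- NA_integer_
  ok <- which(inv$status == "ok" & !is.na(inv$image_file))
  for (i in ok) {
    img <- read_image(file.path(image_dir, inv$image_file[i]))
    h <- hue_histogram(img)
    inv$gvi[i] <- picture_gvi(h, range)
    inv$counted_pixels[i] <- h$counted_pixels
  }
  sites <- inv %>%
    filter(!is.na(.data$gvi)) %>%
    group_by(.data$site_id, .data$segment_id) %>%
    summarise(x = .data$x[1], y = .data$y[1], n_images = dplyr::n(),
              gvi = mean(.data$gvi), .groups = "drop") %>%
    filter(.data$n_images >= min_images)
  sites$category <- classify_gvi(sites$gvi)
  list(images = inv, sites = sites)
}

#' Plot a hue histogram in its own colors
#'
#' @param object A `gv_hue_histogram`.
#' @param range Green range to shade.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gv_hue_histogram
#' @export
autoplot.gv_hue_histogram <- function(object, range = green_range(), ...) {
  df <- as_tibble(object)
  df$col <- grDevices::hsv(df$hue / 360, 0.8, 0.85)
  ggplot(df, aes(.data$hue, .data$fraction)) +
    annotate("rect", xmin = range$lo, xmax = range$hi, ymin = -Inf,
             ymax = Inf, alpha = 0.08, fill = "green4") +
    geom_col(aes(fill = .data$col), width = 1) +
    scale_fill_identity() +
    labs(x = "hue (degrees)", y = "fraction of pixels") +
    theme_minimal()
}
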