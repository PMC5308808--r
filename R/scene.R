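# Synthetic street scenes with known per-pixel vegetation ground truth.
#
# A scene is an 8-bit RGB image in which "vegetation" pixels are drawn as
# coherent blobs (canopy-like patches) with hues inside a green band, and the
# remaining pixels carry non-green clutter (sky-, building- and road-like
# hues plus achromatic gray). The emitted mask marks exactly the vegetation
# pixels, so hue-based GVI estimates can be benchmarked against per-pixel
# truth without any downloaded imagery.

#' Specify a synthetic street scene
#'
#' @param width,height Image size in pixels; defaults mirror the 960 x 640
#'   frames delivered by street-view panorama APIs.
#' @param green_fraction Target fraction of vegetation pixels in `[0, 1]`.
#' @param green_hue_band Two-element degree range inside `[60, 180]` from
#'   which vegetation hues are drawn (default `c(90, 150)`, leafy greens).
#' @param clutter_bands Data frame with columns `lo`, `hi`, `weight`: hue
#'   bands for chromatic non-vegetation pixels. Bands must lie entirely
#'   outside `[60, 180]`. Default: sky blues (195-255) and warm building
#'   tones (15-45).
#' @param gray_weight Relative weight of achromatic (saturation 0) clutter
#'   pixels such as road surface; hue of such pixels is 0 by convention.
#' @param illumination_jitter Log-normal sd of a multiplicative brightness
#'   perturbation applied to the HSV value channel of every pixel. Hue is
#'   never touched, so the vegetation mask stays exact under jitter.
#' @param seed Integer RNG seed; scenes are reproducible byte-for-byte.
#' @return A `gv_scene_spec` list.
#' @export
scene_spec <- function(width = 960L, height = 640L, green_fraction = 0.25,
                       green_hue_band = c(90, 150),
                       clutter_bands = default_clutter_bands(),
                       gray_weight = 0.25,
                       illumination_jitter = 0.15, seed = 1L) {
  stopifnot_scalar_num(green_fraction, "green_fraction", 0, 1)
  stopifnot_scalar_num(illumination_jitter, "illumination_jitter", 0, 2)
  stopifnot(width >= 8, height >= 8)
  if (length(green_hue_band) != 2 || green_hue_band[1] < 60 ||
      green_hue_band[2] > 180 || diff(green_hue_band) < 6) {
    abort("`green_hue_band` must be a range of width >= 6 inside [60, 180].")
  }
  cb <- as_tibble(clutter_bands)
  if (!all(c("lo", "hi", "weight") %in% names(cb))) {
    abort("`clutter_bands` needs columns lo, hi, weight.")
  }
  if (any(!(cb$hi <= 60 | cb$lo >= 180)) || any(cb$hi - cb$lo < 6)) {
    abort("clutter hue bands must be disjoint from [60, 180] and >= 6 deg wide.")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         green_fraction = green_fraction, green_hue_band = green_hue_band,
         clutter_bands = cb, gray_weight = gray_weight,
         illumination_jitter = illumination_jitter, seed = as.integer(seed)),
    class = "gv_scene_spec")
}

#' @rdname scene_spec
#' @export
default_clutter_bands <- function() {
  tibble(lo = c(195, 15), hi = c(255, 45), weight = c(0.45, 0.30))
}

# Hues are sampled this many degrees inside any band so that 8-bit RGB
# quantization (hue error < ~3 deg at the chroma floor below) can never move
# a pixel across a band edge.
HUE_MARGIN <- 4

#' Render a synthetic scene with its vegetation mask
#'
#' Vegetation pixels are laid out as random disk-shaped blobs until the
#' target pixel count is met exactly (the last blob is trimmed from its rim
#' inward), so `|mask fraction - green_fraction| < 1/(width x height)`.
#'
#' @param spec A [scene_spec()].
#' @return A `gv_scene`: list with `image` (height x width x 3 integer array,
#'   0-255), `mask` (height x width logical matrix, TRUE = vegetation),
#'   `green_fraction` (achieved mask fraction) and the `spec`.
#' @export
#' @examples
#' sc <- make_scene(scene_spec(width = 64, height = 48, green_fraction = 0.3,
#'                             seed = 7))
#' mean(sc$mask)
make_scene <- function(spec) {
  stopifnot(inherits(spec, "gv_scene_spec"))
  w <- spec$width; h <- spec$height; n <- w * h
  k <- round(spec$green_fraction * n)
  if (abs(k / n - spec$green_fraction) > 0.01) {
    abort(sprintf(
      "green_fraction %.4f unreachable with %d pixels; closest achievable is %.4f",
      spec$green_fraction, n, k / n))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  mask <- matrix(FALSE, nrow = h, ncol = w)
  count <- 0L
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)   # column index per cell
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)  # row index per cell
  while (count < k) {
    cx <- runif(1, 1, w); cy <- runif(1, 1, h)
    r <- runif(1, min(w, h) / 16, min(w, h) / 4)
    d2 <- (xs - cx)^2 + (ys - cy)^2
    newly <- which(d2 <= r^2 & !mask)
    if (length(newly) == 0) next
    if (count + length(newly) >= k) {
      need <- k - count
      newly <- newly[order(d2[newly])][seq_len(need)]
    }
    mask[newly] <- TRUE
    count <- count + length(newly)
  }

  hue <- numeric(n); sat <- numeric(n); val <- numeric(n)
  gi <- which(mask)
  if (length(gi) > 0) {
    gb <- spec$green_hue_band
    hue[gi] <- runif(length(gi), gb[1] + HUE_MARGIN, gb[2] - HUE_MARGIN)
    sat[gi] <- runif(length(gi), 0.5, 0.95)
    val[gi] <- runif(length(gi), 0.35, 0.9)
  }
  ci <- which(!mask)
  if (length(ci) > 0) {
    cb <- spec$clutter_bands
    wts <- c(cb$weight, spec$gray_weight)
    pick <- sample.int(length(wts), length(ci), replace = TRUE, prob = wts)
    for (b in seq_len(nrow(cb))) {
      sel <- ci[pick == b]
      hue[sel] <- runif(length(sel), cb$lo[b] + HUE_MARGIN, cb$hi[b] - HUE_MARGIN)
      sat[sel] <- runif(length(sel), 0.35, 0.9)
      val[sel] <- runif(length(sel), 0.3, 0.95)
    }
    gr <- ci[pick == length(wts)]
    hue[gr] <- 0
    sat[gr] <- 0
    val[gr] <- runif(length(gr), 0.15, 0.95)
  }
  if (spec$illumination_jitter > 0) {
    val <- val * exp(rnorm(n, 0, spec$illumination_jitter))
  }
  # Chroma floor: keeps 8-bit hue quantization error within HUE_MARGIN.
  val <- pmin(pmax(val, 0.25), 1)

  cols <- grDevices::hsv(hue / 360, sat, val)
  rgbm <- grDevices::col2rgb(cols)  # 3 x n, 0..255 integers
  img <- array(0L, dim = c(h, w, 3))
  img[, , 1] <- matrix(as.integer(rgbm[1, ]), nrow = h)
  img[, , 2] <- matrix(as.integer(rgbm[2, ]), nrow = h)
  img[, , 3] <- matrix(as.integer(rgbm[3, ]), nrow = h)

  structure(list(image = img, mask = mask, green_fraction = count / n,
                 spec = spec),
            class = "gv_scene")
}

# Save/restore the global RNG state so generators are pure given their seed.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a scene as PNG image plus sidecar mask
#'
#' The mask is a single-channel PNG with vegetation = 255, other = 0.
#'
#' @param scene A `gv_scene` from [make_scene()].
#' @param image_path,mask_path Output PNG paths (`mask_path = NULL` skips the
#'   mask).
#' @return `image_path`, invisibly.
#' @export
write_scene <- function(scene, image_path, mask_path = NULL) {
  png::writePNG(scene$image / 255, image_path)
  if (!is.null(mask_path)) {
    png::writePNG(matrix(as.numeric(scene$mask), nrow = nrow(scene$mask)),
                  mask_path)
  }
  invisible(image_path)
}

#' Read an 8-bit RGB image
#'
#' @param path PNG file.
#' @return height x width x 3 integer array with values 0-255.
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  img <- array(as.integer(round(a * 255)), dim = dim(a))
  img
}

#' @export
print.gv_scene <- function(x, ...) {
  cat(sprintf("<gv_scene %dx%d px, green fraction %.4f>\n",
              x$spec$width, x$spec$height, x$green_fraction))
  invisible(x)
}

#' Plot a synthetic scene
#'
#' @param object A `gv_scene`.
#' @param ... Unused.
#' @return A ggplot raster of the rendered image.
#' @method autoplot gv_scene
#' @export
autoplot.gv_scene <- function(object, ...) {
  img <- object$image
  h <- dim(img)[1]; w <- dim(img)[2]
  df <- tidyr::expand_grid(row = seq_len(h), col = seq_len(w))
  df$fill <- grDevices::rgb(img[, , 1], img[, , 2], img[, , 3],
                            maxColorValue = 255)
  ggplot(df, aes(x = .data$col, y = .data$row)) +
    geom_raster(aes(fill = .data$fill)) +
    scale_fill_identity() +
    scale_y_reverse() +
    coord_equal(expand = FALSE) +
    theme_void()
}
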