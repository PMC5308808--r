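# Shared fixtures, built in code.

# 200 x 200 m square street loop (centerlines), class 3.
square_loop <- function(side = 200) {
  streets(
    c("s", "e", "n", "w"), 3L,
    list(cbind(x = c(0, side), y = c(0, 0)),
         cbind(x = c(side, side), y = c(0, side)),
         cbind(x = c(side, 0), y = c(side, side)),
         cbind(x = c(0, 0), y = c(side, 0))))
}

# Brute-force per-pixel GVI: fraction of pixels with hue in [lo, hi).
pixel_gvi_oracle <- function(img, lo = 60, hi = 180) {
  hs <- grDevices::rgb2hsv(rbind(as.vector(img[, , 1]),
                                 as.vector(img[, , 2]),
                                 as.vector(img[, , 3])),
                           maxColorValue = 255)
  hue <- hs[1, ] * 360
  mean(hue >= lo & hue < hi)
}

# Small random 8-bit RGB array.
random_image <- function(w, h, seed) {
  set.seed(seed)
  array(sample(0:255, w * h * 3, replace = TRUE), dim = c(h, w, 3))
}

# Minimal site table for provider tests (one straight street, n sites).
toy_sites <- function(n = 10, spacing = 50) {
  tibble::tibble(
    site_id = sprintf("s%02d", seq_len(n)), segment_id = "seg1",
    x = (seq_len(n) - 1) * spacing, y = 0,
    chainage = (seq_len(n) - 1) * spacing, azimuth = 90,
    h_front = 90, h_back = 270, h_left = 180, h_right = 0)
}
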