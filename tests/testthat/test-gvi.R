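# Hue histograms, picture/site GVI, classification, calibration.

test_that("hue histograms put known colors in the right bins and normalize", {
  img <- array(0L, dim = c(4, 4, 3)); img[, , 2] <- 255L  # pure green
  h <- hue_histogram(img)
  expect_equal(unname(h$fractions[["120"]]), 1)
  expect_equal(sum(h$fractions), 1)

  half <- array(0L, dim = c(4, 4, 3))
  half[, 1:2, 1] <- 255L  # left half red
  half[, 3:4, 2] <- 255L  # right half green
  hh <- hue_histogram(half)
  expect_equal(unname(hh$fractions[["0"]]), 0.5)
  expect_equal(unname(hh$fractions[["120"]]), 0.5)

  gray <- array(128L, dim = c(4, 4, 3))  # achromatic -> hue 0 by convention
  expect_equal(unname(hue_histogram(gray)$fractions[["0"]]), 1)

  expect_error(hue_histogram(array(0L, dim = c(0, 4, 3))), "zero-pixel")

  # normalization property on random images
  for (s in 1:10) {
    expect_equal(sum(hue_histogram(random_image(16, 16, s))$fractions), 1,
                 tolerance = 1e-9)
  }
})

test_that("picture_gvi equals the per-pixel oracle exactly, for any integer range", {
  for (s in 1:25) {
    img <- random_image(24, 24, s)
    h <- hue_histogram(img)
    lo <- sample(0:300, 1); hi <- lo + sample(10:59, 1)
    expect_identical(picture_gvi(h, green_range(lo, hi)),
                     pixel_gvi_oracle(img, lo, hi))
    expect_identical(picture_gvi(h), pixel_gvi_oracle(img))
  }
})

test_that("GVI is additive over adjacent ranges, bounded, and hue-monotone", {
  for (s in 1:10) {
    img <- random_image(20, 20, s)
    h <- hue_histogram(img)
    g <- picture_gvi(h)
    expect_gte(g, 0); expect_lte(g, 1)
    expect_equal(g, picture_gvi(h, green_range(60, 120)) +
                   picture_gvi(h, green_range(120, 180)), tolerance = 1e-12)
  }
  # recoloring a non-green pixel to a green hue never decreases GVI
  img <- random_image(12, 12, 99)
  g0 <- image_gvi(img)
  hs <- grDevices::rgb2hsv(rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                                 as.vector(img[, , 3])), maxColorValue = 255)
  nongreen <- which(hs[1, ] * 360 < 60 | hs[1, ] * 360 >= 180)[1]
  idx <- arrayInd(nongreen, dim(img)[1:2])
  img[idx[1], idx[2], ] <- c(0L, 255L, 0L)
  expect_gte(image_gvi(img), g0)
})

test_that("site GVI averages the available views and rejects empty sites", {
  expect_equal(site_gvi(c(0.2, 0.4, 0.3, 0.3)), 0.3)
  expect_equal(site_gvi(0.42), 0.42)
  expect_error(site_gvi(numeric()), "fewer images")
  expect_error(site_gvi(c(0.1, NA), min_images = 2), "fewer images")
  expect_error(site_gvi(rep(0.2, 5)), "at most 4")
})

test_that("the four-category classification matches the threshold truth table", {
  truth <- tibble::tribble(
    ~g, ~label,
    0.00, "not_green",
    0.10, "not_green",
    0.20, "not_green",      # boundary: <= 0.2
    0.2000001, "somewhat_green",
    0.35, "somewhat_green",
    0.40, "somewhat_green", # boundary: (0.2, 0.4]
    0.45, "green",
    0.50, "green",          # boundary: (0.4, 0.5]
    0.5000001, "very_green",
    0.90, "very_green",
    1.00, "very_green")
  expect_equal(as.character(classify_gvi(truth$g)), truth$label)
  expect_error(classify_gvi(1.2), "0, 1")
  expect_error(classify_gvi(-0.1), "0, 1")
})

test_that("green-range calibration picks the range matching the vegetation hues", {
  scenes <- lapply(1:12, function(i)
    make_scene(scene_spec(48, 32, green_fraction = (i - 1) / 12,
                          green_hue_band = c(90, 150), seed = i)))
  imgs <- lapply(scenes, `[[`, "image")
  truth <- vapply(scenes, `[[`, numeric(1), "green_fraction")
  cal <- calibrate_green_range(imgs, truth,
                               list(green_range(60, 180), green_range(200, 280)))
  expect_equal(c(cal$range$lo, cal$range$hi), c(60L, 180L))
  expect_gt(cal$correlation, 0.99)
  # the rival range catches only sky clutter, which shrinks as vegetation
  # grows: strongly anti-correlated with the truth
  expect_lt(cal$table$correlation[cal$table$lo == 200], 0)

  expect_error(calibrate_green_range(imgs, rep(0.5, 12),
                                     list(green_range(), green_range(80, 160))),
               "constant truth")
  expect_error(calibrate_green_range(imgs[1:5], truth[1:5],
                                     list(green_range(), green_range(80, 160))),
               "at least 10")
})

test_that("gvi_table scores inventories and aggregates per site", {
  sites <- toy_sites(4)
  panos <- tibble::tibble(pano_id = paste0("p", 1:4), x = sites$x, y = sites$y)
  p <- mock_provider(panos, seed = 3)
  dir <- withr::local_tempdir()
  inv <- build_inventory(sites, p, image_dir = dir, width = 48, height = 32)
  res <- gvi_table(inv, dir)
  expect_equal(nrow(res$sites), 4)
  expect_true(all(res$sites$n_images == 4))
  expect_true(all(res$sites$gvi >= 0 & res$sites$gvi <= 1))
  # site gvi equals the mean of its four image gvis
  one <- res$images[res$images$site_id == "s01", ]
  expect_equal(res$sites$gvi[res$sites$site_id == "s01"], mean(one$gvi))
})
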