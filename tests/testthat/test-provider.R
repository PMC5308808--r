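# Provider interface: queries, nearest-pano lookup, mock determinism,
# quota, and inventory bookkeeping.

test_that("pano queries enforce the API parameter domains", {
  expect_error(pano_query(width = 2000, pano_id = "p"), "width")
  expect_error(pano_query(height = 700, pano_id = "p"), "height")
  expect_error(pano_query(pano_id = "p", pitch = 95), "pitch")
  expect_error(pano_query(), "exactly one")
  expect_error(pano_query(pano_id = "p", location = c(0, 0)), "exactly one")
  q <- pano_query(pano_id = "p", heading = 370)
  expect_equal(q$heading, 10)
})

test_that("find_pano returns the nearest panorama within the radius", {
  panos <- tibble::tibble(pano_id = c("near", "mid", "far"),
                          x = c(10, 30, 80), y = c(0, 0, 0))
  p <- mock_provider(panos)
  expect_equal(find_pano(p, 0, 0, 50)$pano_id, "near")
  expect_null(find_pano(p, 80 + 60, 0, 50))
  # exhaustive-distance oracle on random layouts
  set.seed(3)
  for (i in 1:10) {
    pts <- tibble::tibble(pano_id = sprintf("p%d", 1:20),
                          x = runif(20, 0, 500), y = runif(20, 0, 500))
    prov <- mock_provider(pts)
    qx <- runif(1, 0, 500); qy <- runif(1, 0, 500)
    d <- sqrt((pts$x - qx)^2 + (pts$y - qy)^2)
    hit <- find_pano(prov, qx, qy, 100)
    if (min(d) > 100) expect_null(hit)
    else expect_equal(hit$pano_id, pts$pano_id[which.min(d)])
  }
})

test_that("mock fetches honor size, are deterministic, and differ by heading", {
  panos <- tibble::tibble(pano_id = "p1", x = 0, y = 0)
  p <- mock_provider(panos, seed = 7)
  img1 <- fetch_image(p, pano_query(width = 96, height = 64, pano_id = "p1",
                                    heading = 0))
  expect_equal(dim(img1), c(64, 96, 3))
  img1b <- fetch_image(p, pano_query(width = 96, height = 64, pano_id = "p1",
                                     heading = 0))
  expect_identical(img1, img1b)
  img90 <- fetch_image(p, pano_query(width = 96, height = 64, pano_id = "p1",
                                     heading = 90))
  expect_false(identical(img1, img90))
})

test_that("the query counter is monotonic and the quota raises a typed error", {
  panos <- tibble::tibble(pano_id = "p1", x = 0, y = 0)
  p <- mock_provider(panos, quota = 3)
  q <- pano_query(width = 32, height = 24, pano_id = "p1")
  for (i in 1:3) {
    fetch_image(p, q)
    expect_equal(queries_used(p), i)
  }
  expect_error(fetch_image(p, q), class = "gv_quota_error")

  # persisted counter resumes across provider instances
  cf <- withr::local_tempfile()
  p1 <- mock_provider(panos, quota = 10, counter_file = cf)
  fetch_image(p1, q); fetch_image(p1, q)
  p2 <- mock_provider(panos, quota = 10, counter_file = cf)
  expect_equal(queries_used(p2), 2)
})

test_that("the inventory records every attempt exactly once", {
  sites <- toy_sites(10, spacing = 200)
  # panos near the first 7 sites only
  panos <- tibble::tibble(pano_id = paste0("p", 1:7),
                          x = sites$x[1:7] + 3, y = sites$y[1:7] - 2)
  p <- mock_provider(panos, seed = 1)
  dir <- withr::local_tempdir()
  inv <- build_inventory(sites, p, search_radius = 50, image_dir = dir,
                         width = 48, height = 32)
  expect_equal(sum(inv$status == "ok"), 28)
  expect_equal(sum(inv$status == "missing"), 3)
  expect_equal(nrow(inv), 31)
  # one row per attempted (site, heading)
  ok <- inv[inv$status == "ok", ]
  expect_false(any(duplicated(ok[, c("site_id", "heading_label")])))
  expect_true(all(table(ok$site_id) == 4))
  expect_true(all(file.exists(file.path(dir, ok$image_file))))

  empty <- build_inventory(sites[0, ], p)
  expect_equal(nrow(empty), 0)
})

test_that("the local provider serves a directory layout and errors typed", {
  root <- withr::local_tempdir()
  sc <- make_scene(scene_spec(48, 32, green_fraction = 0.4, seed = 2))
  dir.create(file.path(root, "panoA"))
  write_scene(sc, file.path(root, "panoA", "90.png"))
  utils::write.csv(data.frame(pano_id = "panoA", x = 5, y = 5),
                   file.path(root, "panos.csv"), row.names = FALSE)
  p <- local_provider(root)
  expect_equal(find_pano(p, 0, 0, 50)$pano_id, "panoA")
  img <- fetch_image(p, pano_query(pano_id = "panoA", heading = 90))
  expect_identical(img, sc$image)
  expect_error(fetch_image(p, pano_query(pano_id = "panoA", heading = 180)),
               class = "gv_provider_error")
})

test_that("the live provider composes the documented URL but is never called offline", {
  p <- live_provider("KEY-123", quota = 5)
  url <- greenview:::live_image_url(
    p, pano_query(width = 960, height = 640,
                  pano_id = "10011022120723095812200", heading = 90))
  expect_equal(url, paste0(
    "https://apis.map.qq.com/ws/streetview/v1/image",
    "?size=960x640&pano=10011022120723095812200&heading=90&pitch=0&key=KEY-123"))
  expect_error(live_provider(""), class = "gv_auth_error")
})
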