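# Segment statistics, block delineation, nearest-block assignment, filters.

test_that("segment statistics use closed-form mean and population sd", {
  st <- streets(c("a", "b"), 3L,
                list(cbind(x = c(0, 100), y = c(0, 0)),
                     cbind(x = c(0, 1000), y = c(100, 100))))
  sites <- tibble::tibble(
    site_id = c("a1", "a2", "b1", paste0("b", 2:13)),
    segment_id = c("a", "a", rep("b", 13)),
    x = 0, y = 0, gvi = c(0.1, 0.3, rep(0.25, 13)))
  seg <- aggregate_segments(sites, st)
  a <- seg[seg$segment_id == "a", ]
  expect_equal(a$gvi_mean, 0.2)
  expect_equal(a$gvi_sd, 0.1)      # population sd of {0.1, 0.3}
  b <- seg[seg$segment_id == "b", ]
  expect_equal(b$sites_per_km, 13) # 13 sites on 1 km
  expect_equal(b$gvi_sd, 0)

  single <- aggregate_segments(sites[1, ], st)
  expect_equal(single$gvi_sd, 0)
})

test_that("a buffered square loop leaves one interior block of closed-form area", {
  b <- delineate_blocks(square_loop(200), scheme = 5, resolution = 0.25)
  expect_equal(nrow(b), 1)
  expect_equal(b$area_ha, 3.61, tolerance = 1e-9)  # (200 - 2*5)^2 m2
  expect_equal(c(b$centroid_x, b$centroid_y), c(100, 100), tolerance = 0.2)
  # the traced boundary ring surrounds the block interior
  expect_true(greenview:::point_in_ring(100, 100, b$boundary[[1]]))
  expect_false(greenview:::point_in_ring(2, 2, b$boundary[[1]]))
})

test_that("grid networks yield the combinatorial number of interior blocks", {
  g <- make_street_grid(network_spec(3, 3, spacing = 200))
  b <- delineate_blocks(g, scheme = 5, resolution = 0.5)
  expect_equal(nrow(b), 4)
  expect_equal(b$area_ha, rep(3.61, 4), tolerance = 1e-9)
  g4 <- make_street_grid(network_spec(4, 4, spacing = 150))
  expect_equal(nrow(delineate_blocks(g4, scheme = 5, resolution = 0.5)), 9)
})

test_that("degenerate block configurations warn as contracted", {
  expect_warning(none <- delineate_blocks(square_loop(200), scheme = 120,
                                          resolution = 1), "zero blocks")
  expect_equal(nrow(none), 0)
  empty <- streets(character(), integer(), list())
  expect_warning(all_area <- delineate_blocks(empty, scheme = 5,
                                              area = study_area(c(0, 0), 500)),
                 "one block")
  expect_equal(all_area$area_ha, pi * 500^2 / 1e4)
})

test_that("sites go to their nearest block; ties break to the lower id", {
  g <- make_street_grid(network_spec(2, 3, spacing = 200))  # two blocks side by side
  b <- delineate_blocks(g, scheme = 5, resolution = 0.5)
  expect_equal(nrow(b), 2)
  # 4 sites clearly nearer block 1, 2 nearer block 2 (exhaustive distances)
  sites <- tibble::tibble(
    site_id = sprintf("s%d", 1:6),
    x = c(50, 90, 110, 60, 250, 320), y = c(0, 0, 200, 200, 0, 200),
    gvi = c(0.2, 0.2, 0.4, 0.4, 0.6, 0.8))
  ba <- assign_sites_to_blocks(sites, b)
  expect_equal(ba$n_sites, c(4L, 2L))
  expect_equal(ba$gvi_mean, c(0.3, 0.7))
  # a site exactly midway between the two blocks goes to block 1
  tie <- tibble::tibble(site_id = "t", x = 200, y = 100, gvi = 0.5)
  expect_equal(block_assignments(assign_sites_to_blocks(tie, b))$block_id, 1L)
  # a single block absorbs everything
  b1 <- delineate_blocks(square_loop(200), scheme = 5, resolution = 0.5)
  ba1 <- assign_sites_to_blocks(sites, b1)
  expect_equal(ba1$n_sites, 6L)
  expect_equal(ba1$gvi_mean, mean(sites$gvi))
})

test_that("assignments partition the sites and preserve the weighted mean", {
  set.seed(7)
  g <- make_street_grid(network_spec(3, 3, spacing = 200))
  b <- delineate_blocks(g, scheme = 5, resolution = 1)
  for (rep in 1:8) {
    n <- sample(10:60, 1)
    sites <- tibble::tibble(site_id = sprintf("s%d", seq_len(n)),
                            x = runif(n, -20, 420), y = runif(n, -20, 420),
                            gvi = runif(n))
    ba <- assign_sites_to_blocks(sites, b)
    expect_equal(sum(ba$n_sites), n)
    expect_equal(sum(ba$n_sites * ba$gvi_mean, na.rm = TRUE) / n,
                 mean(sites$gvi), tolerance = 1e-9)
  }
})

test_that("scaling coordinates scales areas quadratically and leaves GVI alone", {
  k <- 2
  base <- delineate_blocks(square_loop(200), scheme = 5, resolution = 0.25)
  scaled_net <- square_loop(200 * k)
  scaled <- delineate_blocks(scaled_net, scheme = 5 * k, resolution = 0.25 * k)
  expect_equal(scaled$area_ha, base$area_ha * k^2, tolerance = 1e-9)
  sites <- tibble::tibble(site_id = c("a", "b"), x = c(100, 50), y = c(0, 200),
                          gvi = c(0.3, 0.5))
  g1 <- assign_sites_to_blocks(sites, base)$gvi_mean
  sites2 <- sites; sites2$x <- sites2$x * k; sites2$y <- sites2$y * k
  g2 <- assign_sites_to_blocks(sites2, scaled)$gvi_mean
  expect_equal(g1, g2)
})

test_that("density filters apply the strict Table-style thresholds", {
  seg <- tibble::tibble(segment_id = c("a", "b", "c"),
                        n_sites = c(3L, 13L, 2L),
                        gvi_mean = 0.3, gvi_sd = 0,
                        length_m = c(148, 1000, 200),
                        sites_per_km = c(3 / 0.148, 13, 10))
  blk <- tibble::tibble(block_id = 1:3,
                        area_ha = c(0.5, 2, 2),
                        n_sites = c(10L, 2L, 5L),
                        gvi_mean = 0.3,
                        sites_per_ha = c(20, 1, 2.5))
  suppressMessages(kept <- filter_units(seg, blk))
  expect_equal(kept$segments$segment_id, "a")   # 20.3/km kept; 13 exactly dropped
  expect_equal(kept$blocks$block_id, 3L)        # 0.5 ha dropped; 1.0/ha dropped
})

test_that("buffer schemes span the class range with the widest class widest", {
  s <- buffer_scheme(c(1, 2, 3, 4, 5))
  expect_equal(unname(s[c("1", "5")]), c(30, 2))
  expect_true(all(diff(s) < 0))
  expect_true(all(s >= 2 & s <= 30))
  expect_error(delineate_blocks(square_loop(), scheme = c("2" = 5)),
               "misses road classes")
})
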