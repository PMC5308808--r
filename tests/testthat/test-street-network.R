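# Centerline preprocessing: merging, filtering, topology, clipping, sampling.

test_that("parallel same-class lines merge to the equidistant midline", {
  dual <- streets(c("a", "b"), 3L,
                  list(cbind(x = c(0, 100), y = c(0, 0)),
                       cbind(x = c(0, 100), y = c(20, 20))))
  m <- merge_divided_roads(dual, merge_distance = 30)
  expect_equal(nrow(m), 1)
  expect_equal(m$road_class, 3L)
  expect_true(all(m$geometry[[1]][, "y"] == 10))

  # crossing perpendicular streets are not "generally parallel"
  cross <- streets(c("a", "b"), 3L,
                   list(cbind(x = c(0, 100), y = c(50, 50)),
                        cbind(x = c(50, 50), y = c(0, 100))))
  expect_equal(nrow(merge_divided_roads(cross, 30)), 2)

  # different classes never merge
  mixed <- streets(c("a", "b"), c(2L, 3L),
                   list(cbind(x = c(0, 100), y = c(0, 0)),
                        cbind(x = c(0, 100), y = c(20, 20))))
  expect_equal(nrow(merge_divided_roads(mixed, 30)), 2)

  # beyond the merge distance nothing happens
  expect_equal(nrow(merge_divided_roads(dual, 10)), 2)
})

test_that("geographic input to metric operations demands reprojection", {
  ll <- streets("a", 3L, list(cbind(x = c(116.30, 116.31), y = c(39.98, 39.99))))
  expect_error(merge_divided_roads(ll, 30), "reproject")
  proj <- project_streets(ll, center = c(116.305, 39.985))
  expect_gt(proj$length_m, 1000)  # ~1.4 km in meters now
  expect_silent(check <- enforce_topology(proj))
})

test_that("class and bridge filtering drops exactly the unsuitable segments", {
  st <- streets(sprintf("s%d", 1:8), c(1L, 1L, 1L, 3L, 3L, 3L, 3L, 3L),
                replicate(8, cbind(x = c(0, 100), y = c(0, 0)), simplify = FALSE))
  expect_message(out <- remove_unsuitable(st, excluded_classes = 1L),
                 "dropped 3 of 8")
  expect_equal(nrow(out), 5)
  expect_message(expect_equal(nrow(remove_unsuitable(st, integer())), 8))
  expect_warning(expect_message(
    empty <- remove_unsuitable(st, c(1L, 3L))), "all street segments")
  expect_equal(nrow(empty), 0)
})

test_that("topology enforcement removes short dangles and dissolves pseudo-nodes", {
  g <- make_street_grid(network_spec(3, 3, spacing = 200, dangle_count = 2,
                                     pseudo_node_count = 1, seed = 2))
  before <- network_length(g)
  t <- enforce_topology(g, dangle_threshold = 100)
  nodes <- greenview:::street_nodes(t)$nodes
  expect_equal(sum(nodes$degree == 1), 0)          # dangles gone
  expect_false(any(grepl("^dangle", t$segment_id)))
  expect_equal(nrow(t), 12)                         # pseudo-split re-dissolved
  expect_equal(network_length(t),
               before - 2 * network_spec()$dangle_length, tolerance = 1e-6)

  # chain A-B-C with a pseudo-node at B collapses to one segment, length kept
  chain <- streets(c("ab", "bc"), 3L,
                   list(cbind(x = c(0, 60), y = c(0, 0)),
                        cbind(x = c(60, 150), y = c(0, 0))))
  d <- enforce_topology(chain)
  expect_equal(nrow(d), 1)
  expect_equal(d$length_m, 150)

  # clean grid: idempotent
  clean <- make_street_grid(network_spec(3, 3, spacing = 200))
  once <- enforce_topology(clean)
  twice <- enforce_topology(once)
  expect_equal(once, twice)
  expect_equal(once, clean)
})

test_that("clipping keeps exactly the geometry inside the study disc", {
  area <- study_area(c(0, 0), 3000)
  outside <- streets("o", 3L, list(cbind(x = c(5000, 6000), y = c(0, 0))))
  expect_equal(nrow(clip_to_study_area(outside, area)), 0)

  through <- streets("t", 3L, list(cbind(x = c(-4000, 4000), y = c(0, 0))))
  cl <- clip_to_study_area(through, area)
  expect_equal(network_length(cl), 6000, tolerance = 1e-6)  # the diameter

  inside <- streets("i", 3L, list(cbind(x = c(-100, 100), y = c(50, 50))))
  expect_equal(clip_to_study_area(inside, area)$geometry,
               inside$geometry)

  # chord at y = 2997: half-length = sqrt(3000^2 - 2997^2)
  chord <- streets("c", 3L, list(cbind(x = c(-500, 500), y = c(2997, 2997))))
  expect_equal(network_length(clip_to_study_area(chord, area)),
               2 * sqrt(3000^2 - 2997^2), tolerance = 1e-6)
})

test_that("site counts, chainages and headings follow the sampling contract", {
  st <- streets("a", 3L, list(cbind(x = c(0, 200), y = c(0, 0))))
  sp <- sample_points(st, 50)
  expect_equal(nrow(sp), 5)
  expect_equal(sp$chainage, c(0, 50, 100, 150, 200))
  # due east: azimuth 90, headings front/back/left/right = 90/270/180/0
  expect_true(all(sp$azimuth == 90))
  expect_equal(unique(sp[, c("h_front", "h_back", "h_left", "h_right")]),
               tibble::tibble(h_front = 90, h_back = 270, h_left = 180,
                              h_right = 0))

  short <- streets("b", 3L, list(cbind(x = c(0, 0), y = c(0, 40))))
  expect_equal(nrow(sample_points(short, 50)), 1)  # the start, always

  expect_error(sample_points(st, 0), "positive")
})

test_that("sampling density and heading closure hold for arbitrary polylines", {
  set.seed(42)
  for (i in 1:15) {
    nv <- sample(2:6, 1)
    m <- cbind(x = cumsum(runif(nv, 10, 120)), y = cumsum(rnorm(nv, 0, 40)))
    st <- streets("r", 3L, list(m))
    sp <- sample_points(st, 50)
    expect_equal(nrow(sp), floor(st$length_m / 50) + 1)
    expect_true(all(abs((sp$h_front - sp$h_back) %% 360 - 180) < 1e-9))
    expect_true(all(abs((sp$h_left - sp$h_right) %% 360 - 180) < 1e-9))
    expect_true(all(sp$chainage >= 0 & sp$chainage <= st$length_m + 1e-9))
  }
})

test_that("full preprocessing is idempotent", {
  g <- make_street_grid(network_spec(3, 3, spacing = 200, dangle_count = 2,
                                     dual_carriageway_fraction = 0.25,
                                     carriageway_offset = 16, seed = 8))
  area <- study_area(c(200, 200), 3000)
  once <- suppressMessages(preprocess_streets(g, area))
  twice <- suppressMessages(preprocess_streets(once, area))
  expect_equal(nrow(once), nrow(twice))
  expect_equal(network_length(once), network_length(twice), tolerance = 1e-9)
})
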