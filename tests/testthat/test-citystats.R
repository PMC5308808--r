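# City summaries, typology, Moran's I, standardized regressions.

test_that("city summaries use arithmetic mean and population sd", {
  sites <- tibble::tibble(city_id = c("a", "a", "b", "c", "c", "c"),
                          gvi = c(0.2, 0.4, 0.25, 0.3, 0.3, 0.3))
  s <- summarize_city(sites)
  expect_equal(s$gvi_mean[s$city_id == "a"], 0.3)
  expect_equal(s$gvi_sd[s$city_id == "a"], 0.1)
  expect_equal(s$gvi_sd[s$city_id == "b"], 0)    # single site
  expect_equal(s$gvi_sd[s$city_id == "c"], 0)    # identical sites
})

test_that("the four-type typology compares against the reference pair with Low ties", {
  s <- tibble::tibble(city_id = c("hl", "ll", "hh", "lh", "tie"),
                      gvi_mean = c(0.30, 0.20, 0.35, 0.25, 0.276),
                      gvi_sd = c(0.10, 0.09, 0.20, 0.30, 0.128))
  out <- classify_cities(s, reference = c(0.276, 0.128))
  expect_equal(as.character(out$type),
               c("HighAvgLowStd", "LowAvgLowStd", "HighAvgHighStd",
                 "LowAvgHighStd", "LowAvgLowStd"))
  # the labels always partition the cities
  expect_equal(sum(table(out$type)), nrow(s))
  # identical cities share a label; default reference is the cross-city mean
  two <- tibble::tibble(city_id = c("x", "y"), gvi_mean = 0.3, gvi_sd = 0.1)
  expect_equal(length(unique(classify_cities(two)$type)), 1L)
})

test_that("Moran's I matches a brute-force double sum and ape's implementation", {
  set.seed(10)
  x <- runif(40, 0, 100); y <- runif(40, 0, 100)
  v <- x / 100 + rnorm(40, 0, 0.3)
  w <- greenview:::knn_weights(x, y, k = 6)
  m <- morans_i(x, y, v, k = 6, permutations = 0)
  # brute force
  z <- v - mean(v); n <- length(v)
  I_bf <- (n / sum(w)) * sum(outer(z, z) * w) / sum(z^2)
  expect_equal(m$I, I_bf, tolerance = 1e-12)
  # independent implementation
  a <- ape::Moran.I(v, w)
  expect_equal(m$I, a$observed, tolerance = 1e-9)
  expect_equal(m$expected, a$expected, tolerance = 1e-12)
})

test_that("Moran's I is positive on gradients, null on noise, negative on checkerboards", {
  gridpts <- expand.grid(x = seq(0, 90, 10), y = seq(0, 90, 10))
  grad <- morans_i(gridpts$x, gridpts$y,
                   gridpts$y / 90 + rnorm(100, 0, 0.15),
                   permutations = 199, seed = 4)
  expect_gt(grad$I, 0)
  expect_gt(grad$z, 2)
  expect_lt(grad$p_perm, 0.05)

  # permuting values across locations kills the autocorrelation
  set.seed(6)
  zs <- vapply(1:10, function(i) {
    morans_i(gridpts$x, gridpts$y, sample(gridpts$y / 90 + rnorm(100, 0, 0.15)),
             permutations = 0)$z
  }, numeric(1))
  expect_gte(mean(abs(zs) < 2), 0.9)

  # checkerboard with rook weights: alternation forces I below expectation
  board <- expand.grid(r = 1:8, c = 1:8)
  vals <- (-1)^(board$r + board$c)
  d <- as.matrix(dist(board))
  rook <- (d == 1) * 1  # orthogonal neighbors only
  chk <- morans_i(board$r, board$c, vals + rnorm(64, 0, 0.01),
                  weights = rook, permutations = 0)
  expect_lt(chk$I, chk$expected)
  expect_lt(chk$z, -2)

  expect_error(morans_i(1:20, 1:20, rep(1, 20)), "constant")
  expect_error(morans_i(1:5, 1:5, rnorm(5)), "at least 8")
})

test_that("standardized coefficients are invariant to affine predictor rescaling", {
  p <- make_city_panel(panel_spec(30, 100, beta = c(LENGTH = 0.1),
                                  noise_sd = 1, seed = 8))
  td1 <- tidy(fit_location_models(p, 1))
  p2 <- p
  p2$LENGTH <- p2$LENGTH * 1000 + 5
  p2$CENTER <- p2$CENTER / 37 - 2
  td2 <- tidy(fit_location_models(p2, 1))
  expect_equal(td1$estimate, td2$estimate, tolerance = 1e-12)
  expect_equal(td1$p.value, td2$p.value, tolerance = 1e-9)
})

test_that("nested models do not lose adjusted R^2 when added effects are real", {
  beta <- c(CENTER = 0.05, LENGTH = 0.11, ELEVATION = -0.08, WEST = 0.14)
  p <- make_city_panel(panel_spec(60, 300, beta = beta,
                                  noise_sd = sqrt(1 - sum(beta^2)), seed = 12))
  r2 <- vapply(1:3, function(m)
    glance(fit_location_models(p, m))$adj.r.squared, numeric(1))
  expect_true(all(diff(r2) > 0))
})

test_that("rank-deficient designs fail loudly, naming the collinear pair", {
  p <- make_city_panel(panel_spec(20, 30, seed = 3))
  p$SIZE <- p$ECONOMY
  expect_error(fit_location_models(p, 2), "SIZE|ECONOMY")
})

test_that("p-values are calibrated when the response is pure noise", {
  set.seed(21)
  hits <- vapply(1:300, function(i) {
    n <- 120
    df <- tibble::tibble(GVI = rnorm(n), CENTER = rnorm(n), LENGTH = rnorm(n))
    td <- tidy(fit_location_models(df, 1))
    sum(td$p.value <= 0.05)
  }, numeric(1))
  rate <- sum(hits) / (300 * 2)
  expect_gt(rate, 0.02); expect_lt(rate, 0.09)
})

test_that("backward elimination keeps strong effects, drops constants, and is deterministic", {
  beta <- c(LENGTH = 0.12, WEST = 0.15)
  p <- make_city_panel(panel_spec(60, 200, beta = beta,
                                  noise_sd = sqrt(1 - sum(beta^2)), seed = 31))
  f <- fit_by_level(p, level = 4)
  kept <- tidy(f)$term
  expect_true(all(c("LENGTH", "WEST") %in% kept))
  expect_true(all(tidy(f)$p.value <= 0.05))
  # identical inputs give identical final sets
  f2 <- fit_by_level(p, level = 4)
  expect_identical(sort(tidy(f2)$term), sort(kept))
  expect_identical(f$eliminated, f2$eliminated)

  # constant covariate within the subset is dropped up front and noted
  p3 <- p; p3$WATER <- 0
  f3 <- fit_by_level(p3, level = 4)
  expect_true("WATER" %in% f3$dropped)

  expect_error(fit_by_level(p[1:10, ]), "need >= 30")

  # with no true effects the final model is usually empty
  # with 9 null candidates the intercept-only outcome has probability
  # ~0.95^9 = 0.63 under the 0.05 stopping rule
  empties <- vapply(1:30, function(s) {
    pn <- make_city_panel(panel_spec(25, 40, seed = 500 + s))
    nrow(tidy(fit_by_level(pn)))
  }, numeric(1))
  expect_gte(mean(empties == 0), 0.5)
})

test_that("covariate correlation checks flag engineered dependence", {
  p <- make_city_panel(panel_spec(40, 50, seed = 9))
  rep1 <- check_covariate_correlations(p, variables = c("CENTER", "LENGTH",
                                                        "SIZE", "ECONOMY"))
  expect_false(any(rep1$flagged))
  p$DUP <- p$LENGTH
  rep2 <- check_covariate_correlations(p, variables = c("LENGTH", "DUP"))
  expect_true(rep2$flagged[1])
  expect_equal(rep2$r[1], 1)
  # bivariate Gaussian with r = 0.9
  set.seed(2)
  n <- 5000
  a <- rnorm(n); b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(n)
  rep3 <- check_covariate_correlations(tibble::tibble(A = a, B = b),
                                       variables = c("A", "B"))
  expect_true(rep3$flagged[1])
  expect_equal(rep3$r[1], 0.9, tolerance = 0.02)
})
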