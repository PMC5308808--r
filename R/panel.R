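# Synthetic multi-city location panels with a known linear effect structure,
# for exercising and validating the standardized regression machinery.

#' Variables of the location-level regression panel
#'
#' `CENTER` (air distance to the city center, m) and `LENGTH` (street length
#' of the containing segment, m) are street-level; the rest are city-level
#' controls: `SIZE` (urban area), `LEVEL` (administrative tier 1-4),
#' `DENSITY` (population density), `ECONOMY` (economic output), `ELEVATION`
#' (m a.s.l.), `WATER` (water body crossing the center, 0/1), and the region
#' dummies `MIDDLE` / `WEST` (never both 1).
#'
#' @return Character vector of variable names.
#' @export
panel_variables <- function() {
  c("CENTER", "LENGTH", "SIZE", "LEVEL", "DENSITY", "ECONOMY",
    "ELEVATION", "WATER", "MIDDLE", "WEST")
}

#' Specify a synthetic location panel
#'
#' @param n_cities Number of cities (>= 2).
#' @param sites_per_city Locations per city.
#' @param beta Named numeric vector of true standardized coefficients; names
#'   must be a subset of [panel_variables()]; unnamed variables get 0.
#' @param noise_sd Gaussian noise sd added to the standardized linear
#'   predictor (> 0). With covariates z-scored, choosing
#'   `noise_sd = sqrt(1 - sum(beta^2))` makes the response variance 1 so
#'   fitted standardized coefficients estimate `beta` directly.
#' @param seed Integer RNG seed.
#' @return A `gv_panel_spec` list.
#' @export
panel_spec <- function(n_cities = 50L, sites_per_city = 100L,
                       beta = numeric(), noise_sd = 1, seed = 1L) {
  if (n_cities < 2) abort("`n_cities` must be >= 2")
  stopifnot_scalar_num(noise_sd, "noise_sd", 1e-9, Inf)
  vars <- panel_variables()
  full <- setNames(numeric(length(vars)), vars)
  if (length(beta) > 0) {
    if (is.null(names(beta)) || !all(names(beta) %in% vars)) {
      abort(paste("`beta` must be named with a subset of:",
                  paste(vars, collapse = ", ")))
    }
    full[names(beta)] <- beta
  }
  structure(
    list(n_cities = as.integer(n_cities),
         sites_per_city = as.integer(sites_per_city),
         beta = full, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "gv_panel_spec")
}

#' Generate a synthetic location panel
#'
#' City-level covariates are drawn once per city (log-normal sizes,
#' economies and densities; administrative levels weighted toward
#' prefecture-level cities as in the Chinese city system; a three-way
#' east/middle/west region draw), street-level covariates per location. All
#' covariates are then z-scored across the panel and the response is
#' `GVI = X_z %*% beta + N(0, noise_sd)`, so the true standardized effect of
#' every variable is known exactly.
#'
#' @param spec A [panel_spec()].
#' @return A tibble with `site_id`, `city_id`, city centroid `cx`/`cy`
#'   (arbitrary planar km for spatial tests), `GVI`, and the standardized
#'   covariates of [panel_variables()].
#' @export
make_city_panel <- function(spec) {
  stopifnot(inherits(spec, "gv_panel_spec"))
  n <- spec$n_cities * spec$sites_per_city
  if (n < length(spec$beta) + 2L) {
    abort("panel too small: need at least covariates + 2 rows")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  region <- sample(c("east", "middle", "west"), spec$n_cities,
                   replace = TRUE, prob = c(0.5, 0.25, 0.25))
  cities <- tibble(
    city_id = sprintf("city%03d", seq_len(spec$n_cities)),
    cx = runif(spec$n_cities, 0, 2000),
    cy = runif(spec$n_cities, 0, 2000),
    LEVEL = sample(1:4, spec$n_cities, replace = TRUE,
                   prob = c(0.05, 0.10, 0.15, 0.70)),
    SIZE = rlnorm(spec$n_cities, log(300), 0.7),
    DENSITY = rlnorm(spec$n_cities, log(2000), 0.5),
    ECONOMY = rlnorm(spec$n_cities, log(1500), 0.8),
    ELEVATION = rlnorm(spec$n_cities, log(200), 1),
    WATER = rbinom(spec$n_cities, 1, 0.5),
    MIDDLE = as.integer(region == "middle"),
    WEST = as.integer(region == "west")
  )
  panel <- cities[rep(seq_len(spec$n_cities), each = spec$sites_per_city), ]
  panel$site_id <- sprintf("%s_s%05d", panel$city_id,
                           rep(seq_len(spec$sites_per_city), spec$n_cities))
  panel$CENTER <- runif(n, 0, 3000)
  panel$LENGTH <- rlnorm(n, log(148), 0.5)

  panel$LEVEL_raw <- panel$LEVEL  # tier identity survives standardization
  vars <- panel_variables()
  for (v in vars) {
    s <- sd(panel[[v]])
    panel[[v]] <- if (s > 0) (panel[[v]] - mean(panel[[v]])) / s else panel[[v]] * 0
  }
  xz <- as.matrix(panel[, vars])
  panel$GVI <- as.vector(xz %*% spec$beta) + rnorm(n, 0, spec$noise_sd)
  panel %>%
    select("site_id", "city_id", "cx", "cy", "GVI", "LEVEL_raw",
           dplyr::all_of(vars)) %>%
    as_tibble()
}
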