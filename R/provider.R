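# Street-view image providers.
#
# A provider abstracts where directional street-level photographs come from:
# a live panorama web API (Tencent dialect), a local directory of
# pre-downloaded images, or a fully synthetic mock whose images are
# generated scenes with known ground truth. All providers share the
# find_pano() / fetch_image() interface and a client-side query quota.

#' Construct a panorama image query
#'
#' Mirrors the parameter set of the panorama image API: picture size (at
#' most 960 x 640), either a panorama id or a location, a heading clockwise
#' from north, a pitch in [-20, 90] (fixed at 0 throughout this package; the
#' vertical angle is not analyzed), and the developer key.
#'
#' @param width,height Requested image size in pixels (<= 960 x 640).
#' @param pano_id Panorama id; exactly one of `pano_id`/`location`.
#' @param location `c(x, y)` coordinate; exactly one of `pano_id`/`location`.
#' @param heading Degrees clockwise from north, in [0, 360).
#' @param pitch Vertical angle in degrees, [-20, 90].
#' @param key Developer key string (providers that need none ignore it).
#' @return A `gv_pano_query` list.
#' @export
pano_query <- function(width = 960L, height = 640L, pano_id = NULL,
                       location = NULL, heading = 0, pitch = 0, key = "") {
  stopifnot_scalar_num(width, "width", 1, 960)
  stopifnot_scalar_num(height, "height", 1, 640)
  stopifnot_scalar_num(pitch, "pitch", -20, 90)
  heading <- as.numeric(heading) %% 360
  if (is.null(pano_id) == is.null(location)) {
    abort("exactly one of `pano_id` and `location` must be given")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 pano_id = pano_id, location = location,
                 heading = heading, pitch = pitch, key = key),
            class = "gv_pano_query")
}

#' Find the nearest panorama to a coordinate
#'
#' Returns the closest available panorama within `search_radius`, or `NULL`
#' when none exists there -- absence of coverage is an expected outcome, not
#' an error (provider outages raise a `gv_provider_error` instead).
#'
#' @param provider A provider object.
#' @param x,y Projected coordinate (meters).
#' @param search_radius Search radius in meters (default 50).
#' @return A one-row tibble (`pano_id`, `x`, `y`, `capture_date`) or `NULL`.
#' @export
find_pano <- function(provider, x, y, search_radius = 50) {
  UseMethod("find_pano")
}

#' Fetch one street-view image
#'
#' @param provider A provider object.
#' @param query A [pano_query()].
#' @return An integer RGB array (height x width x 3, 0-255) of exactly the
#'   requested size.
#' @export
fetch_image <- function(provider, query) {
  UseMethod("fetch_image")
}

# ---- quota bookkeeping ---------------------------------------------------

# Client-side counter of API queries per key; the live service allows
# 100,000 per key. Persisted to `counter_file` when set, so interrupted
# crawls resume without losing the count.
new_quota <- function(limit = 100000L, counter_file = NULL) {
  env <- new.env(parent = emptyenv())
  env$limit <- limit
  env$counter_file <- counter_file
  env$count <- 0L
  if (!is.null(counter_file) && file.exists(counter_file)) {
    env$count <- as.integer(readLines(counter_file, warn = FALSE)[1])
  }
  env
}

quota_tick <- function(q) {
  if (q$count >= q$limit) {
    gv_error("gv_quota_error",
             sprintf("query quota exhausted (%d of %d used)", q$count, q$limit))
  }
  q$count <- q$count + 1L
  if (!is.null(q$counter_file)) writeLines(as.character(q$count), q$counter_file)
  invisible(q$count)
}

#' Number of queries a provider has issued
#' @param provider A provider object.
#' @return Integer count.
#' @export
queries_used <- function(provider) provider$quota$count

# ---- mock provider -------------------------------------------------------

#' Mock street-view provider backed by synthetic scenes
#'
#' Each (panorama, heading) pair maps deterministically to a synthetic scene
#' seed, so repeated fetches are byte-identical and different headings of
#' one panorama differ. Per-view green fractions are drawn (deterministically
#' per pano/heading) from `green_fraction_range`.
#'
#' @param panos Tibble with `pano_id`, `x`, `y` (projected meters); see
#'   [mock_panos_from_sites()].
#' @param seed Integer seed from which all per-view scene seeds derive.
#' @param quota Query limit (default 100000 as per the live service).
#' @param green_fraction_range Range of per-view vegetation fractions.
#' @param illumination_jitter Scene brightness jitter (see [scene_spec()]).
#' @param counter_file Optional path persisting the query counter.
#' @return A `gv_mock_provider`.
#' @export
mock_provider <- function(panos, seed = 1L, quota = 100000L,
                          green_fraction_range = c(0, 0.6),
                          illumination_jitter = 0.15,
                          counter_file = NULL) {
  stopifnot(all(c("pano_id", "x", "y") %in% names(panos)))
  structure(list(panos = as_tibble(panos), seed = as.integer(seed),
                 green_fraction_range = green_fraction_range,
                 illumination_jitter = illumination_jitter,
                 quota = new_quota(as.integer(quota), counter_file)),
            class = c("gv_mock_provider", "gv_provider"))
}

#' Scatter mock panoramas near sample sites
#'
#' @param sites Site tibble from [sample_points()].
#' @param coverage Fraction of sites that get a panorama nearby.
#' @param offset_sd Gaussian positional offset of the panorama from its
#'   site, meters (street-view cars do not stop exactly on sample points).
#' @param seed RNG seed.
#' @return A pano tibble for [mock_provider()].
#' @export
mock_panos_from_sites <- function(sites, coverage = 1, offset_sd = 5,
                                  seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  keep <- runif(nrow(sites)) <= coverage
  s <- sites[keep, ]
  tibble(pano_id = paste0("p_", s$site_id),
         x = s$x + rnorm(nrow(s), 0, offset_sd),
         y = s$y + rnorm(nrow(s), 0, offset_sd))
}

#' @export
find_pano.gv_mock_provider <- function(provider, x, y, search_radius = 50) {
  d <- sqrt((provider$panos$x - x)^2 + (provider$panos$y - y)^2)
  if (length(d) == 0 || min(d) > search_radius) return(NULL)
  i <- which.min(d)
  tibble(pano_id = provider$panos$pano_id[i],
         x = provider$panos$x[i], y = provider$panos$y[i],
         capture_date = NA_character_)
}

#' @export
fetch_image.gv_mock_provider <- function(provider, query) {
  stopifnot(inherits(query, "gv_pano_query"))
  quota_tick(provider$quota)
  pano_id <- query$pano_id
  if (is.null(pano_id)) {
    hit <- find_pano(provider, query$location[1], query$location[2])
    if (is.null(hit)) {
      gv_error("gv_provider_error", "no panorama at the queried location")
    }
    pano_id <- hit$pano_id
  }
  view_key <- sprintf("%s|%.2f", pano_id, query$heading)
  view_seed <- child_seed(provider$seed, view_key)
  gr <- provider$green_fraction_range
  # deterministic per-view green fraction
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(view_seed)
  gf <- runif(1, gr[1], gr[2])
  sc <- make_scene(scene_spec(width = query$width, height = query$height,
                              green_fraction = gf,
                              illumination_jitter = provider$illumination_jitter,
                              seed = child_seed(view_seed, "scene")))
  sc$image
}

# ---- local directory provider --------------------------------------------

#' Local directory street-view provider
#'
#' Reads pre-downloaded images laid out as `<root>/<pano_id>/<heading>.png`
#' (heading as an integer number of degrees). Panorama locations come from
#' `<root>/panos.csv` with columns `pano_id`, `x`, `y`.
#'
#' @param root Directory root.
#' @param quota Query limit.
#' @return A `gv_local_provider`.
#' @export
local_provider <- function(root, quota = 100000L) {
  idx <- file.path(root, "panos.csv")
  panos <- if (file.exists(idx)) {
    as_tibble(utils::read.csv(idx, stringsAsFactors = FALSE))
  } else {
    tibble(pano_id = character(), x = numeric(), y = numeric())
  }
  structure(list(root = root, panos = panos,
                 quota = new_quota(as.integer(quota))),
            class = c("gv_local_provider", "gv_provider"))
}

#' @export
find_pano.gv_local_provider <- function(provider, x, y, search_radius = 50) {
  d <- sqrt((provider$panos$x - x)^2 + (provider$panos$y - y)^2)
  if (length(d) == 0 || min(d) > search_radius) return(NULL)
  i <- which.min(d)
  tibble(pano_id = provider$panos$pano_id[i],
         x = provider$panos$x[i], y = provider$panos$y[i],
         capture_date = NA_character_)
}

#' @export
fetch_image.gv_local_provider <- function(provider, query) {
  stopifnot(inherits(query, "gv_pano_query"))
  quota_tick(provider$quota)
  if (is.null(query$pano_id)) {
    gv_error("gv_provider_error", "local provider needs `pano_id` queries")
  }
  path <- file.path(provider$root, query$pano_id,
                    sprintf("%d.png", as.integer(round(query$heading)) %% 360L))
  if (!file.exists(path)) {
    gv_error("gv_provider_error", sprintf("image not found: %s", path))
  }
  read_image(path)
}

# ---- live HTTP provider (Tencent dialect) --------------------------------

#' Live panorama API provider (Tencent dialect)
#'
#' Builds image requests as
#' `<base>?size=WxH&pano=<id>&heading=<h>&pitch=<p>&key=<key>` and place-id
#' lookups as `<search_base>?location=<lat>,<lon>&radius=<r>&key=<key>`.
#' Requires network access and a valid key; all offline analysis and every
#' test in this package use the mock or local provider instead. An invalid
#' key raises a `gv_auth_error`; exceeding the per-key quota (100,000
#' queries) raises a `gv_quota_error` client-side.
#'
#' @param key Developer key.
#' @param base_url Image endpoint.
#' @param search_url Place-id (nearest panorama) endpoint.
#' @param quota Per-key query budget.
#' @param counter_file Optional persisted query counter.
#' @return A `gv_live_provider`.
#' @export
live_provider <- function(key,
                          base_url = "https://apis.map.qq.com/ws/streetview/v1/image",
                          search_url = "https://apis.map.qq.com/ws/streetview/v1/getpano",
                          quota = 100000L, counter_file = NULL) {
  if (!nzchar(key)) gv_error("gv_auth_error", "a non-empty API key is required")
  structure(list(key = key, base_url = base_url, search_url = search_url,
                 quota = new_quota(as.integer(quota), counter_file)),
            class = c("gv_live_provider", "gv_provider"))
}

live_image_url <- function(provider, query) {
  sprintf("%s?size=%dx%d&pano=%s&heading=%d&pitch=%d&key=%s",
          provider$base_url, query$width, query$height, query$pano_id,
          as.integer(round(query$heading)), as.integer(round(query$pitch)),
          provider$key)
}

#' @export
fetch_image.gv_live_provider <- function(provider, query) {
  stopifnot(inherits(query, "gv_pano_query"))
  quota_tick(provider$quota)
  url <- live_image_url(provider, query)
  tmp <- tempfile(fileext = ".png")
  ok <- tryCatch(utils::download.file(url, tmp, mode = "wb", quiet = TRUE),
                 error = function(e) -1L, warning = function(w) -1L)
  if (!identical(ok, 0L)) {
    gv_error("gv_provider_error", sprintf("download failed: %s", url))
  }
  read_image(tmp)
}

#' @export
find_pano.gv_live_provider <- function(provider, x, y, search_radius = 50) {
  quota_tick(provider$quota)
  url <- sprintf("%s?location=%f,%f&radius=%f&key=%s", provider$search_url,
                 y, x, search_radius, provider$key)
  ans <- tryCatch(jsonlite::fromJSON(url), error = function(e) NULL)
  if (is.null(ans) || is.null(ans$detail$id)) return(NULL)
  tibble(pano_id = as.character(ans$detail$id),
         x = as.numeric(ans$detail$x %||% NA),
         y = as.numeric(ans$detail$y %||% NA),
         capture_date = NA_character_)
}

# ---- inventory -----------------------------------------------------------

#' Crawl images for sample sites and build the SVP inventory
#'
#' For every site the nearest panorama within `search_radius` is looked up;
#' when found, one image per heading (front, back, left, right) is fetched
#' and optionally written to `image_dir` as `<pano_id>_<heading>.png`. Sites
#' without a panorama get a single `status = "missing"` row. Per-row
#' provider failures are recorded (`status = "error"`), never aborting the
#' batch; only an exhausted quota stops the crawl (resume later with the
#' persisted counter and the partial inventory).
#'
#' @param sites Site tibble from [sample_points()].
#' @param provider A provider object.
#' @param search_radius Panorama search radius, meters.
#' @param image_dir Directory for fetched images (`NULL` = don't write).
#' @param width,height Image size to request.
#' @return Inventory tibble: `site_id`, `segment_id`, `x`, `y`,
#'   `heading_label`, `heading`, `pano_id`, `image_file`, `status`.
#' @export
build_inventory <- function(sites, provider, search_radius = 50,
                            image_dir = NULL, width = 960L, height = 640L) {
  if (!is.null(image_dir)) dir.create(image_dir, showWarnings = FALSE,
                                      recursive = TRUE)
  labels <- c(front = "h_front", back = "h_back",
              left = "h_left", right = "h_right")
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    hit <- tryCatch(find_pano(provider, s$x, s$y, search_radius),
                    gv_provider_error = function(e) e)
    if (inherits(hit, "gv_error")) {
      rows[[i]] <- tibble(site_id = s$site_id, segment_id = s$segment_id,
                          x = s$x, y = s$y, heading_label = NA_character_,
                          heading = NA_real_, pano_id = NA_character_,
                          image_file = NA_character_, status = "error")
      next
    }
    if (is.null(hit)) {
      rows[[i]] <- tibble(site_id = s$site_id, segment_id = s$segment_id,
                          x = s$x, y = s$y, heading_label = NA_character_,
                          heading = NA_real_, pano_id = NA_character_,
                          image_file = NA_character_, status = "missing")
      next
    }
    site_rows <- purrr::map_dfr(names(labels), function(lab) {
      h <- s[[labels[[lab]]]]
      safe_id <- gsub("[^A-Za-z0-9_.-]", "-", hit$pano_id)
      fname <- sprintf("%s_%03d.png", safe_id, as.integer(round(h)) %% 360L)
      st <- tryCatch({
        img <- fetch_image(provider, pano_query(
          width = width, height = height, pano_id = hit$pano_id, heading = h))
        if (!is.null(image_dir)) {
          png::writePNG(img / 255, file.path(image_dir, fname))
        }
        "ok"
      },
      gv_quota_error = function(e) "quota",
      gv_provider_error = function(e) "error")
      tibble(site_id = s$site_id, segment_id = s$segment_id, x = s$x, y = s$y,
             heading_label = lab, heading = h, pano_id = hit$pano_id,
             image_file = ifelse(st == "ok", fname, NA_character_),
             status = st)
    })
    rows[[i]] <- site_rows
  }
  dplyr::bind_rows(rows)
}
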