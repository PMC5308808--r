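# Resumable pipeline: street preprocessing -> site sampling -> image
# crawling -> picture analysis -> aggregation -> city statistics.
#
# Each stage reads the previous stage's files from the run directory and
# writes its own under fixed names, so every intermediate artifact
# (processed network, site list, crawl inventory, GVI table, units) is an
# inspectable file. A JSON manifest records per-stage completion, input
# digests and entity counts; a completed stage is a no-op on re-run unless
# forced, and a stage refuses to run when an upstream output changed after
# it last ran.

PIPELINE_STAGES <- c("preprocess", "sample", "fetch", "gvi", "aggregate",
                     "citystats")

# Fixed file names inside a run directory.
run_files <- function(run_dir) {
  list(network = file.path(run_dir, "network.geojson"),
       sites = file.path(run_dir, "sites.csv"),
       inventory = file.path(run_dir, "inventory.csv"),
       images = file.path(run_dir, "images"),
       gvi = file.path(run_dir, "gvi.csv"),
       sites_gvi = file.path(run_dir, "sites_gvi.csv"),
       segment_stats = file.path(run_dir, "segment_stats.csv"),
       segments_geojson = file.path(run_dir, "segments.geojson"),
       blocks_geojson = file.path(run_dir, "blocks.geojson"),
       blocks = file.path(run_dir, "blocks.csv"),
       city_summary = file.path(run_dir, "city_summary.csv"),
       models = file.path(run_dir, "models.csv"),
       manifest = file.path(run_dir, "manifest.json"))
}

#' Default pipeline configuration
#'
#' Returns the full configuration list with every knob at its default;
#' values in `...` (or a YAML file via [read_run_config()]) override
#' defaults. Key entries: `seed`; `network` (GeoJSON path) or `synthetic`
#' (list of [network_spec()] arguments); `center` (`c(lon, lat)`, optional);
#' `study_radius_m` (3000); `sampling_interval` (50); `excluded_classes`
#' (1); `merge_distance` (30); `dangle_threshold` (100); `green_range`
#' (`c(60, 180)`); `provider` (list with `type` = "mock", "local", "live"
#' or "none" plus type-specific fields); `search_radius` (50);
#' `image_width`/`image_height`; `buffer_min`/`buffer_max` (2/30);
#' `block_resolution` (NULL = auto); `min_sites_per_km` (13),
#' `min_area_ha` (1), `min_sites_per_ha` (1).
#'
#' @param ... Overrides.
#' @return Named list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L, network = NULL, synthetic = NULL, center = NULL,
    study_radius_m = 3000, sampling_interval = 50,
    excluded_classes = 1L, merge_distance = 30, dangle_threshold = 100,
    green_range = c(60, 180),
    provider = list(type = "mock", coverage = 1, offset_sd = 5,
                    green_fraction_range = c(0, 0.6), root = NULL,
                    key = NULL, quota = 100000L),
    search_radius = 50, image_width = 320L, image_height = 213L,
    buffer_min = 2, buffer_max = 30, block_resolution = NULL,
    min_sites_per_km = 13, min_area_ha = 1, min_sites_per_ha = 1)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a YAML pipeline configuration
#' @param path YAML file; keys as in [run_config()].
#' @return Configuration list with defaults filled in.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

read_manifest <- function(run_dir) {
  f <- run_files(run_dir)$manifest
  if (file.exists(f)) jsonlite::read_json(f) else
    list(stages = list(), config = NULL)
}

write_manifest <- function(run_dir, manifest) {
  jsonlite::write_json(manifest, run_files(run_dir)$manifest,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

digest_of <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(setNames(unname(tools::md5sum(paths)), basename(paths)))
}

stage_inputs <- function(stage, f) {
  switch(stage,
         preprocess = character(),
         sample = f$network,
         fetch = f$sites,
         gvi = c(f$sites, f$inventory),
         aggregate = c(f$network, f$sites_gvi),
         citystats = f$sites_gvi)
}

#' Run one pipeline stage
#'
#' @param run_dir Run directory (created if needed).
#' @param stage One of `preprocess`, `sample`, `fetch`, `gvi`, `aggregate`,
#'   `citystats`.
#' @param config Configuration from [run_config()]/[read_run_config()].
#' @param force Re-run even if the manifest marks the stage complete.
#' @return The updated manifest, invisibly.
#' @export
run_stage <- function(run_dir, stage, config = run_config(), force = FALSE) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  f <- run_files(run_dir)
  manifest <- read_manifest(run_dir)

  ins <- stage_inputs(stage, f)
  missing_in <- ins[!file.exists(ins)]
  if (length(missing_in) > 0) {
    abort(sprintf("stage '%s' needs upstream outputs first: %s",
                  stage, paste(basename(missing_in), collapse = ", ")))
  }
  # refuse on stale upstream digests
  for (up in PIPELINE_STAGES[seq_len(match(stage, PIPELINE_STAGES) - 1)]) {
    rec <- manifest$stages[[up]]
    if (is.null(rec)) next
    for (nm in names(rec$outputs)) {
      p <- file.path(run_dir, nm)
      if (file.exists(p) && !identical(unname(tools::md5sum(p))[1],
                                       rec$outputs[[nm]])) {
        abort(sprintf(
          "output '%s' of stage '%s' changed since it ran; re-run '%s' (or remove the manifest) before '%s'",
          nm, up, up, stage))
      }
    }
  }
  rec <- manifest$stages[[stage]]
  cur_in <- digest_of(ins)
  if (!force && !is.null(rec) && isTRUE(rec$done) &&
      identical(rec$inputs, cur_in)) {
    inform(sprintf("stage '%s' already complete; skipping (use force = TRUE)",
                   stage))
    return(invisible(manifest))
  }

  set.seed(child_seed(config$seed, stage))
  counts <- switch(stage,
    preprocess = stage_preprocess(f, config),
    sample = stage_sample(f, config),
    fetch = stage_fetch(f, config),
    gvi = stage_gvi(f, config),
    aggregate = stage_aggregate(f, config),
    citystats = stage_citystats(f, config))

  outs <- switch(stage,
    preprocess = f$network,
    sample = f$sites,
    fetch = f$inventory,
    gvi = c(f$gvi, f$sites_gvi),
    aggregate = c(f$segment_stats, f$segments_geojson, f$blocks,
                  f$blocks_geojson),
    citystats = c(f$city_summary,
                  if (file.exists(f$models)) f$models))
  manifest$stages[[stage]] <- list(done = TRUE, inputs = cur_in,
                                   outputs = digest_of(outs),
                                   counts = counts,
                                   time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  manifest$config <- config
  write_manifest(run_dir, manifest)
  invisible(manifest)
}

#' Run all pipeline stages in order
#' @inheritParams run_stage
#' @param stages Stages to run (default all, in order).
#' @return The final manifest, invisibly.
#' @export
run_pipeline <- function(run_dir, config = run_config(),
                         stages = PIPELINE_STAGES, force = FALSE) {
  for (s in stages) run_stage(run_dir, s, config, force = force)
  invisible(read_manifest(run_dir))
}

# ---- stage bodies --------------------------------------------------------

stage_preprocess <- function(f, config) {
  if (!is.null(config$synthetic)) {
    spec <- do.call(network_spec, c(config$synthetic,
                                    list(seed = child_seed(config$seed, "net"))))
    raw <- make_street_grid(spec)
  } else if (!is.null(config$network)) {
    raw <- read_streets_geojson(config$network, center = config$center)
  } else {
    abort("config needs either `network` (GeoJSON path) or `synthetic`")
  }
  n_in <- nrow(raw)
  area <- if (is.null(config$study_radius_m) || n_in == 0) NULL else {
    ctr <- if (!is.null(config$center)) c(0, 0) else {
      # without a declared center, use the network's bounding-box middle
      allm <- do.call(rbind, raw$geometry)
      c(mean(range(allm[, 1])), mean(range(allm[, 2])))
    }
    study_area(ctr, config$study_radius_m)
  }
  out <- preprocess_streets(raw, area = area,
                            excluded_classes = config$excluded_classes,
                            merge_distance = config$merge_distance,
                            dangle_threshold = config$dangle_threshold)
  write_streets_geojson(out, f$network)
  list(segments_in = n_in, segments_out = nrow(out))
}

stage_sample <- function(f, config) {
  net <- read_streets_geojson(f$network)
  sites <- sample_points(net, interval = config$sampling_interval)
  write_sites_csv(sites, f$sites, center = config$center)
  list(sites = nrow(sites))
}

make_provider <- function(config, sites) {
  p <- config$provider
  switch(p$type,
    mock = {
      panos <- mock_panos_from_sites(
        sites, coverage = p$coverage %||% 1, offset_sd = p$offset_sd %||% 5,
        seed = child_seed(config$seed, "panos"))
      mock_provider(panos, seed = child_seed(config$seed, "provider"),
                    quota = p$quota %||% 100000L,
                    green_fraction_range = p$green_fraction_range %||% c(0, 0.6))
    },
    local = local_provider(p$root, quota = p$quota %||% 100000L),
    live = live_provider(p$key %||% "", quota = p$quota %||% 100000L),
    abort(sprintf("unknown provider type '%s'", p$type)))
}

stage_fetch <- function(f, config) {
  sites <- read_sites_csv(f$sites)
  if (identical(config$provider$type, "none")) {
    if (!file.exists(f$inventory)) {
      abort("provider 'none' expects a pre-populated inventory.csv and images/")
    }
    inv <- utils::read.csv(f$inventory)
    return(list(rows = nrow(inv), skipped = TRUE))
  }
  provider <- make_provider(config, sites)
  inv <- build_inventory(sites, provider,
                         search_radius = config$search_radius,
                         image_dir = f$images,
                         width = config$image_width,
                         height = config$image_height)
  utils::write.csv(inv, f$inventory, row.names = FALSE)
  list(rows = nrow(inv), ok = sum(inv$status == "ok"),
       missing = sum(inv$status == "missing"),
       errors = sum(inv$status == "error"))
}

stage_gvi <- function(f, config) {
  inv <- as_tibble(utils::read.csv(f$inventory, stringsAsFactors = FALSE))
  rng <- green_range(config$green_range[1], config$green_range[2])
  res <- gvi_table(inv, f$images, range = rng)
  utils::write.csv(res$images, f$gvi, row.names = FALSE)
  utils::write.csv(res$sites, f$sites_gvi, row.names = FALSE)
  list(images_scored = sum(!is.na(res$images$gvi)),
       sites_scored = nrow(res$sites))
}

stage_aggregate <- function(f, config) {
  net <- read_streets_geojson(f$network)
  sg <- as_tibble(utils::read.csv(f$sites_gvi, stringsAsFactors = FALSE))
  seg <- aggregate_segments(sg, net)
  scheme <- buffer_scheme(net$road_class, config$buffer_min, config$buffer_max)
  blocks <- delineate_blocks(net, scheme, resolution = config$block_resolution)
  blocks <- if (nrow(blocks) > 0) assign_sites_to_blocks(sg, blocks) else blocks
  kept <- filter_units(seg, blocks,
                       min_sites_per_km = config$min_sites_per_km,
                       min_area_ha = config$min_area_ha,
                       min_sites_per_ha = config$min_sites_per_ha)
  utils::write.csv(seg, f$segment_stats, row.names = FALSE)
  write_streets_geojson(net, f$segments_geojson, extra_properties =
    seg %>% mutate(category = as.character(.data$category)) %>%
      select("segment_id", "n_sites", "gvi_mean", "gvi_sd", "category"))
  utils::write.csv(
    blocks %>% select(-dplyr::any_of(c("boundary", "boundary_cells"))) %>%
      mutate(category = as.character(.data$category)),
    f$blocks, row.names = FALSE)
  write_blocks_geojson(blocks, f$blocks_geojson)
  list(segments = nrow(seg), segments_kept = nrow(kept$segments),
       blocks = nrow(blocks), blocks_kept = nrow(kept$blocks))
}

stage_citystats <- function(f, config) {
  sg <- as_tibble(utils::read.csv(f$sites_gvi, stringsAsFactors = FALSE))
  if (!"city_id" %in% names(sg)) sg$city_id <- "city1"
  cs <- summarize_city(sg)
  if (nrow(cs) >= 2) cs <- classify_cities(cs)
  utils::write.csv(cs, f$city_summary, row.names = FALSE)
  list(cities = nrow(cs))
}
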