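# greenview

Street greenery — the vegetation a pedestrian actually sees — is poorly
captured by planning quantities like green coverage. `greenview` implements
an automatic framework for measuring it from street-level imagery: street
centerlines are simplified, sample sites are placed every 50 m, four
directional photographs per site are acquired through a pluggable provider,
and each image is scored with the **Green View Index (GVI)** — the fraction
of pixels whose HSV hue falls in a green range:

```
GVI(image) = (1/N) * #{ pixels p : 60° ≤ hue(p) < 180° }
GVI(site)  = mean over the (up to 4) directional images at the site
```

Site GVIs aggregate upward to street segments (mean, population SD,
location density), to blocks (polygons left when class-dependent street
buffers of 2–30 m half-width are subtracted from the study area, each site
assigned to its nearest block), and to cities (ranking, a four-type
mean/spread typology, global Moran's I, and standardized OLS regressions of
location GVI on street- and city-level covariates, with backward
elimination by administrative level).

The package is aimed at urban analytics researchers who want a desk-scale,
fully offline-testable implementation: synthetic generators produce street
scenes with exact per-pixel vegetation masks, street networks with the
defects of real centerline data (dual carriageways, dangles, pseudo-nodes),
and multi-city regression panels with known standardized effects.

## Worked example

A 3×3 synthetic street grid (200 m spacing) with two dangling stubs and a
quarter of its streets digitized as dual carriageways, scored through the
mock image provider:

```r
library(greenview)

raw <- make_street_grid(network_spec(
  grid_rows = 3, grid_cols = 3, spacing = 200,
  dual_carriageway_fraction = 0.25, carriageway_offset = 16,
  dangle_count = 2, seed = 42))
nrow(raw)                                    # 17 raw segments

net <- preprocess_streets(raw, merge_distance = 30)
nrow(net); network_length(net)               # 12 segments, 2400 m

sites <- sample_points(net, interval = 50)   # 60 sites (5 per 200 m street)

prov <- mock_provider(mock_panos_from_sites(sites, seed = 1), seed = 7)
inv  <- build_inventory(sites, prov, image_dir = "imgs",
                        width = 160, height = 107)
res  <- gvi_table(inv, "imgs")
head(res$sites, 3)
#>   site_id           segment_id        x     y n_images   gvi category
#> 1 h_1_1/a+h_1_1/b:1 h_1_1/a+h_1_1/b   0     0        4 0.351 somewhat_green
#> 2 h_1_1/a+h_1_1/b:2 h_1_1/a+h_1_1/b  50     0        4 0.296 somewhat_green
#> 3 h_1_1/a+h_1_1/b:3 h_1_1/a+h_1_1/b 100     0        4 0.351 somewhat_green
```

The merged dual carriageway keeps its compound id (`a+b`); each site's GVI
is the mean of its four directional images, classified on the four-level
scale (not green ≤ 0.2 < somewhat green ≤ 0.4 < green ≤ 0.5 < very green).
Aggregation:

```r
aggregate_segments(res$sites, net)[1:3, ]
#>   segment_id      n_sites gvi_mean gvi_sd  sites_per_km category
#> 1 h_1_1/a+h_1_1/b       5    0.334  0.035            25 somewhat_green
#> 2 h_1_2                 5    0.304  0.117            25 somewhat_green
#> 3 h_2_1                 5    0.320  0.095            25 somewhat_green

blocks <- delineate_blocks(net, buffer_scheme(net$road_class, 2, 10),
                           resolution = 0.5)
assign_sites_to_blocks(res$sites, blocks)[, 1:5]
#>   block_id area_ha n_sites gvi_mean category
#> 1        1    3.24      24    0.331 somewhat_green
#> 2        2    3.24      14    0.317 somewhat_green
#> 3        3    3.24      14    0.318 somewhat_green
#> 4        4    3.24       8    0.318 somewhat_green
```

Each 180 m × 180 m interior block (200 m spacing minus two 10 m buffer
half-widths) is 3.24 ha; the four blocks partition the 60 sites, and the
site-count-weighted mean of block GVIs equals the global site mean
(0.3244). `filter_units()` then applies the density cuts (> 13 locations
per km for segments; > 1 ha and > 1 location per ha for blocks) used before
any statistical analysis.

For multi-city statistics, `summarize_city()`, `classify_cities()`,
`morans_i()` and `fit_location_models()` / `fit_by_level()` operate on
location tables such as those from `make_city_panel()`; fitted models come
back as tidy tibbles via `tidy()` and `glance()`.

A staged, resumable pipeline (`run_pipeline()` / `run_stage()`, or the
`inst/cli/greenview.R` script with a YAML config) writes every intermediate
artifact — processed network, site list, crawl inventory, GVI tables,
segment/block layers, city summary — as inspectable GeoJSON/CSV files with
a digest-checked manifest.

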