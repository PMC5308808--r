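# City-level analysis: summaries, the mean/spread typology, global Moran's
# I spatial autocorrelation, and standardized OLS regression of
# location-level GVI with backward elimination by administrative level.

#' Per-city GVI summary
#'
#' @param sites_gvi Tibble with `city_id` and `gvi` columns (one row per
#'   sample location).
#' @return Tibble: `city_id`, `n_sites`, `gvi_mean`, `gvi_sd` (population
#'   sd). Cities with no sites are absent; a warning reports them when the
#'   input carries factor levels with zero rows.
#' @export
summarize_city <- function(sites_gvi) {
  sites_gvi %>%
    group_by(.data$city_id) %>%
    summarise(n_sites = dplyr::n(), gvi_mean = mean(.data$gvi),
              gvi_sd = pop_sd(.data$gvi), .groups = "drop")
}

#' Classify cities into the four mean/spread types
#'
#' The reference pair is the cross-city average of city means and of city
#' standard deviations (unless given). "High average" means a city mean
#' strictly above the reference mean; "high spread" a city sd strictly
#' above the reference sd -- boundary ties are assigned Low on both axes.
#'
#' @param summaries From [summarize_city()] (needs >= 2 cities), or any
#'   tibble with `city_id`, `gvi_mean`, `gvi_sd`.
#' @param reference Optional `c(mean, sd)` reference pair overriding the
#'   cross-city averages.
#' @return `summaries` with a `type` factor added: `HighAvgLowStd`,
#'   `LowAvgLowStd`, `HighAvgHighStd`, `LowAvgHighStd`.
#' @export
#' @examples
#' s <- tibble::tibble(city_id = c("a", "b"), gvi_mean = c(0.30, 0.25),
#'                     gvi_sd = c(0.10, 0.15))
#' classify_cities(s, reference = c(0.276, 0.128))$type
classify_cities <- function(summaries, reference = NULL) {
  if (nrow(summaries) < 2 && is.null(reference)) {
    abort("need >= 2 cities (or an explicit reference pair)")
  }
  ref <- reference %||% c(mean(summaries$gvi_mean), mean(summaries$gvi_sd))
  high_avg <- summaries$gvi_mean > ref[1]
  high_std <- summaries$gvi_sd > ref[2]
  summaries$type <- factor(
    dplyr::case_when(
      high_avg & !high_std ~ "HighAvgLowStd",
      !high_avg & !high_std ~ "LowAvgLowStd",
      high_avg & high_std ~ "HighAvgHighStd",
      TRUE ~ "LowAvgHighStd"),
    levels = c("HighAvgLowStd", "LowAvgLowStd", "HighAvgHighStd",
               "LowAvgHighStd"))
  attr(summaries, "reference") <- ref
  summaries
}

# ---- Moran's I -----------------------------------------------------------

# Row-standardized k-nearest-neighbor weight matrix on point coordinates.
knn_weights <- function(x, y, k = 8) {
  n <- length(x)
  if (k >= n) abort("k must be smaller than the number of points")
  d <- as.matrix(stats::dist(cbind(x, y)))
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- setdiff(order(d[i, ]), i)[seq_len(k)]
    w[i, nb] <- 1
  }
  w / rowSums(w)
}

# The bare Moran statistic for a given weight matrix.
moran_stat <- function(values, w) {
  z <- values - mean(values)
  n <- length(z)
  s0 <- sum(w)
  (n / s0) * sum(w * outer(z, z)) / sum(z^2)
}

#' Global Moran's I with analytic z-score and permutation null
#'
#' Computes Moran's I for values observed at point locations using
#' row-standardized k-nearest-neighbor weights (the weight structure is a
#' configuration choice; inverse-distance weights are available). The
#' z-score uses the expectation `-1/(n-1)` and the variance under the
#' normality assumption; a permutation p-value (values shuffled across
#' locations) is returned alongside.
#'
#' @param x,y Point coordinates.
#' @param values Numeric attribute (non-constant).
#' @param k Neighbors for the knn weights (default 8).
#' @param weights Optional explicit weight matrix (overrides `k`); rows are
#'   re-standardized.
#' @param permutations Number of value permutations for the empirical null
#'   (default 999; 0 skips it).
#' @param seed RNG seed for the permutations.
#' @return A `gv_moran` list: `I`, `expected`, `sd_norm`, `z`, `p_norm`
#'   (two-sided), `p_perm`, `n`, `k`.
#' @export
morans_i <- function(x, y, values, k = 8, weights = NULL,
                     permutations = 999, seed = 1L) {
  n <- length(values)
  if (n < 8) abort("need at least 8 points")
  if (sd(values) == 0) abort("constant values: Moran's I undefined")
  w <- if (is.null(weights)) knn_weights(x, y, k) else {
    sweep(weights, 1, pmax(rowSums(weights), .Machine$double.eps), `/`)
  }
  I <- moran_stat(values, w)
  e <- -1 / (n - 1)
  # variance under normality
  s0 <- sum(w)
  s1 <- sum((w + t(w))^2) / 2
  s2 <- sum((rowSums(w) + colSums(w))^2)
  v <- (n^2 * s1 - n * s2 + 3 * s0^2) / (s0^2 * (n^2 - 1)) - e^2
  z <- (I - e) / sqrt(v)
  p_norm <- 2 * pnorm(-abs(z))
  p_perm <- NA_real_
  if (permutations > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    null_I <- vapply(seq_len(permutations), function(...) {
      moran_stat(sample(values), w)
    }, numeric(1))
    p_perm <- (1 + sum(abs(null_I - e) >= abs(I - e))) / (permutations + 1)
  }
  structure(list(I = I, expected = e, sd_norm = sqrt(v), z = z,
                 p_norm = p_norm, p_perm = p_perm, n = n,
                 k = if (is.null(weights)) k else NA_integer_),
            class = "gv_moran")
}

#' @export
print.gv_moran <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f), z = %.2f, p_norm = %.4g, p_perm = %.4g\n",
              x$I, x$expected, x$z, x$p_norm, x$p_perm))
  invisible(x)
}

#' @method tidy gv_moran
#' @export
tidy.gv_moran <- function(x, ...) {
  tibble(statistic = x$I, expected = x$expected, std.error = x$sd_norm,
         z = x$z, p.value = x$p_norm, p.permutation = x$p_perm, n = x$n)
}

# ---- standardized OLS ----------------------------------------------------

# z-score; constant columns come back all-zero (caller drops them first).
zscore <- function(v) {
  s <- sd(v)
  if (is.na(s) || s == 0) return(v * 0)
  (v - mean(v)) / s
}

# Core standardized fit: z-scored response and predictors, OLS via lm.
fit_standardized <- function(data, response, predictors, model_id = "model") {
  zero_var <- predictors[vapply(predictors, function(p)
    sd(data[[p]]) == 0, logical(1))]
  used <- setdiff(predictors, zero_var)
  df <- as.data.frame(lapply(data[c(response, used)], zscore))
  qx <- qr(as.matrix(cbind(1, df[used])))
  if (qx$rank < length(used) + 1L) {
    cm <- abs(cor(df[used]))
    diag(cm) <- 0
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    abort(sprintf("rank-deficient design; most collinear pair: %s, %s",
                  used[worst[1]], used[worst[2]]))
  }
  fml <- stats::as.formula(paste(response, "~",
                                 if (length(used) == 0) "1" else
                                   paste(used, collapse = " + ")))
  fit <- lm(fml, data = df)
  structure(list(fit = fit, model_id = model_id, response = response,
                 predictors = used, dropped = zero_var,
                 n = nrow(df)),
            class = "gv_fit")
}

#' @export
print.gv_fit <- function(x, ...) {
  cat(sprintf("<standardized OLS '%s': n = %d, adj R^2 = %.4f>\n",
              x$model_id, x$n, summary(x$fit)$adj.r.squared))
  print(tidy(x))
  invisible(x)
}

#' Tidy a standardized GVI regression
#'
#' @param x A `gv_fit` from [fit_location_models()] or [fit_by_level()].
#' @param ... Unused.
#' @return Tibble: `term`, `estimate` (standardized coefficient),
#'   `std.error`, `statistic`, `p.value`, `significant` (p <= 0.05).
#' @method tidy gv_fit
#' @export
tidy.gv_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  out <- tibble(term = rownames(sm), estimate = sm[, 1],
                std.error = sm[, 2], statistic = sm[, 3], p.value = sm[, 4])
  out <- out[out$term != "(Intercept)", ]
  out$significant <- out$p.value <= 0.05
  out
}

#' @rdname tidy.gv_fit
#' @method glance gv_fit
#' @export
glance.gv_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(model = x$model_id, adj.r.squared = sm$adj.r.squared,
         r.squared = sm$r.squared, n = x$n,
         n.predictors = length(x$predictors),
         dropped = paste(x$dropped, collapse = ","))
}

# Predictor sets of the three nested location-level models: Model 1 street
# attributes only, Model 2 adds city controls, Model 3 adds region dummies.
location_model_predictors <- function(model) {
  m1 <- c("CENTER", "LENGTH")
  m2 <- c(m1, "SIZE", "LEVEL", "DENSITY", "ECONOMY", "ELEVATION", "WATER")
  m3 <- c(m2, "MIDDLE", "WEST")
  switch(as.character(model), "1" = m1, "2" = m2, "3" = m3,
         abort("model must be 1, 2 or 3"))
}

#' Fit the nested location-level GVI regressions
#'
#' Standardized OLS of location GVI on street-level predictors (Model 1:
#' CENTER, LENGTH), plus city-level controls (Model 2: SIZE, LEVEL,
#' DENSITY, ECONOMY, ELEVATION, WATER), plus region dummies (Model 3:
#' MIDDLE, WEST). LEVEL enters as a numeric ordinal. Response and
#' predictors are z-scored, so coefficients are standardized and
#' comparable across variables.
#'
#' @param records Location tibble with `GVI` and the model variables (e.g.
#'   from [make_city_panel()]).
#' @param model 1, 2 or 3.
#' @return A `gv_fit`; see [tidy.gv_fit()] and [glance.gv_fit()].
#' @export
fit_location_models <- function(records, model = 3) {
  preds <- location_model_predictors(model)
  missing <- setdiff(preds, names(records))
  if (length(missing) > 0) {
    abort(paste("records lack variables:", paste(missing, collapse = ", ")))
  }
  fit_standardized(records, "GVI", preds,
                   model_id = paste0("model", model))
}

#' Backward-elimination regression within one administrative level
#'
#' Records are filtered to one city level; LEVEL itself (constant within
#' the subset) and any other zero-variance covariates are dropped up
#' front. Starting from the full Model 3 predictor set, the least
#' significant predictor (largest p-value) is removed one at a time until
#' every remaining predictor has `p <= threshold`.
#'
#' @param records Location tibble (as for [fit_location_models()]) with a
#'   `LEVEL_raw` or unstandardized `LEVEL` column identifying the tier, or
#'   pre-filtered records with `level = NULL`.
#' @param level Administrative tier to keep (matched against `LEVEL_raw`
#'   when present, else `LEVEL`); `NULL` fits all records.
#' @param threshold Retention p-value (default 0.05).
#' @param min_records Refuse to fit below this many rows (default 30).
#' @return A `gv_fit` whose `eliminated` element records the removal order.
#' @export
fit_by_level <- function(records, level = NULL, threshold = 0.05,
                         min_records = 30) {
  if (!is.null(level)) {
    lv <- records[["LEVEL_raw"]] %||% records[["LEVEL"]]
    records <- records[lv == level, ]
  }
  if (nrow(records) < min_records) {
    abort(sprintf("only %d records at this level; need >= %d for a stable fit",
                  nrow(records), min_records))
  }
  preds <- setdiff(location_model_predictors(3), "LEVEL")
  preds <- intersect(preds, names(records))
  eliminated <- character()
  repeat {
    f <- fit_standardized(records, "GVI", preds, model_id =
                            paste0("level", level %||% "all", "_backward"))
    td <- tidy(f)
    if (nrow(td) == 0) break
    worst <- td[which.max(td$p.value), ]
    if (worst$p.value <= threshold) break
    preds <- setdiff(preds, worst$term)
    eliminated <- c(eliminated, worst$term)
  }
  f$eliminated <- eliminated
  f$threshold <- threshold
  f
}

#' Pairwise covariate correlation check
#'
#' Regression covariates should not be strongly correlated; reports all
#' pairwise Pearson correlations with a flag where `|r|` exceeds the
#' threshold.
#'
#' @param records Tibble of records.
#' @param variables Covariate names (default: all of [panel_variables()]
#'   present).
#' @param threshold Flagging level for `|r|` (default 0.7).
#' @return Tibble: `var1`, `var2`, `r`, `flagged`.
#' @export
check_covariate_correlations <- function(records, variables = NULL,
                                         threshold = 0.7) {
  vars <- variables %||% intersect(panel_variables(), names(records))
  if (length(vars) < 2) abort("need at least 2 covariates")
  cm <- cor(as.matrix(records[vars]))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  tibble(var1 = vars[idx[, 1]], var2 = vars[idx[, 2]],
         r = cm[idx]) %>%
    mutate(flagged = abs(.data$r) > threshold) %>%
    arrange(dplyr::desc(abs(.data$r)))
}

#' Coefficient plot for a standardized fit
#'
#' @param object A `gv_fit`.
#' @param ... Unused.
#' @return A ggplot dot-and-whisker chart of standardized coefficients
#'   with 95% confidence intervals.
#' @method autoplot gv_fit
#' @export
autoplot.gv_fit <- function(object, ...) {
  td <- tidy(object)
  td$term <- stats::reorder(td$term, td$estimate)
  ggplot(td, aes(.data$estimate, .data$term)) +
    geom_vline(xintercept = 0, linetype = 2, color = "grey50") +
    geom_errorbarh(aes(xmin = .data$estimate - 1.96 * .data$std.error,
                       xmax = .data$estimate + 1.96 * .data$std.error),
                   height = 0.2) +
    geom_point(aes(color = .data$significant)) +
    labs(x = "standardized coefficient", y = NULL,
         color = "p <= 0.05") +
    theme_minimal()
}
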