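#' Build a gridded burned-area table
#'
#' Gridded monthly burned area on a regular lat/lon grid, carried long:
#' columns `lat`, `lon` (cell centers), `year`, `month`, `value`.  `unit` is
#' either `"area"` (absolute burned area, e.g. Mha) or `"fraction"` (burned
#' fraction of the cell, aggregated with cos-latitude area weights).
#'
#' @param df Data frame with the columns above.
#' @param res_lat,res_lon Grid resolution in degrees.
#' @param unit `"area"` or `"fraction"`.
#' @return A `fs_ba` tibble with grid metadata attributes.
#' @export
gridded_ba <- function(df, res_lat, res_lon, unit = c("area", "fraction")) {
  unit <- match.arg(unit)
  need <- c("lat", "lon", "year", "month", "value")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("gridded BA lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$value < 0)) stop("burned area must be >= 0", call. = FALSE)
  if (unit == "fraction" && any(df$value > 1)) {
    stop("burned fraction must be <= 1", call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  attr(out, "res_lat") <- res_lat
  attr(out, "res_lon") <- res_lon
  attr(out, "unit") <- unit
  class(out) <- unique(c("fs_ba", class(out)))
  out
}

# relative cell area of a regular lat/lon cell (cos-latitude weighting)
cell_weight <- function(lat, res_lat, res_lon) {
  cos(lat * pi / 180) * res_lat * res_lon
}

#' Aggregate burned area to a coarser grid
#'
#' Coarse cells must tile an integer number of fine cells (`fact_lat` by
#' `fact_lon`).  Absolute burned areas sum (global totals conserved exactly);
#' burned fractions aggregate as cos-latitude area-weighted means.
#'
#' @param ba A `fs_ba` tibble.
#' @param fact_lat,fact_lon Integer coarsening factors.
#' @return A `fs_ba` tibble on the coarse grid.
#' @export
aggregate_ba <- function(ba, fact_lat, fact_lon = fact_lat) {
  stopifnot(inherits(ba, "fs_ba"))
  if (fact_lat < 1 || fact_lon < 1 ||
      fact_lat != round(fact_lat) || fact_lon != round(fact_lon)) {
    stop("coarsening factors must be positive integers", call. = FALSE)
  }
  res_lat <- attr(ba, "res_lat")
  res_lon <- attr(ba, "res_lon")
  unit <- attr(ba, "unit")
  lat0 <- min(ba$lat) - res_lat / 2
  lon0 <- min(ba$lon) - res_lon / 2
  ilat <- (ba$lat - res_lat / 2 - lat0) / res_lat
  ilon <- (ba$lon - res_lon / 2 - lon0) / res_lon
  if (any(abs(ilat - round(ilat)) > 1e-8) ||
      any(abs(ilon - round(ilon)) > 1e-8)) {
    stop("fine grid is not regular; cannot nest", call. = FALSE)
  }
  blat <- floor(round(ilat) / fact_lat)
  blon <- floor(round(ilon) / fact_lon)
  df <- dplyr::mutate(
    tibble::as_tibble(ba),
    .lat = lat0 + (blat + 0.5) * res_lat * fact_lat,
    .lon = lon0 + (blon + 0.5) * res_lon * fact_lon,
    .w = cell_weight(.data$lat, res_lat, res_lon)
  )
  agg <- df |>
    dplyr::group_by(lat = .data$.lat, lon = .data$.lon, .data$year,
                    .data$month)
  agg <- if (unit == "area") {
    dplyr::summarise(agg, value = sum(.data$value), .groups = "drop")
  } else {
    dplyr::summarise(agg, value = sum(.data$value * .data$.w) / sum(.data$.w),
                     .groups = "drop")
  }
  gridded_ba(agg, res_lat * fact_lat, res_lon * fact_lon, unit)
}

#' Burned-area change between two periods, by land-cover class
#'
#' For each class: mean annual burned area in period B minus period A, the
#' percent change relative to the period-A mean, and the uncertainty of the
#' change as the standard deviation of the paired year-to-year differences
#' (year k of B minus year k of A) divided by sqrt(n).  Periods must have
#' equal lengths so years pair by position.
#'
#' @param ba A `fs_ba` tibble (absolute areas recommended).
#' @param lc Land-cover map: tibble with `lat`, `lon`, `class`.
#' @param period_a,period_b Integer year vectors of equal length.
#' @return Tibble: `class`, `mean_a`, `mean_b`, `delta`, `pct`, `se`.
#' @export
ba_change_by_class <- function(ba, lc, period_a, period_b) {
  if (length(period_a) != length(period_b)) {
    stop("periods must have equal lengths (paired years)", call. = FALSE)
  }
  df <- dplyr::inner_join(tibble::as_tibble(ba), tibble::as_tibble(lc),
                          by = c("lat", "lon"))
  annual <- df |>
    dplyr::filter(.data$year %in% c(period_a, period_b)) |>
    dplyr::group_by(.data$class, .data$year) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop")
  per_class <- function(d) {
    a <- d$value[match(period_a, d$year)]
    b <- d$value[match(period_b, d$year)]
    a[is.na(a)] <- 0
    b[is.na(b)] <- 0
    diffs <- b - a
    tibble::tibble(mean_a = mean(a), mean_b = mean(b),
                   delta = mean(b) - mean(a),
                   pct = if (mean(a) == 0) NA_real_ else
                     100 * (mean(b) - mean(a)) / mean(a),
                   se = sd(diffs) / sqrt(length(diffs)))
  }
  annual |>
    dplyr::group_by(.data$class) |>
    dplyr::group_modify(~ per_class(.x)) |>
    dplyr::ungroup()
}

#' Percent-per-year trend of an annual series
#'
#' Ordinary least-squares slope of value against year, expressed as percent
#' of the period-mean value per year, with the two-sided p-value of the
#' slope's t statistic.  A constant series returns trend 0 with p = 1 by
#' convention.
#'
#' @param annual Tibble with columns `year` and `value`.
#' @return One-row tibble: `trend_pct_yr`, `slope`, `p_value`.
#' @export
percent_trend <- function(annual) {
  if (nrow(annual) < 3) stop("need at least 3 years", call. = FALSE)
  if (var(annual$value) == 0) {
    return(tibble::tibble(trend_pct_yr = 0, slope = 0, p_value = 1))
  }
  fit <- lm(value ~ year, data = annual)
  sm <- summary(fit)$coefficients
  slope <- sm["year", "Estimate"]
  p <- sm["year", "Pr(>|t|)"]
  tibble::tibble(trend_pct_yr = 100 * slope / mean(annual$value),
                 slope = slope, p_value = p)
}

#' Period means, spread, and change of an annual series
#'
#' @param annual Tibble with columns `year` and `value` (and optionally
#'   `sd`).
#' @param period_a,period_b Integer year vectors.
#' @return One-row tibble: per-period mean and across-year sd, and the
#'   difference of means.
#' @export
period_change <- function(annual, period_a, period_b) {
  a <- annual$value[annual$year %in% period_a]
  b <- annual$value[annual$year %in% period_b]
  if (!length(a) || !length(b)) stop("empty period", call. = FALSE)
  tibble::tibble(mean_a = mean(a), sd_a = sd(a),
                 mean_b = mean(b), sd_b = sd(b),
                 delta = mean(b) - mean(a))
}

#' Convert fire CO emissions to carbon emissions with uncertainty
#'
#' Per biome and year, C = CO * rho, where rho is the biome-specific ratio of
#' carbon to CO emission factors.  Relative uncertainties combine in
#' quadrature: (sd_C/C)^2 = (sd_CO/CO)^2 + (sd_rho/rho)^2; for a zero CO
#' value the absolute fallback sd_C = sd_CO * rho is used.  Totals across
#' biomes (per year) sum with independent-error quadrature.
#'
#' @param co Tibble with `biome`, `year`, `value`, `sd` (CO emissions).
#' @param ratios Tibble with `biome`, `ratio`, `sd`.
#' @return List with `by_biome` (carbon per biome-year) and `total` (per
#'   year).
#' @export
co_to_carbon <- function(co, ratios) {
  if (any(ratios$ratio <= 0)) stop("ratios must be > 0", call. = FALSE)
  if (any(co$sd <= 0) || any(ratios$sd < 0)) {
    stop("uncertainties must be positive", call. = FALSE)
  }
  df <- dplyr::inner_join(tibble::as_tibble(co),
                          dplyr::rename(tibble::as_tibble(ratios),
                                        ratio_sd = "sd"),
                          by = "biome")
  by_biome <- df |>
    dplyr::mutate(
      carbon = .data$value * .data$ratio,
      carbon_sd = ifelse(
        .data$value == 0,
        .data$sd * .data$ratio,
        abs(.data$carbon) * sqrt((.data$sd / .data$value)^2 +
                                   (.data$ratio_sd / .data$ratio)^2)
      )
    ) |>
    dplyr::select("biome", "year", "carbon", "carbon_sd")
  total <- by_biome |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(carbon = sum(.data$carbon),
                     carbon_sd = sqrt(sum(.data$carbon_sd^2)),
                     .groups = "drop")
  list(by_biome = by_biome, total = total)
}
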