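DELTA_VARS <- c("fire", "gpp", "ter", "nee", "nbe")

#' Fixed burned-area control forcing
#'
#' Replaces burned-area fractions inside the experiment window with the
#' per-calendar-month climatology of a baseline period (the mean of each
#' calendar month over the baseline years), leaving every other column and
#' every month outside the window untouched.  Using a monthly climatology
#' rather than an annual scalar preserves the fire seasonality.
#'
#' @param forcing Forcing tibble.
#' @param baseline_years Integer vector of baseline years (e.g. 2001:2007).
#' @param window_years Integer vector of window years whose burned area is
#'   overwritten (e.g. 2008:2014).
#' @return The modified forcing tibble.
#' @export
build_fixed_ba <- function(forcing, baseline_years, window_years) {
  forcing <- validate_forcing(forcing)
  if (!length(baseline_years) || !length(window_years)) {
    stop("baseline and window must be non-empty", call. = FALSE)
  }
  if (length(intersect(baseline_years, window_years))) {
    stop("baseline and window years overlap", call. = FALSE)
  }
  span <- unique(forcing$year)
  if (!all(c(baseline_years, window_years) %in% span)) {
    stop("baseline/window years outside the forcing span", call. = FALSE)
  }
  clim <- forcing |>
    dplyr::filter(.data$year %in% baseline_years) |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(ba_clim = mean(.data$ba_frac), .groups = "drop")
  in_win <- forcing$year %in% window_years
  forcing$ba_frac[in_win] <-
    clim$ba_clim[match(forcing$month[in_win], clim$month)]
  forcing
}

#' Extend a forcing series by recycling past years
#'
#' Appends `n_years` built from the `recycle_years` block repeated
#' cyclically (meteorology and burned area alike), so counterfactual pairs
#' can be run beyond the observation period under identical forcing.
#'
#' @param forcing Forcing tibble.
#' @param n_years Number of years to append (0 returns the input unchanged).
#' @param recycle_years Years to recycle; default the full span.
#' @return The extended forcing tibble.
#' @export
extend_forcing <- function(forcing, n_years,
                           recycle_years = unique(forcing$year)) {
  forcing <- validate_forcing(forcing)
  if (n_years < 0) stop("n_years must be >= 0", call. = FALSE)
  if (n_years == 0) return(forcing)
  span <- unique(forcing$year)
  if (!all(recycle_years %in% span)) {
    stop("recycle_years outside the forcing span", call. = FALSE)
  }
  last <- max(forcing$year)
  src_years <- rep_len(recycle_years, n_years)
  blocks <- purrr::imap(src_years, function(y, k) {
    b <- dplyr::filter(forcing, .data$year == y)
    b$year <- last + k
    b
  })
  validate_forcing(dplyr::bind_rows(forcing, blocks))
}

#' Paired counterfactual runs and ensemble delta series
#'
#' For each posterior draw the model is run under both forcings with the same
#' parameters and initial pools ("all else being equal"), and the monthly
#' flux differences (observed minus fixed) are aggregated into annual
#' per-draw series and ensemble quantiles (Q1, median, Q3) for FIRE, GPP,
#' TER, NEE and NBE.  By construction dNEE = dTER - dGPP and
#' dNBE = dNEE + dFIRE per draw.
#'
#' @param posterior A `fs_posterior` (use [posterior_from_draws()] for
#'   truth-parameter experiments).
#' @param forcing_obs,forcing_fixed The two forcings; must have equal length.
#' @param n_draws Number of posterior draws to use.
#' @param window_years Years of the experiment window (used for downstream
#'   window/legacy summaries).
#' @param seed Seed for the draw selection.
#' @param const Structural constants.
#' @return A `fs_delta` object with elements `monthly` (tibble: variable, t,
#'   year, month, q25, q50, q75), `annual` (tibble: variable, year, q25, q50,
#'   q75), `annual_draws` (tibble: draw, variable, year, value) and
#'   `window_years`.
#' @export
run_delta <- function(posterior, forcing_obs, forcing_fixed, n_draws = 100,
                      window_years = NULL, seed = 1,
                      const = model_constants()) {
  forcing_obs <- validate_forcing(forcing_obs)
  forcing_fixed <- validate_forcing(forcing_fixed)
  if (nrow(forcing_obs) != nrow(forcing_fixed)) {
    stop("the two forcings must have the same length", call. = FALSE)
  }
  n_avail <- nrow(posterior$samples)
  if (n_avail == 0) stop("empty posterior", call. = FALSE)
  set.seed(seed)
  idx <- if (n_draws >= n_avail) rep_len(seq_len(n_avail), n_draws) else
    sample.int(n_avail, n_draws)
  years <- forcing_obs$year
  ygroup <- match(years, unique(years))
  month_delta <- vector("list", n_draws)
  annual_rows <- vector("list", n_draws)
  for (k in seq_len(n_draws)) {
    ds <- posterior_draw_state(posterior, idx[k])
    t_obs <- simulate_carbon(forcing_obs, ds$params, ds$init, const)
    t_fix <- simulate_carbon(forcing_fixed, ds$params, ds$init, const)
    dm <- as.matrix(t_obs[, DELTA_VARS]) - as.matrix(t_fix[, DELTA_VARS])
    month_delta[[k]] <- dm
    ann <- rowsum(dm, ygroup)
    annual_rows[[k]] <- tibble::tibble(
      draw = k,
      year = rep(unique(years), times = length(DELTA_VARS)),
      variable = rep(DELTA_VARS, each = length(unique(years))),
      value = as.vector(ann)
    )
  }
  marr <- simplify2array(month_delta)  # month x var x draw
  mq <- apply(marr, c(1, 2), quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE)
  monthly <- tidyr::expand_grid(variable = DELTA_VARS,
                                t = seq_len(nrow(forcing_obs)))
  monthly$year <- years[monthly$t]
  monthly$month <- forcing_obs$month[monthly$t]
  monthly$q25 <- as.vector(mq[1, , ])
  monthly$q50 <- as.vector(mq[2, , ])
  monthly$q75 <- as.vector(mq[3, , ])

  annual_draws <- dplyr::bind_rows(annual_rows)
  annual <- annual_draws |>
    dplyr::group_by(.data$variable, .data$year) |>
    dplyr::summarise(q25 = quantile(.data$value, 0.25, names = FALSE),
                     q50 = median(.data$value),
                     q75 = quantile(.data$value, 0.75, names = FALSE),
                     .groups = "drop")
  out <- list(monthly = monthly[, c("variable", "t", "year", "month",
                                    "q25", "q50", "q75")],
              annual = annual, annual_draws = annual_draws,
              window_years = window_years)
  class(out) <- "fs_delta"
  out
}

#' @export
print.fs_delta <- function(x, ...) {
  cat("<fs_delta> ", length(unique(x$annual$year)), " years, ",
      max(x$annual_draws$draw), " draws; window ",
      if (is.null(x$window_years)) "unset" else
        paste(range(x$window_years), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Tidy an ensemble delta object
#' @param x A `fs_delta`.
#' @param ... Unused.
#' @return The annual quantile series as a tibble.
#' @export
tidy.fs_delta <- function(x, ...) x$annual

# annual median series of one variable, ordered by year
delta_median_series <- function(delta, variable) {
  d <- dplyr::filter(delta$annual, .data$variable == !!variable)
  dplyr::arrange(d, .data$year)[, c("year", "q50")]
}

#' Mean delta fluxes over legacy windows
#'
#' Windows are year ranges counted from the first year after the experiment
#' window (1 = first post-window year), matching the way legacy effects are
#' summarised after a disturbance perturbation ends.
#'
#' @param delta A `fs_delta` with `window_years` set.
#' @param windows List of length-2 integer vectors, e.g.
#'   `list(c(1, 5), c(6, 10), c(11, 20))`.
#' @param variables Delta variables to summarise.
#' @return Tibble: `window`, `variable`, mean of the annual Q1/median/Q3
#'   series over the window.
#' @export
legacy_window_means <- function(delta, windows = list(c(1, 5), c(6, 10),
                                                      c(11, 20)),
                                variables = DELTA_VARS) {
  if (is.null(delta$window_years)) {
    stop("delta has no window_years", call. = FALSE)
  }
  end_win <- max(delta$window_years)
  purrr::map_dfr(windows, function(w) {
    if (w[2] < w[1]) stop("empty window", call. = FALSE)
    yrs <- (end_win + w[1]):(end_win + w[2])
    d <- dplyr::filter(delta$annual, .data$year %in% yrs,
                       .data$variable %in% variables)
    if (!nrow(d)) stop("window outside the simulated horizon", call. = FALSE)
    d |>
      dplyr::group_by(.data$variable) |>
      dplyr::summarise(q25 = mean(.data$q25), q50 = mean(.data$q50),
                       q75 = mean(.data$q75), .groups = "drop") |>
      dplyr::mutate(window = paste0(w[1], "-", w[2]), .before = 1)
  })
}

#' Mean delta fluxes inside the experiment window
#'
#' @param delta A `fs_delta` with `window_years` set.
#' @param variables Delta variables to summarise.
#' @param stat `"median"` uses the ensemble median series, `"mean"` the
#'   per-draw mean (both reported by [tidy()]-style columns).
#' @return Tibble of window means per variable.
#' @export
window_means <- function(delta, variables = DELTA_VARS, stat = "median") {
  if (is.null(delta$window_years)) {
    stop("delta has no window_years", call. = FALSE)
  }
  d <- dplyr::filter(delta$annual, .data$year %in% delta$window_years,
                     .data$variable %in% variables)
  if (stat == "mean") {
    delta$annual_draws |>
      dplyr::filter(.data$year %in% delta$window_years,
                    .data$variable %in% variables) |>
      dplyr::group_by(.data$variable) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  } else {
    d |>
      dplyr::group_by(.data$variable) |>
      dplyr::summarise(value = mean(.data$q50), .groups = "drop")
  }
}

#' Years until net biome exchange returns to neutrality
#'
#' Finds the first year whose annual |dNBE| (ensemble median) falls below
#' `tolerance_frac` times the peak |dNBE|.  An all-zero series is neutral
#' from its first year.  The 5%-of-peak default operationalises "neutral";
#' it is configurable.
#'
#' @param delta A `fs_delta`, or a data frame with columns `year` and
#'   `value` (annual dNBE, any consistent year indexing).
#' @param tolerance_frac Fraction of the peak |dNBE| below which the series
#'   counts as neutral.
#' @return The year (in the series' own indexing; for a `fs_delta`, years
#'   since the window start with the start year = 1).  `NA` with a
#'   `"not reached"` attribute when the horizon is too short.
#' @export
nbe_neutrality_time <- function(delta, tolerance_frac = 0.05) {
  if (inherits(delta, "fs_delta")) {
    s <- delta_median_series(delta, "nbe")
    start <- if (!is.null(delta$window_years)) min(delta$window_years) else
      min(s$year)
    ser <- tibble::tibble(year = s$year - start + 1, value = s$q50)
    ser <- dplyr::filter(ser, .data$year >= 1)
  } else {
    ser <- tibble::tibble(year = delta$year, value = delta$value)
  }
  v <- abs(ser$value)
  peak <- max(v)
  if (peak == 0) return(ser$year[1])
  hit <- which(v <= tolerance_frac * peak)
  if (!length(hit)) {
    out <- NA_real_
    attr(out, "status") <- "not reached"
    return(out)
  }
  ser$year[hit[1]]
}
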