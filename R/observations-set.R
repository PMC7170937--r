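OBS_STREAMS <- c("lai", "gpp_anom", "biomass", "som", "fire_annual")

#' Assemble an observation set
#'
#' Observations are carried as a long tibble with columns `stream`, `time`,
#' `value`, `sd`.  Streams: `lai` (monthly leaf area index, `time` = month
#' index into the simulation), `gpp_anom` (monthly GPP anomaly z-scores, a
#' variability-only constraint in the spirit of SIF), `biomass` (one
#' time-mean wood+foliar stock, gC m-2), `som` (one time-mean soil organic
#' carbon stock, gC m-2), `fire_annual` (annual fire emissions, gC m-2 yr-1,
#' `time` = calendar year).  Any stream may be absent; its likelihood term is
#' simply skipped.
#'
#' @param lai,gpp_anom Optional tibbles with columns `time`, `value`, `sd`.
#' @param biomass,som Optional length-2 numeric `c(value, sd)`.
#' @param fire_annual Optional tibble with columns `time` (year), `value`,
#'   `sd`.
#' @return A validated `fs_observations` tibble.
#' @export
observation_set <- function(lai = NULL, gpp_anom = NULL, biomass = NULL,
                            som = NULL, fire_annual = NULL) {
  pieces <- list()
  series <- function(df, stream) {
    tibble::tibble(stream = stream, time = as.numeric(df$time),
                   value = as.numeric(df$value), sd = as.numeric(df$sd))
  }
  if (!is.null(lai)) pieces <- c(pieces, list(series(lai, "lai")))
  if (!is.null(gpp_anom)) pieces <- c(pieces, list(series(gpp_anom, "gpp_anom")))
  if (!is.null(biomass)) {
    pieces <- c(pieces, list(tibble::tibble(stream = "biomass", time = NA_real_,
                                            value = biomass[1], sd = biomass[2])))
  }
  if (!is.null(som)) {
    pieces <- c(pieces, list(tibble::tibble(stream = "som", time = NA_real_,
                                            value = som[1], sd = som[2])))
  }
  if (!is.null(fire_annual)) {
    pieces <- c(pieces, list(series(fire_annual, "fire_annual")))
  }
  if (!length(pieces)) {
    out <- tibble::tibble(stream = character(), time = numeric(),
                          value = numeric(), sd = numeric())
  } else {
    out <- dplyr::bind_rows(pieces)
  }
  validate_observations(out)
}

#' Validate an observation set
#' @param obs Long observation tibble (`stream`, `time`, `value`, `sd`).
#' @return The classed `fs_observations` tibble.
#' @export
validate_observations <- function(obs) {
  need <- c("stream", "time", "value", "sd")
  missing <- setdiff(need, names(obs))
  if (length(missing)) {
    stop("observations lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!obs$stream %in% OBS_STREAMS)) {
    stop("unknown stream; allowed: ", paste(OBS_STREAMS, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(obs) && any(!is.finite(obs$sd) | obs$sd <= 0)) {
    stop("all observation sd must be > 0", call. = FALSE)
  }
  out <- tibble::as_tibble(obs)
  class(out) <- unique(c("fs_observations", class(out)))
  out
}

#' Read / write observation sets as CSV (long format)
#' @param path File path.
#' @return `read_observations_csv()` returns the validated tibble.
#' @export
read_observations_csv <- function(path) {
  validate_observations(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_observations_csv
#' @param obs Observation tibble.
#' @export
write_observations_csv <- function(obs, path) {
  readr::write_csv(validate_observations(obs), path)
  invisible(path)
}

#' Gaussian log-likelihood of a trajectory given observations
#'
#' Independent Gaussian terms per stream: modelled LAI is foliar/lcma;
#' modelled GPP anomalies are the z-scores of the monthly GPP series (so only
#' variability, not magnitude, constrains the model); biomass and SOM are
#' time means of wood+foliar and of SOM; fire is compared as annual sums.
#' Streams absent from `obs` contribute nothing (additivity).
#'
#' @param trajectory Trajectory tibble from [simulate_carbon()].
#' @param obs Observation tibble, see [observation_set()].
#' @param params Parameter vector (needed for `lcma`).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(trajectory, obs, params) {
  obs <- validate_observations(obs)
  p <- validate_params(params)
  ll <- 0
  by_stream <- split(obs, obs$stream)

  if (!is.null(by_stream$lai)) {
    o <- by_stream$lai
    mod <- trajectory$foliar[o$time] / p[["lcma"]]
    ll <- ll + sum(dnorm(o$value, mod, o$sd, log = TRUE))
  }
  if (!is.null(by_stream$gpp_anom)) {
    o <- by_stream$gpp_anom
    g <- trajectory$gpp
    sdg <- sd(g)
    z <- if (sdg > 0) (g - mean(g)) / sdg else rep(0, length(g))
    ll <- ll + sum(dnorm(o$value, z[o$time], o$sd, log = TRUE))
  }
  if (!is.null(by_stream$biomass)) {
    o <- by_stream$biomass
    mod <- mean(trajectory$wood + trajectory$foliar)
    ll <- ll + sum(dnorm(o$value, mod, o$sd, log = TRUE))
  }
  if (!is.null(by_stream$som)) {
    o <- by_stream$som
    ll <- ll + sum(dnorm(o$value, mean(trajectory$som), o$sd, log = TRUE))
  }
  if (!is.null(by_stream$fire_annual)) {
    o <- by_stream$fire_annual
    ann <- tapply(trajectory$fire, trajectory$year, sum)
    mod <- as.numeric(ann[as.character(o$time)])
    ll <- ll + sum(dnorm(o$value, mod, o$sd, log = TRUE))
  }
  ll
}
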