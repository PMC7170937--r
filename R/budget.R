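#' Validate a global carbon budget table
#'
#' Columns per year (all PgC yr-1): `e_ff` (fossil emissions), `e_luc`
#' (land-use change emissions), `g_atm` (atmospheric growth), `s_ocean`,
#' `s_land` (process-based sink estimates).
#'
#' @param budget Data frame with columns `year`, `e_ff`, `e_luc`, `g_atm`,
#'   `s_ocean`, `s_land`.
#' @return The validated tibble.
#' @export
validate_budget <- function(budget) {
  need <- c("year", "e_ff", "e_luc", "g_atm", "s_ocean", "s_land")
  missing <- setdiff(need, names(budget))
  if (length(missing)) {
    stop("budget lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(budget$e_ff + budget$e_luc <= 0)) {
    stop("total anthropogenic emissions must be > 0 each year", call. = FALSE)
  }
  tibble::as_tibble(budget)
}

#' Observed airborne fraction
#'
#' AF_obs = G_ATM / (E_FF + E_LUC): the share of anthropogenic emissions
#' remaining in the atmosphere.
#'
#' @param budget A budget table, see [validate_budget()].
#' @return Tibble with `year`, `af_obs`.
#' @export
af_observed <- function(budget) {
  b <- validate_budget(budget)
  tibble::tibble(year = b$year,
                 af_obs = b$g_atm / (b$e_ff + b$e_luc))
}

#' Process-explained airborne fraction
#'
#' AF_process = 1 - (S_OCEAN + S_LAND) / (E_FF + E_LUC): the airborne
#' fraction implied by the process-based sink estimates.  When the budget
#' closes exactly it equals [af_observed()].
#'
#' @inheritParams af_observed
#' @return Tibble with `year`, `af_process`.
#' @export
af_process <- function(budget) {
  b <- validate_budget(budget)
  tibble::tibble(year = b$year,
                 af_process = 1 - (b$s_ocean + b$s_land) / (b$e_ff + b$e_luc))
}

#' Airborne fraction adjusted for fire-decline impacts
#'
#' AF_adjusted = 1 - (S_OCEAN + S_LAND - dFIRE - dNEE) / (E_FF + E_LUC).
#' `dFIRE` and `dNEE` carry the counterfactual sign convention of
#' [run_delta()] (observed minus fixed burned area; negative values = extra
#' land sink), so negative deltas strengthen the effective sink and lower
#' the adjusted airborne fraction toward the observed one.
#'
#' @inheritParams af_observed
#' @param deltas Tibble with `year`, `d_fire`, `d_nee` (PgC yr-1).
#' @param anchor Optional: remove the mean of the delta series over these
#'   years before adjusting (expresses deltas relative to a reference
#'   period); `NULL` uses the deltas as given.
#' @return Tibble with `year`, `af_adjusted`.
#' @export
af_adjusted <- function(budget, deltas, anchor = NULL) {
  b <- validate_budget(budget)
  need <- c("year", "d_fire", "d_nee")
  if (!all(need %in% names(deltas))) {
    stop("deltas needs columns year, d_fire, d_nee", call. = FALSE)
  }
  d <- tibble::as_tibble(deltas)
  if (!setequal(b$year, d$year)) {
    stop("budget and delta years are misaligned", call. = FALSE)
  }
  d <- d[match(b$year, d$year), ]
  if (!is.null(anchor)) {
    ref <- d$year %in% anchor
    if (!any(ref)) stop("anchor years not in the delta series", call. = FALSE)
    d$d_fire <- d$d_fire - mean(d$d_fire[ref])
    d$d_nee <- d$d_nee - mean(d$d_nee[ref])
  }
  tibble::tibble(
    year = b$year,
    af_adjusted = 1 - (b$s_ocean + b$s_land - d$d_fire - d$d_nee) /
      (b$e_ff + b$e_luc)
  )
}

#' Bias and RMS of an airborne-fraction model series
#'
#' @param af_obs,af_model Numeric series of equal length.
#' @return One-row tibble: `bias` (mean of model minus observed) and `rms`
#'   (root-mean-square residual).
#' @export
af_metrics <- function(af_obs, af_model) {
  if (length(af_obs) != length(af_model)) {
    stop("series lengths differ", call. = FALSE)
  }
  r <- af_model - af_obs
  tibble::tibble(bias = mean(r), rms = sqrt(mean(r^2)))
}

#' Percent reduction in bias and RMS between two model series
#'
#' @param af_obs Observed series.
#' @param af_before,af_after Model series before and after an adjustment.
#' @return One-row tibble: `bias_reduction_pct`, `rms_reduction_pct`.
#' @export
af_improvement <- function(af_obs, af_before, af_after) {
  m0 <- af_metrics(af_obs, af_before)
  m1 <- af_metrics(af_obs, af_after)
  tibble::tibble(
    bias_reduction_pct = 100 * (abs(m0$bias) - abs(m1$bias)) / abs(m0$bias),
    rms_reduction_pct = 100 * (m0$rms - m1$rms) / m0$rms
  )
}

#' Read / write budget tables as CSV
#' @param path File path.
#' @return `read_budget_csv()` returns the validated budget tibble.
#' @export
read_budget_csv <- function(path) {
  validate_budget(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_budget_csv
#' @param budget Budget tibble.
#' @export
write_budget_csv <- function(budget, path) {
  readr::write_csv(validate_budget(budget), path)
  invisible(path)
}
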