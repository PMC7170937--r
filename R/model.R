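FLUX_NAMES <- c("gpp", "ra", "rh_litter", "rh_som", "fire",
                "mort_labile", "mort_foliar", "mort_root", "mort_wood",
                "npp", "ter", "nee", "nbe")

#' Gross primary production for a single month
#'
#' GPP = lue * APAR * g_T * days, with LAI = foliar / lcma, APAR =
#' 0.5 * sw_rad * (1 - exp(-k_ext * LAI)) (Beer-Lambert light interception of
#' the ~50% photosynthetically active share of shortwave radiation), and
#' g_T = exp(theta * (t_mean - t_ref)) capped at `gt_cap`.  GPP saturates at
#' lue * 0.5 * sw_rad * g_T * days as the canopy closes and is strictly
#' increasing in the foliar pool below saturation.
#'
#' @param foliar Foliar carbon, gC m-2 (vectorised).
#' @param params Parameter vector, see [default_params()].
#' @param met A list or one-row data frame with `t_mean`, `sw_rad`, `days`.
#' @param const Structural constants, see [model_constants()].
#' @return GPP in gC m-2 month-1.
#' @export
#' @examples
#' compute_gpp(90, default_params(),
#'             list(t_mean = 25, sw_rad = 20, days = 30))
compute_gpp <- function(foliar, params, met, const = model_constants()) {
  if (any(foliar < 0)) stop("foliar must be >= 0", call. = FALSE)
  p <- validate_params(params)
  g_t <- pmin(exp(p[["theta"]] * (met$t_mean - const$t_ref)), const$gt_cap)
  lai <- foliar / p[["lcma"]]
  apar <- 0.5 * met$sw_rad * (1 - exp(-const$k_ext * lai))
  p[["lue"]] * apar * g_t * met$days
}

#' Apply one month of fire to a pool state
#'
#' Each pool loses `C_i * ba_frac * cc_i` to combustion (the labile and
#' fine-root pools share the foliar combustion completeness; wood uses the
#' structural factor).  In addition each live pool transfers
#' `C_i * ba_frac * (1 - cc_i) * (1 - resilience)` to litter as fire-induced
#' mortality.  The fire emission is the sum of the combustion terms.
#'
#' @param state Named pool vector.
#' @param ba_frac Burned fraction of the cell, in \[0, 1\].
#' @param params Parameter vector.
#' @return List with elements `state` (post-fire pools), `emission`
#'   (gC m-2 month-1) and `mortality` (named vector, live pools).
#' @export
#' @examples
#' st <- default_init(foliar = 200, wood = 1000, litter = 300, som = 5000)
#' apply_fire(st, 0.1, default_params())$emission
apply_fire <- function(state, ba_frac, params) {
  if (length(ba_frac) != 1 || is.na(ba_frac) || ba_frac < 0 || ba_frac > 1) {
    stop("ba_frac must be a single value in [0, 1]", call. = FALSE)
  }
  s <- validate_state(state)
  p <- validate_params(params)
  cc <- c(labile = p[["cc_foliar"]], foliar = p[["cc_foliar"]],
          fine_root = p[["cc_foliar"]], wood = p[["cc_wood"]])
  live <- names(cc)
  comb_live <- s[live] * ba_frac * cc
  mort <- s[live] * ba_frac * (1 - cc) * (1 - p[["resilience"]])
  comb_litter <- s[["litter"]] * ba_frac * p[["cc_litter"]]
  comb_som <- s[["som"]] * ba_frac * p[["cc_som"]]
  s[live] <- s[live] - comb_live - mort
  s[["litter"]] <- s[["litter"]] - comb_litter + sum(mort)
  s[["som"]] <- s[["som"]] - comb_som
  list(state = s,
       emission = unname(sum(comb_live) + comb_litter + comb_som),
       mortality = mort)
}

#' Advance the carbon model by one month (reference implementation)
#'
#' Pure-R single step in the documented order: (1) GPP and Ra = f_auto * GPP,
#' (2) NPP allocation with labile release to foliar, (3) turnover
#' (foliar/root to litter, wood to SOM), (4) decomposition scaled by the
#' temperature scalar g_T and the moisture scalar g_W = W / (W + w_half),
#' (5) fire, (6) water bucket.  Demanded outfluxes exceeding a pool are
#' scaled proportionally so the pool bottoms out at zero instead of erroring.
#' [simulate_carbon()] runs the same recursion in compiled code; this
#' function is the readable reference the compiled path is tested against.
#'
#' @inheritParams apply_fire
#' @param met A list or one-row data frame with `t_mean`, `precip`, `sw_rad`,
#'   `days`.
#' @param const Structural constants.
#' @return List with `state` (month-end pools) and `fluxes` (named vector:
#'   gpp, ra, rh_litter, rh_som, fire, mortality per live pool, npp, ter,
#'   nee, nbe).
#' @export
step_carbon <- function(state, params, met, ba_frac,
                        const = model_constants()) {
  s <- validate_state(state)
  p <- validate_params(params)

  gpp <- unname(compute_gpp(s[["foliar"]], p, met, const))
  ra <- p[["f_auto"]] * gpp
  npp <- gpp - ra
  g_t <- min(exp(p[["theta"]] * (met$t_mean - const$t_ref)), const$gt_cap)
  g_w <- s[["water"]] / (s[["water"]] + p[["w_half"]])

  rel <- min(p[["labile_release"]] * s[["labile"]], s[["labile"]])
  tof <- min(p[["turn_foliar"]] * s[["foliar"]], s[["foliar"]])
  tor <- min(p[["turn_root"]] * s[["fine_root"]], s[["fine_root"]])
  tow <- min(p[["turn_wood"]] * s[["wood"]], s[["wood"]])
  rate_rh <- p[["decomp_litter"]] * g_t * g_w
  rate_l2s <- p[["lit2som"]] * g_t * g_w
  demand <- (rate_rh + rate_l2s) * s[["litter"]]
  if (demand > s[["litter"]] && demand > 0) {
    sc <- s[["litter"]] / demand
    rate_rh <- rate_rh * sc
    rate_l2s <- rate_l2s * sc
  }
  rh_litter <- rate_rh * s[["litter"]]
  tosom <- rate_l2s * s[["litter"]]
  rh_som <- min(p[["decomp_som"]] * g_t * g_w * s[["som"]], s[["som"]])

  alloc_wood <- 1 - p[["alloc_foliar"]] - p[["alloc_labile"]] - p[["alloc_root"]]
  s[["labile"]] <- s[["labile"]] + p[["alloc_labile"]] * npp - rel
  s[["foliar"]] <- s[["foliar"]] + p[["alloc_foliar"]] * npp + rel - tof
  s[["fine_root"]] <- s[["fine_root"]] + p[["alloc_root"]] * npp - tor
  s[["wood"]] <- s[["wood"]] + alloc_wood * npp - tow
  s[["litter"]] <- s[["litter"]] + tof + tor - rh_litter - tosom
  s[["som"]] <- s[["som"]] + tow + tosom - rh_som

  burn <- apply_fire(s, ba_frac, p)
  s <- burn$state

  s[["water"]] <- min(max(s[["water"]] + met$precip - const$evap_coef * gpp,
                          0), const$w_max)

  ter <- ra + rh_litter + rh_som
  fluxes <- c(gpp = gpp, ra = ra, rh_litter = rh_litter, rh_som = rh_som,
              fire = burn$emission,
              mort_labile = unname(burn$mortality[["labile"]]),
              mort_foliar = unname(burn$mortality[["foliar"]]),
              mort_root = unname(burn$mortality[["fine_root"]]),
              mort_wood = unname(burn$mortality[["wood"]]),
              npp = npp, ter = ter, nee = ter - gpp,
              nbe = ter - gpp + burn$emission)
  list(state = s, fluxes = fluxes)
}

#' Simulate the carbon model over a forcing series
#'
#' Deterministic monthly recursion over the whole forcing series using the
#' compiled core.  Month-over-month change of total carbon equals
#' GPP - Ra - Rh_litter - Rh_som - fire for every month (mass closure).
#'
#' @param forcing A forcing tibble, see [forcing_series()].
#' @param params Parameter vector.
#' @param init Initial pool state, see [default_init()].
#' @param const Structural constants.
#' @return A `fs_trajectory` tibble: one row per month with `year`, `month`,
#'   the month-end pools, and all component fluxes (gC m-2 month-1).
#' @export
#' @examples
#' f <- forcing_series(rep(25, 12), rep(80, 12), rep(20, 12), rep(0.02, 12))
#' traj <- simulate_carbon(f, default_params(), default_init())
#' traj[1, c("gpp", "fire", "nee")]
simulate_carbon <- function(forcing, params, init = default_init(),
                            const = model_constants()) {
  forcing <- validate_forcing(forcing)
  p <- validate_params(params)
  s0 <- validate_state(init)
  res <- .sim_core(unname(p), unname(s0), forcing_matrix(forcing),
                   const$k_ext, const$t_ref, const$gt_cap, const$w_max,
                   const$evap_coef)
  states <- res$states
  fluxes <- res$fluxes
  colnames(states) <- POOL_NAMES
  colnames(fluxes) <- FLUX_NAMES
  out <- dplyr::bind_cols(
    forcing[, c("year", "month")],
    tibble::as_tibble(as.data.frame(states)),
    tibble::as_tibble(as.data.frame(fluxes))
  )
  attr(out, "params") <- p
  attr(out, "init") <- s0
  class(out) <- unique(c("fs_trajectory", class(out)))
  out
}

#' Annual flux totals (and optional global aggregation)
#'
#' Sums monthly fluxes to calendar years; requires whole years.  If `area_m2`
#' is given, per-area fluxes (gC m-2 yr-1) are also expressed as absolute
#' totals in PgC yr-1 (`* area_m2 * 1e-15`).
#'
#' @param trajectory A trajectory tibble from [simulate_carbon()].
#' @param area_m2 Optional cell area in m2.
#' @return Tibble of yearly flux sums, one row per year.
#' @export
annualize <- function(trajectory, area_m2 = NULL) {
  counts <- table(trajectory$year)
  if (any(counts != 12)) {
    stop("annualize() requires complete 12-month years", call. = FALSE)
  }
  out <- trajectory |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(FLUX_NAMES), sum),
                     .groups = "drop")
  if (!is.null(area_m2)) {
    pg <- dplyr::mutate(out, dplyr::across(dplyr::all_of(FLUX_NAMES),
                                           ~ .x * area_m2 * 1e-15))
    names(pg)[-1] <- paste0(FLUX_NAMES, "_pgc")
    out <- dplyr::bind_cols(out, pg[-1])
  }
  out
}

#' Area-weighted aggregation of per-cell annual fluxes
#'
#' @param annual_by_cell Tibble with columns `year`, a flux column, and
#'   `area_m2` per cell-year.
#' @param flux Name of the flux column.
#' @return Tibble of `year`, global total in PgC yr-1.
#' @export
global_total <- function(annual_by_cell, flux = "fire") {
  annual_by_cell |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      pgc = sum(.data[[flux]] * .data$area_m2) * 1e-15,
      .groups = "drop"
    )
}
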