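# deterministic per-stream sub-seeds derived from one root seed, so adding a
# stream never perturbs the draws of existing streams
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 7919) %% 2147483647)
}

#' Configuration of the synthetic study
#'
#' Bundles everything the generators need: the seed, the study length, a
#' seasonal climate description (dry-tropics defaults), the burned-area
#' regime (mean annual burned fraction, dry-season concentration, the
#' decline factor between the first and second half of the study, and the
#' interannual coefficient of variation), the truth parameters and initial
#' pools, per-stream observation noise, and the spin-up length.
#'
#' @param seed Root seed; every generator derives deterministic sub-seeds
#'   from it.
#' @param n_years Study length in years (even, for two-period designs).
#' @param start_year First calendar year.
#' @param climate Named list: `t_mean`, `t_amp`, `t_iav` (deg C), `p_mean`,
#'   `p_amp` (mm month-1), `p_cv`, `sw_mean`, `sw_amp` (MJ m-2 d-1),
#'   `sw_cv`.
#' @param ba_regime Named list: `mean_frac` (mean annual burned fraction),
#'   `peak_month`, `concentration` (seasonal concentration of burning),
#'   `decline_factor` in (0, 1\], `cv` (interannual).
#' @param truth Truth parameter vector.
#' @param init Initial pools fed to the spin-up.
#' @param noise Named list: `lai_sd` (absolute LAI units), `gpp_anom_sd`
#'   (z-score units), `biomass_rel_sd`, `som_rel_sd`, `fire_rel_sd`
#'   (relative).
#' @param spin_years Spin-up years discarded before the study window.
#' @return A `fs_synth_config` list.
#' @export
synth_config <- function(seed = 1, n_years = 14, start_year = 2001,
                         climate = list(), ba_regime = list(), noise = list(),
                         truth = default_params(), init = default_init(),
                         spin_years = 50) {
  if (n_years %% 2 != 0) {
    stop("n_years must be even for the two-period design", call. = FALSE)
  }
  clim <- utils::modifyList(
    list(t_mean = 25, t_amp = 4, t_iav = 0.3, p_mean = 80, p_amp = 70,
         p_cv = 0.1, sw_mean = 20, sw_amp = 3, sw_cv = 0.05),
    climate
  )
  ba <- utils::modifyList(
    list(mean_frac = 0.45, peak_month = 8, concentration = 2,
         decline_factor = 0.8, cv = 0.15),
    ba_regime
  )
  if (ba$decline_factor <= 0 || ba$decline_factor > 1) {
    stop("decline_factor must lie in (0, 1]", call. = FALSE)
  }
  nz <- utils::modifyList(
    list(lai_sd = 0.1, gpp_anom_sd = 0.3, biomass_rel_sd = 0.1,
         som_rel_sd = 0.15, fire_rel_sd = 0.1),
    noise
  )
  if (any(unlist(nz) <= 0)) stop("noise sds must be > 0", call. = FALSE)
  out <- list(seed = seed, n_years = n_years, start_year = start_year,
              climate = clim, ba_regime = ba, truth = validate_params(truth),
              init = validate_state(init), noise = nz,
              spin_years = spin_years)
  class(out) <- "fs_synth_config"
  out
}

#' Generate synthetic monthly forcing
#'
#' Sinusoidal seasonal cycles of temperature, precipitation and shortwave
#' radiation with lognormal (multiplicative, mean-one) interannual factors;
#' burning concentrated around a dry-season peak month with a von-Mises-like
#' seasonal profile.  Second-half annual burned-area levels are
#' `decline_factor` times the first-half levels (exactly so when the
#' interannual cv is zero), emulating a decadal fire decline between two
#' equal periods.  Deterministic under the config seed.
#'
#' @param config A [synth_config()].
#' @return A `fs_forcing` tibble of `12 * n_years` months.
#' @export
gen_forcing <- function(config) {
  stopifnot(inherits(config, "fs_synth_config"))
  cl <- config$climate
  ba <- config$ba_regime
  ny <- config$n_years
  m <- rep(1:12, ny)
  yi <- rep(seq_len(ny), each = 12)

  lognorm_factors <- function(cv, offset) {
    if (cv <= 0) return(rep(1, ny))
    set.seed(sub_seed(config$seed, offset))
    sdlog <- sqrt(log(1 + cv^2))
    rlnorm(ny, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  set.seed(sub_seed(config$seed, 1))
  t_anom <- rnorm(ny, 0, cl$t_iav)
  p_fac <- lognorm_factors(cl$p_cv, 2)
  sw_fac <- lognorm_factors(cl$sw_cv, 3)

  # wet season opposite the fire peak
  wet_peak <- (ba$peak_month + 5) %% 12 + 1
  t_mean <- cl$t_mean + cl$t_amp * cos(2 * pi * (m - ba$peak_month) / 12) +
    t_anom[yi]
  precip <- pmax(cl$p_mean + cl$p_amp * cos(2 * pi * (m - wet_peak) / 12),
                 0) * p_fac[yi]
  sw_rad <- pmax(cl$sw_mean + cl$sw_amp * cos(2 * pi * (m - ba$peak_month) /
                                                12), 0) * sw_fac[yi]

  w <- exp(ba$concentration * cos(2 * pi * (1:12 - ba$peak_month) / 12))
  w <- w / sum(w)
  decline <- ifelse(seq_len(ny) <= ny / 2, 1, ba$decline_factor)
  ba_fac <- lognorm_factors(ba$cv, 4)
  annual <- ba$mean_frac * decline * ba_fac
  ba_frac <- pmin(annual[yi] * w[m], 1)

  forcing_series(t_mean, precip, sw_rad, ba_frac,
                 start_year = config$start_year)
}

#' Truth run: spin-up plus study-window simulation
#'
#' Spins the model up for `spin_years` under the pre-decline (first-half)
#' forcing recycled, so pools start near the fire-inclusive quasi-steady
#' state, then simulates the study window.  The spun-up initial state is
#' attached as the `"init"` attribute.
#'
#' @param config A [synth_config()].
#' @param const Structural constants.
#' @return A `fs_trajectory` for the study window.
#' @export
gen_truth_run <- function(config, const = model_constants()) {
  forcing <- gen_forcing(config)
  first_half <- unique(forcing$year)[seq_len(config$n_years / 2)]
  base <- dplyr::filter(forcing, .data$year %in% first_half)
  init <- config$init
  if (config$spin_years > 0) {
    reps <- ceiling(config$spin_years / length(first_half))
    spin <- dplyr::bind_rows(replicate(reps, base, simplify = FALSE))
    spin <- spin[seq_len(config$spin_years * 12), ]
    spin$year <- config$start_year - config$spin_years +
      (seq_len(nrow(spin)) - 1) %/% 12
    spin_traj <- simulate_carbon(validate_forcing(spin), config$truth, init,
                                 const)
    last <- nrow(spin_traj)
    init <- setNames(as.numeric(spin_traj[last, POOL_NAMES]), POOL_NAMES)
  }
  out <- simulate_carbon(forcing, config$truth, init, const)
  attr(out, "init") <- init
  out
}

#' Pseudo-observations from a truth trajectory
#'
#' Adds the configured noise to the deterministic observation transforms of
#' the truth run: Gaussian noise on monthly LAI (= foliar / lcma) and on the
#' z-scored GPP series; relative Gaussian noise on the time-mean
#' wood+foliar stock, the time-mean SOM stock, and the annual fire sums.
#' The standard deviations actually used are recorded in the returned set.
#' With all noise set to ~0 the observations equal the truth transforms.
#'
#' @param truth A truth trajectory from [gen_truth_run()].
#' @param config The same [synth_config()].
#' @return A `fs_observations` tibble.
#' @export
gen_observations <- function(truth, config) {
  stopifnot(inherits(config, "fs_synth_config"))
  nz <- config$noise
  n <- nrow(truth)
  lcma <- config$truth[["lcma"]]

  set.seed(sub_seed(config$seed, 11))
  lai <- tibble::tibble(time = seq_len(n),
                        value = truth$foliar / lcma + rnorm(n, 0, nz$lai_sd),
                        sd = nz$lai_sd)
  set.seed(sub_seed(config$seed, 12))
  g <- truth$gpp
  z <- (g - mean(g)) / sd(g)
  gpp_anom <- tibble::tibble(time = seq_len(n),
                             value = z + rnorm(n, 0, nz$gpp_anom_sd),
                             sd = nz$gpp_anom_sd)
  set.seed(sub_seed(config$seed, 13))
  bio_true <- mean(truth$wood + truth$foliar)
  bio_sd <- nz$biomass_rel_sd * bio_true
  biomass <- c(bio_true + rnorm(1, 0, bio_sd), bio_sd)
  set.seed(sub_seed(config$seed, 14))
  som_true <- mean(truth$som)
  som_sd <- nz$som_rel_sd * som_true
  som <- c(som_true + rnorm(1, 0, som_sd), som_sd)
  set.seed(sub_seed(config$seed, 15))
  ann <- tapply(truth$fire, truth$year, sum)
  fire_sd <- nz$fire_rel_sd * as.numeric(ann)
  fire_annual <- tibble::tibble(
    time = as.numeric(names(ann)),
    value = as.numeric(ann) + rnorm(length(ann), 0, fire_sd),
    sd = fire_sd
  )
  observation_set(lai = lai, gpp_anom = gpp_anom, biomass = biomass,
                  som = som, fire_annual = fire_annual)
}

#' Generate a synthetic global carbon budget table
#'
#' Smoothly increasing fossil emissions, small land-use emissions, and sinks
#' constructed so the yearly budget residual
#' (E_FF + E_LUC - G_ATM - S_OCEAN - S_LAND) equals `imbalance` plus
#' year-to-year noise.  With `imbalance = 0` and `noise_sd = 0` the budget
#' closes and the process-explained airborne fraction equals the observed
#' one.
#'
#' @param seed Seed.
#' @param n_years Number of years.
#' @param imbalance Target residual, PgC yr-1 (scalar or per-year vector).
#' @param noise_sd Sd of the residual noise, PgC yr-1.
#' @param start_year First year.
#' @return A budget tibble, see [validate_budget()].
#' @export
gen_budget_table <- function(seed = 1, n_years = 14, imbalance = 0,
                             noise_sd = 0.05, start_year = 2001) {
  if (n_years < 1) stop("n_years must be >= 1", call. = FALSE)
  t <- seq_len(n_years) - 1
  set.seed(sub_seed(seed, 21))
  e_ff <- 8 + 0.25 * t + rnorm(n_years, 0, 0.05)
  set.seed(sub_seed(seed, 22))
  e_luc <- pmax(1.3 + rnorm(n_years, 0, 0.15), 0.5)
  tot <- e_ff + e_luc
  set.seed(sub_seed(seed, 23))
  g_atm <- 0.45 * tot + rnorm(n_years, 0, 0.4)
  set.seed(sub_seed(seed, 24))
  s_ocean <- 0.24 * tot + rnorm(n_years, 0, 0.1)
  set.seed(sub_seed(seed, 25))
  resid <- rep_len(imbalance, n_years) +
    (if (noise_sd > 0) rnorm(n_years, 0, noise_sd) else 0)
  s_land <- tot - g_atm - s_ocean - resid
  validate_budget(tibble::tibble(year = start_year + t, e_ff = e_ff,
                                 e_luc = e_luc, g_atm = g_atm,
                                 s_ocean = s_ocean, s_land = s_land))
}

#' The packaged savanna fire-decline reference scenario
#'
#' A frozen-seed dry-tropical-savanna setup: 14 study years split into two
#' 7-year periods with a 20% burned-area decline in the second period,
#' strongly seasonal burning, a short-residence-time woody pool, and the
#' default observation noise.  Everything downstream (fusion, counterfactual
#' scenarios, budget accounting) can run against it with known truth.
#'
#' @param const Structural constants.
#' @return List: `config`, `forcing`, `truth` (trajectory), `obs`, `params`
#'   (truth parameters), `init` (spun-up pools at the study start).
#' @export
fixture_savanna_decline <- function(const = model_constants()) {
  config <- synth_config(seed = 4242, n_years = 14)
  truth <- gen_truth_run(config, const)
  obs <- gen_observations(truth, config)
  list(config = config, forcing = gen_forcing(config), truth = truth,
       obs = obs, params = config$truth, init = attr(truth, "init"))
}
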