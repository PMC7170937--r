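test_that("burned-area decline between halves is exact when cv = 0", {
  cfg <- small_config(n_years = 6,
                      ba_regime = list(decline_factor = 0.8, cv = 0))
  f <- gen_forcing(cfg)
  ann <- tapply(f$ba_frac, f$year, sum)
  expect_equal(mean(ann[4:6]) / mean(ann[1:3]), 0.8, tolerance = 1e-12)

  none <- small_config(n_years = 6,
                       ba_regime = list(decline_factor = 1, cv = 0))
  fn <- gen_forcing(none)
  annn <- tapply(fn$ba_frac, fn$year, sum)
  expect_equal(unname(mean(annn[4:6]) / mean(annn[1:3])), 1, tolerance = 1e-12)
  expect_true(all(f$ba_frac >= 0 & f$ba_frac <= 1))
  expect_error(synth_config(ba_regime = list(decline_factor = 0)),
               "decline_factor")
  expect_error(synth_config(n_years = 7), "even")
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- gen_forcing(small_config(seed = 33))
  b <- gen_forcing(small_config(seed = 33))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$ba_frac, gen_forcing(small_config(seed = 34))$ba_frac))

  ta <- gen_truth_run(small_config(seed = 33))
  tb <- gen_truth_run(small_config(seed = 33))
  expect_identical(as.data.frame(ta), as.data.frame(tb))

  ba <- gen_budget_table(seed = 12, n_years = 5)
  bb <- gen_budget_table(seed = 12, n_years = 5)
  expect_identical(ba, bb)

  cfg <- small_config(seed = 33)
  oa <- gen_observations(ta, cfg)
  ob <- gen_observations(tb, cfg)
  expect_identical(as.data.frame(oa), as.data.frame(ob))
})

test_that("fire-free constant forcing settles at the analytic steady state", {
  # truly constant months (30-day months, no seasonality, no fire)
  n <- 300 * 12
  f <- forcing_series(rep(25, n), rep(80, n), rep(20, n), rep(0, n),
                      days = rep(30, n))
  p <- default_params()
  traj <- simulate_carbon(f, p, default_init())
  last <- nrow(traj)
  const <- model_constants()
  g_t <- min(exp(p[["theta"]] * (25 - 15)), const$gt_cap)
  g_w <- traj$water[last] / (traj$water[last] + p[["w_half"]])
  npp <- traj$npp[last]
  rel <- p[["labile_release"]] * traj$labile[last]
  inflow <- c(
    labile = p[["alloc_labile"]] * npp,
    foliar = p[["alloc_foliar"]] * npp + rel,
    fine_root = p[["alloc_root"]] * npp,
    wood = (1 - p[["alloc_foliar"]] - p[["alloc_labile"]] -
              p[["alloc_root"]]) * npp,
    litter = p[["turn_foliar"]] * traj$foliar[last] +
      p[["turn_root"]] * traj$fine_root[last],
    som = p[["turn_wood"]] * traj$wood[last] +
      p[["lit2som"]] * g_t * g_w * traj$litter[last]
  )
  outrate <- c(
    labile = p[["labile_release"]],
    foliar = p[["turn_foliar"]],
    fine_root = p[["turn_root"]],
    wood = p[["turn_wood"]],
    litter = (p[["decomp_litter"]] + p[["lit2som"]]) * g_t * g_w,
    som = p[["decomp_som"]] * g_t * g_w
  )
  expected <- inflow / outrate
  got <- unlist(traj[last, names(expected)])
  expect_equal(unname(got / expected), rep(1, 6), tolerance = 0.01)
})

test_that("noise-free observations equal the truth transforms", {
  cfg <- small_config(noise = list(lai_sd = 1e-12, gpp_anom_sd = 1e-12,
                                   biomass_rel_sd = 1e-12, som_rel_sd = 1e-12,
                                   fire_rel_sd = 1e-12))
  truth <- gen_truth_run(cfg)
  obs <- gen_observations(truth, cfg)
  lai <- obs[obs$stream == "lai", ]
  expect_equal(lai$value, truth$foliar / cfg$truth[["lcma"]],
               tolerance = 1e-9)
  bio <- obs[obs$stream == "biomass", ]
  expect_equal(bio$value, mean(truth$wood + truth$foliar), tolerance = 1e-6)
  ann <- tapply(truth$fire, truth$year, sum)
  fire <- obs[obs$stream == "fire_annual", ]
  expect_equal(fire$value, as.numeric(ann), tolerance = 1e-6)
  # recorded sds are exactly the configured ones
  expect_equal(unique(lai$sd), 1e-12)
  expect_equal(bio$sd, 1e-12 * mean(truth$wood + truth$foliar),
               tolerance = 1e-15)
})

test_that("applied observation noise matches the recorded sd empirically", {
  truth <- gen_truth_run(small_config(seed = 60))
  lcma <- default_params()[["lcma"]]
  resid <- unlist(lapply(1:100, function(s) {
    cfg <- small_config(seed = 1e5 + s)
    obs <- gen_observations(truth, cfg)
    lai <- obs[obs$stream == "lai", ]
    lai$value - truth$foliar / lcma
  }))
  expect_lt(abs(sd(resid) - 0.1) / 0.1, 0.15)
})

test_that("synthetic budgets close when unperturbed and carry the imbalance", {
  b0 <- gen_budget_table(seed = 2, n_years = 6, imbalance = 0, noise_sd = 0)
  expect_equal(af_process(b0)$af_process, af_observed(b0)$af_obs,
               tolerance = 1e-12)

  b6 <- gen_budget_table(seed = 2, n_years = 6, imbalance = 0.6,
                         noise_sd = 0)
  resid <- b6$e_ff + b6$e_luc - b6$g_atm - b6$s_ocean - b6$s_land
  expect_equal(resid, rep(0.6, 6), tolerance = 1e-12)
  # deltas summing to -0.6 recover the observed airborne fraction
  d <- tibble::tibble(year = b6$year, d_fire = -0.2, d_nee = -0.4)
  expect_equal(af_adjusted(b6, d)$af_adjusted, af_observed(b6)$af_obs,
               tolerance = 1e-12)
  expect_error(gen_budget_table(n_years = 0), "n_years")
})

test_that("the packaged savanna fixture validates and matches its regression", {
  fx <- fixture_savanna_decline()
  expect_s3_class(validate_forcing(fx$forcing), "fs_forcing")
  expect_s3_class(validate_observations(fx$obs), "fs_observations")
  expect_silent(validate_params(fx$params))
  expect_silent(validate_state(fx$init))
  expect_identical(nrow(fx$truth), 168L)

  d <- fixture_truth_delta(horizon = 30)
  wm <- window_means(d)
  v <- setNames(wm$value, wm$variable)
  ref <- jsonlite::read_json(
    system.file("extdata", "savanna_decline_regression.json",
                package = "firesink"),
    simplifyVector = TRUE
  )
  expect_lt(v[["fire"]], 0)
  expect_gt(abs(v[["nee"]]), abs(v[["fire"]]))
  expect_equal(v[["fire"]], ref$delta_fire_window_mean, tolerance = 1e-8)
  expect_equal(v[["nee"]], ref$delta_nee_window_mean, tolerance = 1e-8)
  expect_equal(abs(v[["nee"]] / v[["fire"]]), ref$indirect_direct_ratio,
               tolerance = 1e-8)
  leg <- legacy_window_means(d, variables = "nee")
  expect_equal(leg$q50, c(ref$legacy_nee_1_5, ref$legacy_nee_6_10,
                          ref$legacy_nee_11_20), tolerance = 1e-8)
  expect_equal(nbe_neutrality_time(d), ref$nbe_neutrality_years)
})
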