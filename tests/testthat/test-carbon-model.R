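test_that("GPP limits: zero canopy, zero efficiency, saturation asymptote", {
  p <- default_params()
  met <- list(t_mean = 25, sw_rad = 20, days = 30)
  expect_identical(compute_gpp(0, p, met), 0)
  p0 <- default_params(lue = 0)
  expect_identical(compute_gpp(250, p0, met), 0)

  # closed canopy: GPP -> lue * 0.5 * sw * g_T * days
  const <- model_constants()
  g_t <- min(exp(p[["theta"]] * (met$t_mean - const$t_ref)), const$gt_cap)
  asym <- p[["lue"]] * 0.5 * met$sw_rad * g_t * met$days
  gpp50 <- compute_gpp(50 * p[["lcma"]], p, met)
  expect_lt(abs(gpp50 - asym) / asym, 1e-6)

  # strictly increasing in foliar below saturation
  fol <- seq(0, 500, by = 25)
  expect_true(all(diff(compute_gpp(fol, p, met)) > 0))
  expect_error(compute_gpp(-1, p, met), "foliar")
})

test_that("fire combustion matches the worked example exactly", {
  p <- default_params(cc_foliar = 0.9, cc_wood = 0.1, cc_litter = 0.5,
                      cc_som = 0.01, resilience = 0.5)
  st <- c(labile = 0, foliar = 200, fine_root = 0, wood = 1000,
          litter = 300, som = 5000, water = 100)
  burn <- apply_fire(st, 0.1, p)
  expect_equal(burn$emission, 48, tolerance = 1e-14)
  expect_equal(unname(burn$mortality[["foliar"]]), 1, tolerance = 1e-14)
  expect_equal(unname(burn$mortality[["wood"]]), 45, tolerance = 1e-14)
  # burned carbon leaves, mortality moves to litter, nothing goes negative
  expect_true(all(burn$state >= 0))
  expect_equal(total_carbon(burn$state), total_carbon(st) - burn$emission)
})

test_that("fire is linear in burned fraction and monotone in its factors", {
  p <- default_params()
  st <- default_init()
  e <- vapply(c(0.05, 0.2, 0.6, 1), function(b) apply_fire(st, b, p)$emission,
              1)
  expect_equal(e / c(0.05, 0.2, 0.6, 1), rep(e[4], 4), tolerance = 1e-12)

  expect_identical(apply_fire(st, 0, p)$emission, 0)
  expect_identical(apply_fire(st, 0, p)$state, validate_state(st))

  # raising any combustion completeness cannot decrease the emission
  for (cc in c("cc_foliar", "cc_wood", "cc_litter", "cc_som")) {
    lo <- p; lo[cc] <- 0.1
    hi <- p; hi[cc] <- 0.6
    expect_gte(apply_fire(st, 0.3, hi)$emission,
               apply_fire(st, 0.3, lo)$emission)
  }
  # full resilience suppresses mortality entirely
  pr <- default_params(resilience = 1)
  expect_identical(sum(apply_fire(st, 0.7, pr)$mortality), 0)
  # raising resilience cannot increase mortality
  p2 <- default_params(resilience = 0.6)
  expect_lte(sum(apply_fire(st, 0.3, p2)$mortality),
             sum(apply_fire(st, 0.3, default_params(resilience = 0.2))$mortality))
  expect_error(apply_fire(st, 1.2, p), "ba_frac")
})

test_that("a single step matches an independent hand computation", {
  p <- default_params()
  st <- default_init()
  met <- list(t_mean = 25, precip = 80, sw_rad = 20, days = 30)
  const <- model_constants()
  got <- step_carbon(st, p, met, 0.1, const)

  # hand-applied update, written out flux by flux
  g_t <- exp(p[["theta"]] * 10)
  lai <- st[["foliar"]] / p[["lcma"]]
  gpp <- p[["lue"]] * 0.5 * 20 * (1 - exp(-0.5 * lai)) * g_t * 30
  ra <- 0.5 * gpp
  npp <- gpp - ra
  g_w <- 150 / (150 + 100)
  rel <- 0.3 * 30
  tof <- st[["foliar"]] / 6
  tor <- st[["fine_root"]] / 18
  tow <- st[["wood"]] / 240
  rh_l <- 0.03 * g_t * g_w * st[["litter"]]
  tosom <- 0.01 * g_t * g_w * st[["litter"]]
  rh_s <- 0.002 * g_t * g_w * st[["som"]]
  pools <- c(
    labile = 30 + 0.15 * npp - rel,
    foliar = 90 + 0.35 * npp + rel - tof,
    fine_root = 150 + 0.25 * npp - tor,
    wood = 1500 + 0.25 * npp - tow,
    litter = 300 + tof + tor - rh_l - tosom,
    som = 4000 + tow + tosom - rh_s
  )
  live_cc <- c(labile = 0.9, foliar = 0.9, fine_root = 0.9, wood = 0.1)
  live <- pools[names(live_cc)]
  comb <- live * 0.1 * live_cc
  mort <- live * 0.1 * (1 - live_cc) * (1 - 0.2)
  fire <- sum(comb) + pools[["litter"]] * 0.1 * 0.2 +
    pools[["som"]] * 0.1 * 0.005
  pools[names(live_cc)] <- live - comb - mort
  pools[["litter"]] <- pools[["litter"]] * (1 - 0.1 * 0.2) + sum(mort)
  pools[["som"]] <- pools[["som"]] * (1 - 0.1 * 0.005)
  water <- min(max(150 + 80 - const$evap_coef * gpp, 0), const$w_max)

  expect_equal(got$fluxes[["gpp"]], gpp, tolerance = 1e-12)
  expect_equal(got$fluxes[["fire"]], unname(fire), tolerance = 1e-12)
  expect_equal(got$state[names(pools)], pools, tolerance = 1e-12)
  expect_equal(got$state[["water"]], water, tolerance = 1e-12)
  expect_equal(got$fluxes[["nee"]],
               ra + rh_l + rh_s - gpp, tolerance = 1e-12)
})

test_that("compiled trajectory equals the pure-R step recursion", {
  cfg <- small_config()
  f <- gen_forcing(cfg)
  p <- cfg$truth
  traj <- simulate_carbon(f, p, cfg$init)
  st <- cfg$init
  for (i in seq_len(nrow(f))) {
    stp <- step_carbon(st, p, as.list(f[i, ]), f$ba_frac[i])
    st <- stp$state
  }
  last <- nrow(traj)
  expect_equal(unlist(traj[last, POOL_NAMES]),
               setNames(st, POOL_NAMES), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("source-free decay: no light, no fire, pools only lose carbon", {
  p <- default_params(lue = 0)
  f <- flat_forcing(24, ba = 0)
  traj <- simulate_carbon(f, p, default_init())
  tc <- total_carbon(traj)
  expect_true(all(diff(tc) <= 0))
  loss <- -(diff(c(total_carbon(default_init()), tc)))
  expect_equal(loss, traj$ra + traj$rh_litter + traj$rh_som,
               tolerance = 1e-12)
})

test_that("carbon closure holds at every step of a 168-month run", {
  fx <- fixture_savanna_decline()
  tr <- fx$truth
  tc <- total_carbon(tr)
  prev <- c(total_carbon(fx$init), tc[-length(tc)])
  resid <- (tc - prev) -
    (tr$gpp - tr$ra - tr$rh_litter - tr$rh_som - tr$fire)
  expect_lt(max(abs(resid)) / mean(tc), 1e-9)
})

test_that("overdrawn pools are limited proportionally, never negative", {
  # decomposition demand far above the litter stock
  p <- default_params(decomp_litter = 0.9, lit2som = 0.9, theta = 0.08)
  f <- flat_forcing(12, t_mean = 40, ba = 0)
  traj <- simulate_carbon(f, p, default_init(water = 300))
  expect_true(all(as.matrix(traj[, POOL_NAMES]) >= 0))
  expect_true(all(traj$rh_litter >= 0 & traj$rh_som >= 0))
})

test_that("simulation is deterministic and rejects empty forcing", {
  cfg <- small_config()
  f <- gen_forcing(cfg)
  a <- simulate_carbon(f, cfg$truth, cfg$init)
  b <- simulate_carbon(f, cfg$truth, cfg$init)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_error(forcing_series(numeric(0), numeric(0), numeric(0),
                              numeric(0)), "at least one month")
  expect_error(simulate_carbon(f[0, ], cfg$truth, cfg$init), "empty")
})

test_that("annualize sums months, converts units, rejects partial years", {
  f <- flat_forcing(24, ba = 0.01)
  traj <- simulate_carbon(f, default_params(), default_init())
  ann <- annualize(traj, area_m2 = 1e12)
  expect_identical(nrow(ann), 2L)
  expect_equal(ann$gpp[1], sum(traj$gpp[1:12]), tolerance = 1e-12)
  expect_equal(ann$gpp_pgc, ann$gpp * 1e12 * 1e-15, tolerance = 1e-15)
  expect_error(annualize(traj[1:18, ]), "complete")

  # area-weighted multi-cell totals match a hand-weighted sum
  cells <- tibble::tibble(year = c(2001, 2001), fire = c(100, 50),
                          area_m2 = c(1e12, 3e12))
  expect_equal(global_total(cells, "fire")$pgc,
               (100 * 1e12 + 50 * 3e12) * 1e-15, tolerance = 1e-15)
})

test_that("pools stay non-negative across random parameter draws", {
  set.seed(42)
  cfg <- small_config(seed = 5, n_years = 14)
  f <- gen_forcing(cfg)
  for (k in 1:50) {
    p <- random_params()
    traj <- simulate_carbon(f, p, default_init())
    expect_true(all(as.matrix(traj[, POOL_NAMES]) >= 0))
  }
})
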