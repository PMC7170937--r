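make_traj <- function(n = 24) {
  cfg <- small_config(n_years = max(2, ceiling(n / 12)))
  simulate_carbon(gen_forcing(cfg)[seq_len(n), ], cfg$truth, cfg$init)
}

test_that("log-likelihood equals the Gaussian closed form at the mode", {
  p <- default_params()
  traj <- make_traj(24)
  # observations placed exactly on the model transforms, all sd = 1
  lai <- tibble::tibble(time = 1:24, value = traj$foliar / p[["lcma"]], sd = 1)
  z <- (traj$gpp - mean(traj$gpp)) / sd(traj$gpp)
  gpa <- tibble::tibble(time = 1:24, value = z, sd = 1)
  ann <- tapply(traj$fire, traj$year, sum)
  fire <- tibble::tibble(time = as.numeric(names(ann)),
                         value = as.numeric(ann), sd = 1)
  obs <- observation_set(
    lai = lai, gpp_anom = gpa,
    biomass = c(mean(traj$wood + traj$foliar), 1),
    som = c(mean(traj$som), 1), fire_annual = fire
  )
  n_pts <- nrow(obs)
  expect_equal(log_likelihood(traj, obs, p), -(n_pts / 2) * log(2 * pi),
               tolerance = 1e-10)
})

test_that("likelihood is additive over streams and tolerant of dropout", {
  p <- default_params()
  traj <- make_traj(24)
  lai <- tibble::tibble(time = 1:24, value = 1.2, sd = 0.2)
  obs_full <- observation_set(lai = lai, biomass = c(400, 40),
                              som = c(3000, 500))
  obs_lai <- observation_set(lai = lai)
  obs_rest <- observation_set(biomass = c(400, 40), som = c(3000, 500))
  expect_equal(log_likelihood(traj, obs_full, p),
               log_likelihood(traj, obs_lai, p) +
                 log_likelihood(traj, obs_rest, p), tolerance = 1e-12)
  # empty set contributes nothing
  expect_identical(log_likelihood(traj, observation_set(), p), 0)
})

test_that("doubling the sd helps a poorly fitting trajectory", {
  p <- default_params()
  traj <- make_traj(24)
  off <- tibble::tibble(time = 1:24, value = traj$foliar / p[["lcma"]] + 5,
                        sd = 0.5)
  off2 <- dplyr::mutate(off, sd = 1)
  ll1 <- log_likelihood(traj, observation_set(lai = off), p)
  ll2 <- log_likelihood(traj, observation_set(lai = off2), p)
  expect_gt(ll2, ll1)
  # and matches the closed-form difference for a fixed mismatch
  delta <- sum(dnorm(5, 0, 1, log = TRUE) - dnorm(5, 0, 0.5, log = TRUE)) * 24
  expect_equal(ll2 - ll1, delta, tolerance = 1e-10)
})

test_that("prior density: bounds, log-uniformity, truncated-normal ratios", {
  pr <- default_priors(include_init = FALSE)
  x <- setNames((pr$min + pr$max) / 2, pr$name)
  x["lue"] <- 0.3
  expect_true(is.finite(log_prior(x, pr)))
  y <- x
  y["lcma"] <- 1e6
  expect_identical(log_prior(y, pr), -Inf)

  # log-uniform: density uniform in log space, so lp(x1)-lp(x2) = log(x2/x1)
  a <- x
  b <- x
  a["decomp_som"] <- 0.001
  b["decomp_som"] <- 0.004
  expect_equal(log_prior(a, pr) - log_prior(b, pr), log(0.004 / 0.001),
               tolerance = 1e-12)

  # truncated normal: log-density differences follow the Gaussian kernel
  a2 <- x
  b2 <- x
  a2["f_auto"] <- 0.5
  b2["f_auto"] <- 0.6
  expect_equal(log_prior(a2, pr) - log_prior(b2, pr),
               dnorm(0.5, 0.5, 0.1, log = TRUE) -
                 dnorm(0.6, 0.5, 0.1, log = TRUE), tolerance = 1e-12)

  # ecological orderings are enforced
  c2 <- x
  c2["decomp_som"] <- 0.09
  c2["decomp_litter"] <- 0.05
  expect_identical(log_prior(c2, pr), -Inf)
  expect_error(log_prior(x[-1], pr), "length")
})

test_that("the MH kernel recovers a conjugate normal-normal posterior", {
  # one location parameter, N(0, 1) prior, 10 obs of known sd 1
  set.seed(3)
  yobs <- rnorm(10, 1.5, 1)
  post_var <- 1 / (1 + 10)
  post_mean <- post_var * sum(yobs)
  lt <- function(z) dnorm(z, 0, 1, log = TRUE) +
    sum(dnorm(yobs, z, 1, log = TRUE))
  ch <- mh_chain(lt, init = 0, scale = 0.5, n_iter = 50000, n_burn = 10000,
                 thin = 5, seed = 9)
  draws <- ch$samples[, 1]
  n_eff <- ess(draws)
  mcse_mean <- sd(draws) / sqrt(n_eff)
  mcse_sd <- sd(draws) / sqrt(2 * n_eff)
  expect_lt(abs(mean(draws) - post_mean), 3 * mcse_mean)
  expect_lt(abs(sd(draws) - sqrt(post_var)), 3 * mcse_sd)
  expect_gt(ch$acceptance_rate, 0.05)
})

test_that("identical seeds reproduce the chain; prior-only runs sample the prior", {
  cfg <- small_config()
  f <- gen_forcing(cfg)
  obs <- gen_observations(gen_truth_run(cfg), cfg)
  a <- mh_sample(obs, f, n_iter = 2000, chains = 2, seed = 4)
  b <- mh_sample(obs, f, n_iter = 2000, chains = 2, seed = 4)
  expect_identical(a$samples, b$samples)

  # empty observations + disabled equilibrium penalty = prior sampling
  pr <- default_priors(include_init = FALSE)
  post <- mh_sample(observation_set(), f, prior = pr, n_iter = 30000,
                    chains = 2, thin = 5, drift_tol = Inf, seed = 5)
  qs <- quantile(post$samples$theta, c(0.25, 0.75))
  set.seed(1)
  ref <- quantile(prior_draw(pr, 20000)$theta, c(0.25, 0.75))
  expect_equal(unname(qs), unname(ref), tolerance = 0.12)
})

test_that("posterior predictions give ordered, draw-consistent quartiles", {
  cfg <- small_config()
  f <- gen_forcing(cfg)
  one <- tibble::as_tibble(t(cfg$truth))
  degenerate <- posterior_from_draws(dplyr::bind_rows(one, one, one),
                                     init = cfg$init)
  pp <- posterior_predict(degenerate, f, n_draws = 3, seed = 1)
  expect_equal(pp$q25, pp$q50, tolerance = 1e-12)
  expect_equal(pp$q50, pp$q75, tolerance = 1e-12)

  # three distinct draws: quartiles are the type-7 interpolants of the
  # hand-ranked per-month values
  three <- dplyr::bind_rows(
    tibble::as_tibble(t(default_params(lue = 0.2))),
    tibble::as_tibble(t(default_params(lue = 0.3))),
    tibble::as_tibble(t(default_params(lue = 0.6)))
  )
  p3 <- posterior_from_draws(three, init = cfg$init)
  pp3 <- posterior_predict(p3, f[1:2, ], n_draws = 3, seed = 1)
  g <- sapply(c(0.2, 0.3, 0.6), function(l)
    simulate_carbon(f[1:2, ], default_params(lue = l), cfg$init)$gpp[1])
  g <- sort(g)
  row <- pp3[pp3$variable == "gpp" & pp3$t == 1, ]
  expect_equal(row$q25, g[1] + 0.5 * (g[2] - g[1]), tolerance = 1e-12)
  expect_equal(row$q50, g[2], tolerance = 1e-12)
  expect_equal(row$q75, g[2] + 0.5 * (g[3] - g[2]), tolerance = 1e-12)
  expect_true(all(pp3$q25 <= pp3$q50 & pp3$q50 <= pp3$q75))
  expect_error(posterior_predict(p3, f, n_draws = 10), "exceeds")
})

test_that("split-chain diagnostic: hand value, degenerate cases, errors", {
  # two identical 4-point chains: W and B follow from the split halves
  ch <- matrix(c(1, 2, 3, 4), ncol = 1, dimnames = list(NULL, "x"))
  got <- convergence_diag(list(ch, ch))
  half_means <- c(1.5, 3.5, 1.5, 3.5)
  w <- mean(c(var(c(1, 2)), var(c(3, 4)), var(c(1, 2)), var(c(3, 4))))
  b <- 2 * var(half_means)
  expect_equal(got$rhat, sqrt(((2 - 1) / 2 * w + b / 2) / w),
               tolerance = 1e-12)

  # well-mixed white-noise chains sit near 1
  set.seed(8)
  m1 <- matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "x"))
  m2 <- matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "x"))
  expect_lt(convergence_diag(list(m1, m2))$rhat, 1.05)

  # chains stuck at different constants diverge
  c1 <- matrix(rep(0, 100) + rnorm(100, 0, 1e-6), ncol = 1,
               dimnames = list(NULL, "x"))
  c2 <- matrix(rep(5, 100) + rnorm(100, 0, 1e-6), ncol = 1,
               dimnames = list(NULL, "x"))
  expect_gt(convergence_diag(list(c1, c2))$rhat, 100)
  expect_error(convergence_diag(list(c1)), "two chains")
})

test_that("posteriors survive a CSV + JSON round trip", {
  cfg <- small_config()
  f <- gen_forcing(cfg)
  obs <- gen_observations(gen_truth_run(cfg), cfg)
  post <- mh_sample(obs, f, n_iter = 1500, chains = 2, seed = 2)
  path <- file.path(withr::local_tempdir(), "post")
  write_posterior(post, path)
  back <- read_posterior(path)
  expect_equal(as.data.frame(back$samples), as.data.frame(post$samples),
               tolerance = 1e-12)
  expect_equal(back$acceptance_rate, post$acceptance_rate)
  expect_equal(back$meta$thin, post$meta$thin,
               ignore_attr = TRUE)
})
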