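# constant-meteorology forcing for analytic checks
flat_forcing <- function(n = 12, t_mean = 25, precip = 80, sw_rad = 20,
                         ba = 0, start_year = 2001) {
  forcing_series(rep(t_mean, n), rep(precip, n), rep(sw_rad, n),
                 rep(ba, n), start_year = start_year)
}

# small, fast synthetic configuration for module tests
small_config <- function(seed = 11, n_years = 4, ...) {
  synth_config(seed = seed, n_years = n_years, spin_years = 10, ...)
}

# a delta object built from paired truth runs on the packaged fixture
fixture_truth_delta <- function(horizon = 30) {
  fx <- fixture_savanna_decline()
  yrs <- unique(fx$forcing$year)
  base <- yrs[seq_len(length(yrs) / 2)]
  win <- setdiff(yrs, base)
  fobs <- extend_forcing(fx$forcing, horizon, recycle_years = win)
  ffix <- build_fixed_ba(fx$forcing, base, win)
  ffix <- extend_forcing(ffix, horizon, recycle_years = win)
  ffix$ba_frac[ffix$year > max(win)] <- fobs$ba_frac[fobs$year > max(win)]
  p1 <- posterior_from_draws(tibble::as_tibble(t(fx$params)), init = fx$init)
  run_delta(p1, fobs, ffix, n_draws = 1, window_years = win)
}

# random-but-valid parameter vector drawn from the package priors
random_params <- function() {
  pr <- default_priors(include_init = FALSE)
  repeat {
    p <- unlist(prior_draw(pr, 1)[1, ])
    if (p[["alloc_foliar"]] + p[["alloc_labile"]] + p[["alloc_root"]] <= 0.95)
      return(p)
  }
}
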