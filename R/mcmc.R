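#' Random-walk Metropolis-Hastings chain over an arbitrary log target
#'
#' Generic driver used by [mh_sample()]: a Gaussian random walk whose
#' proposal covariance is adapted during burn-in only -- first a diagonal
#' walk, then (once enough burn-in history exists) proposals drawn from the
#' empirical covariance of the chain so far scaled by the classic 2.38^2/d
#' factor, with a global step-size multiplier tuned toward an acceptance
#' rate of 0.234.  The kernel is frozen at the end of burn-in, so the
#' retained draws come from a fixed, detailed-balance-preserving kernel.
#' Non-finite target values always reject.
#'
#' @param log_target Function of the state vector returning a scalar log
#'   density (up to a constant).
#' @param init Numeric starting state (must have finite target).
#' @param scale Per-component proposal sd of the initial diagonal walk.
#' @param n_iter,n_burn Total iterations and burn-in iterations.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed RNG seed: identical seeds give identical chains.
#' @param adapt Adapt during burn-in?
#' @param target_accept Acceptance rate targeted by the adaptation.
#' @return List with `samples` (matrix, retained draws by component), `lp`
#'   (log target per retained draw), `acceptance_rate` (post-burn-in),
#'   `scale_final` (the frozen proposal Cholesky factor, transposed).
#' @export
mh_chain <- function(log_target, init, scale, n_iter, n_burn = n_iter %/% 2,
                     thin = 10, seed = 1, adapt = TRUE,
                     target_accept = 0.234) {
  if (n_iter <= 0) stop("n_iter must be > 0", call. = FALSE)
  if (n_burn < 0 || n_burn >= n_iter) {
    stop("need n_iter > n_burn >= 0", call. = FALSE)
  }
  set.seed(seed)
  d <- length(init)
  scale <- rep_len(scale, d)
  lambda <- 1
  chol_prop <- diag(scale, d)  # proposal = cur + lambda * t(chol_prop) %*% z
  cur <- init
  lp_cur <- log_target(cur)
  if (!is.finite(lp_cur)) stop("initial state has non-finite target",
                               call. = FALSE)
  n_keep <- (n_iter - n_burn) %/% thin
  samples <- matrix(NA_real_, n_keep, d)
  lp_keep <- numeric(n_keep)
  burn_cap <- max(min(n_burn, 20000L), 1L)
  burn_hist <- matrix(NA_real_, burn_cap, d)
  hist_n <- 0L
  acc_window <- 0L
  acc_post <- 0L
  kept <- 0L
  for (i in seq_len(n_iter)) {
    step <- if (runif(1) < 0.1) 3 * lambda else lambda
    prop <- cur + step * drop(crossprod(chol_prop, rnorm(d)))
    lp_prop <- log_target(prop)
    if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp_cur) {
      cur <- prop
      lp_cur <- lp_prop
      acc_window <- acc_window + 1L
      if (i > n_burn) acc_post <- acc_post + 1L
    }
    if (i <= n_burn) {
      if (adapt) {
        if (hist_n < burn_cap) {
          hist_n <- hist_n + 1L
          burn_hist[hist_n, ] <- cur
        }
        if (i %% 100L == 0L) {
          lambda <- lambda * exp(acc_window / 100 - target_accept)
          acc_window <- 0L
          if (i >= 1000L && hist_n > 2L * d) {
            keep <- burn_hist[max(1L, hist_n %/% 2L):hist_n, , drop = FALSE]
            sig <- stats::cov(keep) * (2.38^2 / d) +
              diag(1e-10, d)
            ch <- tryCatch(chol(sig), error = function(e) NULL)
            if (!is.null(ch)) chol_prop <- ch
          }
        }
      } else if (i %% 100L == 0L) {
        acc_window <- 0L
      }
    }
    if (i > n_burn && (i - n_burn) %% thin == 0L && kept < n_keep) {
      kept <- kept + 1L
      samples[kept, ] <- cur
      lp_keep[kept] <- lp_cur
    }
  }
  rate <- acc_post / (n_iter - n_burn)
  if (rate == 0) {
    warning("no proposals accepted after burn-in; chain did not move",
            call. = FALSE)
  }
  list(samples = samples, lp = lp_keep, acceptance_rate = rate,
       scale_final = lambda * chol_prop)
}

# fast likelihood closure over matrices, used inside the MCMC loop.
# drift_tol implements a quasi-steady-state gate (dynamic-equilibrium
# screening): candidate runs whose slow pools (wood, litter, SOM) drift by
# more than this factor between the first and last simulated year are
# rejected outright.
prep_loglik <- function(obs, forcing, const, drift_tol = 1.5) {
  obs <- validate_observations(obs)
  forc <- forcing_matrix(validate_forcing(forcing))
  years <- forcing$year
  year_group <- match(years, unique(years))
  s <- split(obs, obs$stream)
  lai_t <- s$lai$time; lai_v <- s$lai$value; lai_sd <- s$lai$sd
  gpa_t <- s$gpp_anom$time; gpa_v <- s$gpp_anom$value; gpa_sd <- s$gpp_anom$sd
  bio_v <- s$biomass$value; bio_sd <- s$biomass$sd
  som_v <- s$som$value; som_sd <- s$som$sd
  fire_y <- match(s$fire_annual$time, unique(years))
  fire_v <- s$fire_annual$value; fire_sd <- s$fire_annual$sd

  function(par, init) {
    res <- .sim_core(par, init, forc, const$k_ext, const$t_ref, const$gt_cap,
                     const$w_max, const$evap_coef)
    st <- res$states
    fl <- res$fluxes
    n <- nrow(st)
    ll <- 0
    if (is.finite(drift_tol) && n >= 24) {
      sd_drift <- log(drift_tol) / 2
      for (j in c(4L, 5L, 6L)) {
        a <- mean(st[1:12, j])
        b <- mean(st[(n - 11):n, j])
        if (a <= 0 || b <= 0) return(-Inf)
        dr <- log(b / a)
        if (abs(dr) > 3 * log(drift_tol)) return(-Inf)
        ll <- ll - 0.5 * (dr / sd_drift)^2
      }
    }
    if (length(lai_t)) {
      ll <- ll + sum(dnorm(lai_v, st[lai_t, 2] / par[7], lai_sd, log = TRUE))
    }
    if (length(gpa_t)) {
      g <- fl[, 1]
      sdg <- sd(g)
      z <- if (sdg > 0) (g - mean(g)) / sdg else rep(0, length(g))
      ll <- ll + sum(dnorm(gpa_v, z[gpa_t], gpa_sd, log = TRUE))
    }
    if (length(bio_v)) {
      ll <- ll + sum(dnorm(bio_v, mean(st[, 4] + st[, 2]), bio_sd, log = TRUE))
    }
    if (length(som_v)) {
      ll <- ll + sum(dnorm(som_v, mean(st[, 6]), som_sd, log = TRUE))
    }
    if (length(fire_y)) {
      ann <- rowsum(fl[, 5], year_group)[, 1]
      ll <- ll + sum(dnorm(fire_v, ann[fire_y], fire_sd, log = TRUE))
    }
    ll
  }
}

#' Fit the carbon model to observations by Metropolis-Hastings MCMC
#'
#' Samples the model parameters (and, when the prior spec contains `init_*`
#' rows, the initial pool states) from the posterior given the multi-stream
#' observations.  The walk happens in transformed space (log for rates, logit
#' for fractions) with the appropriate Jacobian, so proposals are symmetric
#' and bounds are respected.  Adaptation is restricted to burn-in.
#'
#' @param obs Observation tibble, see [observation_set()].
#' @param forcing Forcing tibble covering the observation period.
#' @param prior Prior spec, see [default_priors()].
#' @param n_iter,n_burn,thin MCMC controls; `n_iter` is the total iteration
#'   budget, split evenly across `chains`; `n_burn` is the per-chain burn-in
#'   fraction of its share.
#' @param chains Number of chains, each started from a distinct polished
#'   mode and pooled after burn-in (a multi-start ensemble guards against
#'   the multi-modal trade-off structure of this posterior).  Capped so
#'   every chain gets at least 1000 iterations.
#' @param seed RNG seed; identical seeds give identical chains.
#' @param proposal_scale Per-quantity initial proposal sd in transformed
#'   space (default 0.1).
#' @param init Fixed initial pools, used only when `prior` has no `init_*`
#'   rows.
#' @param drift_tol Quasi-steady-state penalty: the log drift of each slow
#'   pool (wood, litter, SOM) between the first and last simulated year is
#'   shrunk by a Gaussian with sd `log(drift_tol)/2` and hard-rejected
#'   beyond `drift_tol^3`, reflecting the dynamic-equilibrium assumption
#'   behind the study design.  Set `Inf` to disable.
#' @param const Structural constants.
#' @return A `fs_posterior` object: `samples` (tibble of retained draws in
#'   natural units), `lp`, `acceptance_rate`, `seed`, `prior`, `meta`.
#' @export
mh_sample <- function(obs, forcing, prior = default_priors(),
                      n_iter = 50000, n_burn = NULL, thin = 10, chains = 6,
                      seed = 1, proposal_scale = 0.1, init = default_init(),
                      drift_tol = 1.5, const = model_constants()) {
  prior <- validate_priors(prior)
  forcing <- validate_forcing(forcing)
  chains <- max(1L, min(as.integer(chains), n_iter %/% 1000L))
  d <- nrow(prior)
  par_idx <- match(PAR_NAMES, prior$name)
  if (any(is.na(par_idx))) {
    stop("prior must contain all model parameters", call. = FALSE)
  }
  init_names <- paste0("init_", POOL_NAMES)
  has_init <- all(init_names %in% prior$name)
  init_idx <- match(init_names, prior$name)
  fixed_init <- unname(validate_state(init))

  loglik <- prep_loglik(obs, forcing, const, drift_tol)
  pname <- prior$name

  log_target <- function(z) {
    x <- from_z(z, prior)
    lp <- log_prior(setNames(x, pname), prior)
    if (!is.finite(lp)) return(-Inf)
    par <- x[par_idx]
    st0 <- if (has_init) x[init_idx] else fixed_init
    ll <- loglik(par, st0)
    if (!is.finite(ll)) return(-Inf)
    lp + log_jacobian(z, prior) + ll
  }

  # seeded starts: screen a batch of prior draws, then polish the best few
  # with derivative-free climbs; each chain starts from its own mode
  set.seed(seed + 1L)
  cand <- prior_draw(prior, 1000)
  lt <- vapply(seq_len(nrow(cand)), function(k) {
    v <- log_target(to_z(as.numeric(cand[k, ]), prior))
    if (is.finite(v)) v else -Inf
  }, 1)
  if (!any(is.finite(lt))) {
    stop("could not find a finite starting point", call. = FALSE)
  }
  penalised <- function(z) {
    v <- log_target(z)
    if (is.finite(v)) -v else 1e12
  }
  n_start <- max(chains, 1L)
  top <- order(lt, decreasing = TRUE)[seq_len(min(n_start,
                                                  sum(is.finite(lt))))]
  starts <- lapply(top, function(k) {
    zk <- to_z(as.numeric(cand[k, ]), prior)
    opt <- tryCatch(
      stats::optim(zk, penalised, method = "Nelder-Mead",
                   control = list(maxit = 4000)),
      error = function(e) NULL
    )
    if (!is.null(opt) && is.finite(opt$value) && opt$value < 1e12) opt$par
    else zk
  })

  iter_per <- n_iter %/% max(chains, 1L)
  burn_per <- if (is.null(n_burn)) iter_per %/% 2 else
    min(n_burn %/% max(chains, 1L), iter_per - thin)
  runs <- lapply(seq_len(chains), function(ci) {
    mh_chain(log_target, starts[[(ci - 1L) %% length(starts) + 1L]],
             proposal_scale, n_iter = iter_per, n_burn = burn_per,
             thin = thin, seed = sub_seed(seed, 30 + ci))
  })
  samples_z <- do.call(rbind, lapply(runs, `[[`, "samples"))
  lp <- unlist(lapply(runs, `[[`, "lp"))
  nat <- t(apply(samples_z, 1, from_z, prior = prior))
  colnames(nat) <- pname
  out <- list(
    samples = tibble::as_tibble(as.data.frame(nat)),
    lp = lp,
    acceptance_rate = mean(vapply(runs, `[[`, 1, "acceptance_rate")),
    seed = seed,
    prior = prior,
    meta = list(n_iter = n_iter, n_burn = burn_per * chains, thin = thin,
                chains = chains, has_init = has_init,
                fixed_init = fixed_init,
                chain_id = rep(seq_len(chains),
                               vapply(runs, function(r) nrow(r$samples), 1L)))
  )
  class(out) <- "fs_posterior"
  out
}

#' Build a posterior object from explicit draws
#'
#' Useful for truth-parameter experiments (a single repeated draw) and for
#' testing: the resulting object can be passed anywhere a fitted posterior is
#' accepted.
#'
#' @param draws Data frame of draws; columns must include all of [PAR_NAMES],
#'   and either `init_*` columns or `init` must be supplied.
#' @param init Fixed initial pools used when `draws` has no `init_*` columns.
#' @return A `fs_posterior` object.
#' @export
posterior_from_draws <- function(draws, init = default_init()) {
  draws <- tibble::as_tibble(draws)
  stopifnot(all(PAR_NAMES %in% names(draws)))
  has_init <- all(paste0("init_", POOL_NAMES) %in% names(draws))
  out <- list(samples = draws, lp = rep(NA_real_, nrow(draws)),
              acceptance_rate = NA_real_, seed = NA_integer_, prior = NULL,
              meta = list(has_init = has_init,
                          fixed_init = unname(validate_state(init))))
  class(out) <- "fs_posterior"
  out
}

# params + init pools for draw i of a posterior
posterior_draw_state <- function(posterior, i) {
  row <- posterior$samples[i, ]
  par <- unlist(row[PAR_NAMES])
  st0 <- if (isTRUE(posterior$meta$has_init)) {
    setNames(unlist(row[paste0("init_", POOL_NAMES)]), POOL_NAMES)
  } else {
    setNames(posterior$meta$fixed_init, POOL_NAMES)
  }
  list(params = par, init = st0)
}

#' @export
print.fs_posterior <- function(x, ...) {
  cat("<fs_posterior> ", nrow(x$samples), " retained draws, ",
      ncol(x$samples), " quantities; acceptance rate ",
      signif(x$acceptance_rate, 3), "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted posterior
#'
#' One row per sampled quantity with posterior mean, median, sd and the 90%
#' equal-tailed credible interval.
#'
#' @param x A `fs_posterior`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fs_posterior <- function(x, ...) {
  purrr::imap_dfr(x$samples, function(v, nm) {
    q <- quantile(v, c(0.05, 0.5, 0.95), names = FALSE)
    tibble::tibble(term = nm, estimate = mean(v), median = q[2],
                   std.error = sd(v), conf.low = q[1], conf.high = q[3])
  })
}

#' @rdname tidy.fs_posterior
#' @export
glance.fs_posterior <- function(x, ...) {
  tibble::tibble(n_draws = nrow(x$samples),
                 n_quantities = ncol(x$samples),
                 acceptance_rate = x$acceptance_rate,
                 lp_max = suppressWarnings(max(x$lp)))
}

#' Posterior-predictive flux quantiles
#'
#' Runs the process model for `n_draws` parameter draws and summarises each
#' monthly flux by its median and first/third quartiles.
#'
#' @param posterior A `fs_posterior`.
#' @param forcing Forcing tibble to simulate over.
#' @param n_draws Number of draws (must not exceed the retained draws).
#' @param seed Seed for the draw selection.
#' @param const Structural constants.
#' @return Tidy tibble: `t`, `year`, `month`, `variable`, `q25`, `q50`, `q75`.
#' @export
posterior_predict <- function(posterior, forcing, n_draws = 100, seed = 1,
                              const = model_constants()) {
  n_avail <- nrow(posterior$samples)
  if (n_avail == 0) stop("empty posterior", call. = FALSE)
  if (n_draws > n_avail) {
    stop("n_draws exceeds retained draws", call. = FALSE)
  }
  forcing <- validate_forcing(forcing)
  set.seed(seed)
  idx <- sample.int(n_avail, n_draws)
  sims <- lapply(idx, function(i) {
    ds <- posterior_draw_state(posterior, i)
    traj <- simulate_carbon(forcing, ds$params, ds$init, const)
    as.matrix(traj[, FLUX_NAMES])
  })
  arr <- simplify2array(sims)  # month x flux x draw
  qs <- apply(arr, c(1, 2), quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE)
  base <- tidyr::expand_grid(variable = FLUX_NAMES,
                             t = seq_len(nrow(forcing)))
  base <- dplyr::arrange(base, match(.data$variable, FLUX_NAMES), .data$t)
  base$year <- forcing$year[base$t]
  base$month <- forcing$month[base$t]
  base$q25 <- as.vector(qs[1, , ])
  base$q50 <- as.vector(qs[2, , ])
  base$q75 <- as.vector(qs[3, , ])
  base[, c("t", "year", "month", "variable", "q25", "q50", "q75")]
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Standard variance-ratio diagnostic: each chain is split in half, and for
#' every quantity the pooled-to-within variance ratio is reported; values
#' near 1 indicate well-mixed chains.
#'
#' @param posteriors List of at least two `fs_posterior` objects (or draw
#'   matrices/data frames) of equal length.
#' @return Tibble with `term` and `rhat`.
#' @export
convergence_diag <- function(posteriors) {
  if (length(posteriors) < 2) {
    stop("need at least two chains", call. = FALSE)
  }
  mats <- lapply(posteriors, function(p) {
    m <- if (inherits(p, "fs_posterior")) as.matrix(p$samples) else
      as.matrix(p)
    m
  })
  n <- unique(vapply(mats, nrow, 1L))
  if (length(n) != 1) stop("chains must have equal lengths", call. = FALSE)
  half <- n %/% 2
  splits <- unlist(lapply(mats, function(m) {
    list(m[seq_len(half), , drop = FALSE],
         m[(n - half + 1):n, , drop = FALSE])
  }), recursive = FALSE)
  terms <- colnames(mats[[1]])
  rhat_one <- function(j) {
    chains <- vapply(splits, function(m) m[, j], numeric(half))
    w <- mean(apply(chains, 2, var))
    b <- half * var(colMeans(chains))
    if (w == 0) return(if (b == 0) 1 else Inf)
    sqrt(((half - 1) / half * w + b / half) / w)
  }
  tibble::tibble(term = terms,
                 rhat = vapply(seq_along(terms), rhat_one, 1))
}

#' Effective sample size (initial positive sequence estimator)
#'
#' @param x Numeric vector of MCMC draws.
#' @return Estimated effective sample size.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 3 || var(x) == 0) return(n)
  rho <- as.numeric(stats::acf(x, lag.max = min(n - 1, 1000),
                               plot = FALSE)$acf)[-1]
  s <- 0
  k <- 1
  while (k < length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, n / (1 + 2 * s))
}

#' Persist / load a posterior (CSV draws + JSON metadata sidecar)
#'
#' @param posterior A `fs_posterior`.
#' @param path Base path; writes `<path>.csv` and `<path>.json`.
#' @return `read_posterior()` returns the reconstructed `fs_posterior`.
#' @export
write_posterior <- function(posterior, path) {
  readr::write_csv(dplyr::mutate(posterior$samples, .lp = posterior$lp),
                   paste0(path, ".csv"))
  meta <- list(acceptance_rate = posterior$acceptance_rate,
               seed = posterior$seed,
               meta = posterior$meta[c("n_iter", "n_burn", "thin", "has_init")],
               fixed_init = posterior$meta$fixed_init)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  df <- readr::read_csv(paste0(path, ".csv"), show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- list(samples = dplyr::select(df, -".lp"), lp = df$.lp,
              acceptance_rate = meta$acceptance_rate, seed = meta$seed,
              prior = NULL,
              meta = c(as.list(meta$meta),
                       list(fixed_init = as.numeric(meta$fixed_init))))
  class(out) <- "fs_posterior"
  out
}
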