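#' Default prior specification
#'
#' One row per sampled quantity: the 20 model parameters and (optionally) the
#' 7 initial pool states.  Columns: `name`, `dist` (one of `"logunif"`,
#' `"unif"`, `"tnorm"`), `min`, `max`, `mean`, `sd` (used by `tnorm` only) and
#' `transform` (`"log"` for positive rates, `"logit"` for bounded fractions)
#' -- proposals are symmetric Gaussians in the transformed space.  All priors
#' are proper.  Quantities that trait syntheses and decomposition literature
#' constrain (leaf carbon mass per area, autotrophic fraction, allocation to
#' roots and reserves, fine-fuel combustion completeness) carry truncated
#' normal priors at literature values with generous spreads; the rest get
#' broad log-uniform or uniform priors.  Multi-stream satellite constraints
#' alone leave strong trade-offs between these quantities, so the informed
#' priors play the same role here as in operational model-data fusion.
#'
#' @param include_init Also include rows for the initial pools (`init_*`)?
#' @param obs Optional observation set: when given, the initial-pool priors
#'   for SOM, wood and foliage are recentred on the observed stocks (the way
#'   operational fusion systems initialise pools from soil-carbon and biomass
#'   maps); streams absent from `obs` leave the corresponding vague prior.
#' @return A tibble prior specification.
#' @export
#' @examples
#' default_priors()[1:3, ]
default_priors <- function(include_init = TRUE, obs = NULL) {
  pr <- tibble::tribble(
    ~name,             ~dist,     ~min,     ~max,    ~mean, ~sd,
    "lue",             "tnorm",   0.1,      1.5,     0.4,   0.2,
    "f_auto",          "tnorm",   0.2,      0.8,     0.5,   0.1,
    "alloc_foliar",    "unif",    0.05,     0.6,     NA,    NA,
    "alloc_labile",    "tnorm",   0.02,     0.5,     0.12,  0.08,
    "alloc_root",      "tnorm",   0.05,     0.6,     0.25,  0.1,
    "labile_release",  "logunif", 0.05,     1,       NA,    NA,
    "lcma",            "tnorm",   30,       200,     60,    25,
    "turn_foliar",     "logunif", 1 / 24,   1 / 2,   NA,    NA,
    "turn_root",       "logunif", 1 / 60,   1 / 6,   NA,    NA,
    "turn_wood",       "logunif", 1 / 720,  1 / 60,  NA,    NA,
    "decomp_litter",   "logunif", 0.01,     0.1,     NA,    NA,
    "decomp_som",      "logunif", 2e-4,     0.01,    NA,    NA,
    "lit2som",         "logunif", 1e-3,     0.05,    NA,    NA,
    "theta",           "logunif", 0.01,     0.08,    NA,    NA,
    "w_half",          "logunif", 30,       300,     NA,    NA,
    "cc_foliar",       "unif",    0.2,      1,       NA,    NA,
    "cc_wood",         "unif",    0.01,     0.5,     NA,    NA,
    "cc_litter",       "unif",    0.05,     0.9,     NA,    NA,
    "cc_som",          "unif",    0.001,    0.05,    NA,    NA,
    "resilience",      "unif",    0.01,     0.9,     NA,    NA
  )
  if (include_init) {
    init <- tibble::tribble(
      ~name,            ~dist,     ~min, ~max,  ~mean, ~sd,
      "init_labile",    "logunif", 1,    200,   NA,    NA,
      "init_foliar",    "logunif", 10,   300,   NA,    NA,
      "init_fine_root", "logunif", 10,   500,   NA,    NA,
      "init_wood",      "logunif", 50,   5000,  NA,    NA,
      "init_litter",    "logunif", 20,   2000,  NA,    NA,
      "init_som",       "logunif", 500,  20000, NA,    NA,
      "init_water",     "logunif", 30,   300,   NA,    NA
    )
    if (!is.null(obs)) {
      obs <- validate_observations(obs)
      recenter <- function(init, name, mean, sd, lo, hi) {
        i <- init$name == name
        init$dist[i] <- "tnorm"
        init$mean[i] <- min(max(mean, lo), hi)
        init$sd[i] <- sd
        init
      }
      som_o <- obs[obs$stream == "som", ]
      if (nrow(som_o)) {
        init <- recenter(init, "init_som", som_o$value[1],
                         max(som_o$sd[1], 0.1 * som_o$value[1]), 500, 20000)
      }
      bio_o <- obs[obs$stream == "biomass", ]
      if (nrow(bio_o)) {
        init <- recenter(init, "init_wood", 0.8 * bio_o$value[1],
                         max(bio_o$sd[1], 0.3 * bio_o$value[1]), 50, 5000)
      }
      lai_o <- obs[obs$stream == "lai", ]
      if (nrow(lai_o)) {
        fol <- mean(lai_o$value) * 60
        init <- recenter(init, "init_foliar", fol, 0.5 * fol, 10, 300)
      }
    }
    pr <- dplyr::bind_rows(pr, init)
  }
  fracs <- c(FRACTION_PARS)
  pr$transform <- ifelse(pr$name %in% fracs, "logit", "log")
  pr
}

validate_priors <- function(prior) {
  need <- c("name", "dist", "min", "max", "transform")
  missing <- setdiff(need, names(prior))
  if (length(missing)) {
    stop("prior spec lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(prior$dist %in% c("logunif", "unif", "tnorm")),
            all(is.finite(prior$min)), all(is.finite(prior$max)),
            all(prior$min < prior$max))
  if (any(prior$dist == "logunif" & prior$min <= 0)) {
    stop("log-uniform priors need min > 0", call. = FALSE)
  }
  prior
}

#' Log prior density of a parameter vector
#'
#' Returns `-Inf` outside the prior bounds, when the three allocation
#' fractions jointly exceed 0.95 (keeping a minimum wood allocation), or when
#' ecological process orderings are violated (soil organic matter must turn
#' over more slowly than litter, fine roots more slowly than foliage, wood
#' more slowly than fine roots); finite inside.  Densities are proper: log-uniform is uniform in log-space
#' over (min, max); truncated normals are renormalised over their bounds.
#'
#' @param theta Named numeric vector matching `prior$name`.
#' @param prior A prior spec tibble, see [default_priors()].
#' @return Scalar log density.
#' @export
log_prior <- function(theta, prior) {
  prior <- validate_priors(prior)
  if (length(theta) != nrow(prior)) {
    stop("length(theta) must match nrow(prior)", call. = FALSE)
  }
  x <- if (is.null(names(theta))) setNames(theta, prior$name) else
    theta[prior$name]
  if (any(is.na(x))) stop("theta names must match prior names", call. = FALSE)
  if (any(x < prior$min | x > prior$max)) return(-Inf)
  alloc <- c("alloc_foliar", "alloc_labile", "alloc_root")
  if (all(alloc %in% prior$name) && sum(x[alloc]) > 0.95) return(-Inf)
  # ecological orderings: soil carbon outlives litter, litter decomposition
  # slower than leaf shedding, roots outlive leaves, wood outlives roots
  ord <- list(c("decomp_som", "decomp_litter"), c("turn_root", "turn_foliar"),
              c("turn_wood", "turn_root"))
  for (o in ord) {
    if (all(o %in% prior$name) && x[o[1]] >= x[o[2]]) return(-Inf)
  }
  lp <- numeric(nrow(prior))
  lu <- prior$dist == "logunif"
  un <- prior$dist == "unif"
  tn <- prior$dist == "tnorm"
  if (any(lu)) {
    lp[lu] <- -log(x[lu]) - log(log(prior$max[lu] / prior$min[lu]))
  }
  if (any(un)) lp[un] <- -log(prior$max[un] - prior$min[un])
  if (any(tn)) {
    z <- pnorm(prior$max[tn], prior$mean[tn], prior$sd[tn]) -
      pnorm(prior$min[tn], prior$mean[tn], prior$sd[tn])
    lp[tn] <- dnorm(x[tn], prior$mean[tn], prior$sd[tn], log = TRUE) - log(z)
  }
  sum(lp)
}

#' Draw from the prior
#'
#' @param prior Prior spec tibble.
#' @param n Number of draws.
#' @return Tibble of draws (n rows, one column per quantity).
#' @export
prior_draw <- function(prior, n = 1) {
  prior <- validate_priors(prior)
  draw_one <- function(row) {
    switch(row$dist,
      logunif = exp(runif(n, log(row$min), log(row$max))),
      unif = runif(n, row$min, row$max),
      tnorm = {
        lo <- pnorm(row$min, row$mean, row$sd)
        hi <- pnorm(row$max, row$mean, row$sd)
        qnorm(runif(n, lo, hi), row$mean, row$sd)
      }
    )
  }
  cols <- lapply(seq_len(nrow(prior)), function(i) draw_one(prior[i, ]))
  names(cols) <- prior$name
  tibble::as_tibble(cols)
}

# natural <-> transformed space; proposals live in z-space.
# For "logit" the transform is on the (min,max)-rescaled value, so bounded
# quantities map to the whole real line.
to_z <- function(x, prior) {
  ifelse(prior$transform == "log", log(x),
         qlogis((x - prior$min) / (prior$max - prior$min)))
}

from_z <- function(z, prior) {
  ifelse(prior$transform == "log", exp(z),
         prior$min + (prior$max - prior$min) * plogis(z))
}

# log |dx/dz|, the Jacobian that makes z-space sampling target the prior on x
log_jacobian <- function(z, prior) {
  j <- ifelse(prior$transform == "log", z,
              log(prior$max - prior$min) + plogis(z, log.p = TRUE) +
                plogis(-z, log.p = TRUE))
  sum(j)
}
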