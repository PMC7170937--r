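#' Canonical parameter and pool names
#'
#' The process model is parameterised by 20 scalars, always carried as a named
#' numeric vector in this fixed order; initial pool states use the pool order.
#'
#' @format Character vectors.
#' @name canonical-names
NULL

#' @rdname canonical-names
#' @export
PAR_NAMES <- c(
  "lue", "f_auto", "alloc_foliar", "alloc_labile", "alloc_root",
  "labile_release", "lcma", "turn_foliar", "turn_root", "turn_wood",
  "decomp_litter", "decomp_som", "lit2som", "theta", "w_half",
  "cc_foliar", "cc_wood", "cc_litter", "cc_som", "resilience"
)

#' @rdname canonical-names
#' @export
POOL_NAMES <- c("labile", "foliar", "fine_root", "wood", "litter", "som",
                "water")

# parameters that are fractions in [0,1]; the rest are positive rates/scalars
FRACTION_PARS <- c("f_auto", "alloc_foliar", "alloc_labile", "alloc_root",
                   "cc_foliar", "cc_wood", "cc_litter", "cc_som", "resilience")

#' Structural model constants
#'
#' Constants that are part of the model structure rather than of the sampled
#' parameter vector: canopy light-extinction coefficient `k_ext` (Beer-Lambert),
#' reference temperature `t_ref` (deg C) of the exponential temperature scalar,
#' the cap `gt_cap` on that scalar, water bucket capacity `w_max` (mm), and
#' `evap_coef` (mm per gC m-2), the evapotranspiration draw per unit GPP.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of constants.
#' @export
#' @examples
#' model_constants(w_max = 300)
model_constants <- function(...) {
  const <- list(k_ext = 0.5, t_ref = 15, gt_cap = 10, w_max = 300,
                evap_coef = 0.5)
  dots <- list(...)
  stopifnot(all(names(dots) %in% names(const)))
  const[names(dots)] <- dots
  const
}

#' Default (savanna-like) parameter set
#'
#' A dry-tropical-savanna parameterisation: short leaf lifespan, ~20-year wood
#' residence time, high foliar combustion completeness, low soil combustion.
#' Units are monthly rates, gC MJ-1 for `lue`, gC m-2 per unit LAI for `lcma`,
#' mm for `w_half`; all combustion-completeness and allocation entries are
#' fractions.
#'
#' @param ... Named overrides, e.g. `default_params(lue = 1)`.
#' @return Named numeric vector in [PAR_NAMES] order.
#' @export
#' @examples
#' p <- default_params()
#' p[["cc_foliar"]]
default_params <- function(...) {
  p <- c(
    lue = 0.3, f_auto = 0.5,
    alloc_foliar = 0.35, alloc_labile = 0.15, alloc_root = 0.25,
    labile_release = 0.3, lcma = 60,
    turn_foliar = 1 / 6, turn_root = 1 / 18, turn_wood = 1 / 240,
    decomp_litter = 0.03, decomp_som = 0.002, lit2som = 0.01,
    theta = 0.035, w_half = 100,
    cc_foliar = 0.9, cc_wood = 0.1, cc_litter = 0.2, cc_som = 0.005,
    resilience = 0.2
  )
  dots <- unlist(list(...))
  if (length(dots)) {
    stopifnot(all(names(dots) %in% PAR_NAMES))
    p[names(dots)] <- dots
  }
  validate_params(p)
}

#' Validate a parameter vector
#'
#' Checks names, positivity of rates, fraction bounds, and that the three
#' explicit allocation fractions leave a non-negative share for wood.
#'
#' @param params Named numeric vector (order-free; reordered on return).
#' @return The validated vector in canonical order, invisibly usable anywhere
#'   a `ParameterSet` is expected.
#' @export
validate_params <- function(params) {
  if (!is.numeric(params) || is.null(names(params))) {
    stop("`params` must be a named numeric vector", call. = FALSE)
  }
  missing <- setdiff(PAR_NAMES, names(params))
  if (length(missing)) {
    stop("missing parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- params[PAR_NAMES]
  if (any(!is.finite(p))) stop("non-finite parameter value", call. = FALSE)
  if (any(p[FRACTION_PARS] < 0 | p[FRACTION_PARS] > 1)) {
    stop("fraction parameters must lie in [0, 1]", call. = FALSE)
  }
  rates <- setdiff(PAR_NAMES, c(FRACTION_PARS, "lue"))
  if (any(p[rates] <= 0)) {
    stop("rate/scalar parameters must be > 0", call. = FALSE)
  }
  if (p[["lue"]] < 0) stop("lue must be >= 0", call. = FALSE)
  if (p[["alloc_foliar"]] + p[["alloc_labile"]] + p[["alloc_root"]] > 1) {
    stop("allocation fractions exceed 1", call. = FALSE)
  }
  p
}

#' Default initial pool state
#'
#' Savanna-like stocks in gC m-2 (water in mm).
#'
#' @param ... Named overrides.
#' @return Named numeric vector in [POOL_NAMES] order.
#' @export
default_init <- function(...) {
  s <- c(labile = 30, foliar = 90, fine_root = 150, wood = 1500,
         litter = 300, som = 4000, water = 150)
  dots <- unlist(list(...))
  if (length(dots)) {
    stopifnot(all(names(dots) %in% POOL_NAMES))
    s[names(dots)] <- dots
  }
  validate_state(s)
}

#' Validate a pool-state vector
#' @param state Named numeric vector of the seven pools.
#' @return The validated vector in canonical order.
#' @export
validate_state <- function(state) {
  if (!is.numeric(state) || is.null(names(state))) {
    stop("`state` must be a named numeric vector", call. = FALSE)
  }
  missing <- setdiff(POOL_NAMES, names(state))
  if (length(missing)) {
    stop("missing pools: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  s <- state[POOL_NAMES]
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("pool values must be finite and >= 0", call. = FALSE)
  }
  s
}

#' Total carbon of a pool state
#'
#' Sum of the six carbon pools; the water bucket is excluded.
#'
#' @param state Named pool vector or trajectory tibble.
#' @return Numeric scalar or vector (one value per month for a trajectory).
#' @export
total_carbon <- function(state) {
  cpools <- setdiff(POOL_NAMES, "water")
  if (is.data.frame(state)) {
    rowSums(as.data.frame(state)[, cpools])
  } else {
    sum(validate_state(state)[cpools])
  }
}
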