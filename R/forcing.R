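#' Build a monthly forcing series
#'
#' A forcing series is a tibble with one row per month and columns `year`,
#' `month`, `days`, `t_mean` (deg C), `precip` (mm month-1), `sw_rad`
#' (MJ m-2 d-1) and `ba_frac` (fraction of the cell burned that month).
#'
#' @param t_mean,precip,sw_rad Numeric vectors, one value per month.
#' @param ba_frac Burned fraction per month, in \[0, 1\].
#' @param start_year First calendar year.
#' @param days Days per month; defaults to the non-leap calendar lengths
#'   recycled over years.
#' @return A `fs_forcing` tibble.
#' @export
#' @examples
#' f <- forcing_series(t_mean = rep(25, 24), precip = rep(80, 24),
#'                     sw_rad = rep(20, 24), ba_frac = rep(0.01, 24),
#'                     start_year = 2001)
#' head(f)
forcing_series <- function(t_mean, precip, sw_rad, ba_frac, start_year = 2001,
                           days = NULL) {
  n <- length(t_mean)
  if (n == 0) stop("forcing must contain at least one month", call. = FALSE)
  if (length(precip) != n || length(sw_rad) != n || length(ba_frac) != n) {
    stop("all forcing vectors must have the same length", call. = FALSE)
  }
  mon <- rep_len(1:12, n)
  if (is.null(days)) {
    days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[mon]
  }
  out <- tibble::tibble(
    year = start_year + (seq_len(n) - 1) %/% 12,
    month = mon,
    days = days,
    t_mean = as.numeric(t_mean),
    precip = as.numeric(precip),
    sw_rad = as.numeric(sw_rad),
    ba_frac = as.numeric(ba_frac)
  )
  validate_forcing(out)
}

#' Validate a forcing series
#'
#' @param forcing A data frame with the forcing columns.
#' @return The forcing as a classed `fs_forcing` tibble.
#' @export
validate_forcing <- function(forcing) {
  need <- c("year", "month", "days", "t_mean", "precip", "sw_rad", "ba_frac")
  missing <- setdiff(need, names(forcing))
  if (length(missing)) {
    stop("forcing lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(forcing) == 0) stop("empty forcing series", call. = FALSE)
  if (any(forcing$ba_frac < 0 | forcing$ba_frac > 1)) {
    stop("ba_frac must lie in [0, 1]", call. = FALSE)
  }
  if (any(forcing$precip < 0) || any(forcing$sw_rad < 0)) {
    stop("precip and sw_rad must be >= 0", call. = FALSE)
  }
  if (any(!forcing$days %in% 28:31)) {
    stop("days must be in 28..31", call. = FALSE)
  }
  out <- tibble::as_tibble(forcing)
  class(out) <- unique(c("fs_forcing", class(out)))
  out
}

# matrix view consumed by the compiled core
forcing_matrix <- function(forcing) {
  as.matrix(forcing[, c("t_mean", "precip", "sw_rad", "days", "ba_frac")])
}

#' Read / write a forcing series as CSV
#'
#' @param path File path.
#' @return `read_forcing_csv()` returns a validated `fs_forcing` tibble.
#' @export
read_forcing_csv <- function(path) {
  validate_forcing(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_forcing_csv
#' @param forcing Forcing tibble to write.
#' @export
write_forcing_csv <- function(forcing, path) {
  readr::write_csv(validate_forcing(forcing), path)
  invisible(path)
}
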