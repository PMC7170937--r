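#' Plot a simulated trajectory
#'
#' Monthly GPP, respiration components, fire emissions and NEE over time.
#'
#' @param object A `fs_trajectory`.
#' @param fluxes Flux columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fs_trajectory <- function(object,
                                   fluxes = c("gpp", "ra", "rh_litter",
                                              "rh_som", "fire", "nee"),
                                   ...) {
  df <- tibble::as_tibble(object)
  df$t <- df$year + (df$month - 0.5) / 12
  long <- tidyr::pivot_longer(df[, c("t", fluxes)], -"t",
                              names_to = "flux", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~flux, scales = "free_y") +
    ggplot2::labs(x = "year", y = expression(gC ~ m^-2 ~ month^-1)) +
    ggplot2::theme_minimal()
}

#' Plot counterfactual delta series
#'
#' Annual ensemble medians with interquartile ribbons for the
#' observed-minus-fixed burned-area differences; the experiment window is
#' shaded.
#'
#' @param object A `fs_delta`.
#' @param variables Delta variables to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fs_delta <- function(object, variables = c("fire", "gpp", "ter",
                                                    "nee", "nbe"), ...) {
  df <- dplyr::filter(object$annual, .data$variable %in% variables)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$q50))
  if (!is.null(object$window_years)) {
    p <- p + ggplot2::annotate("rect", xmin = min(object$window_years) - 0.5,
                               xmax = max(object$window_years) + 0.5,
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.3, fill = "firebrick") +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "year",
                  y = expression(Delta ~ flux ~ (gC ~ m^-2 ~ yr^-1))) +
    ggplot2::theme_minimal()
}

#' Plot airborne-fraction series
#'
#' @param af Tibble with `year` and the airborne-fraction columns from
#'   [run_pipeline()] (`af_obs`, `af_process`, `af_adjusted`).
#' @return A ggplot object.
#' @export
plot_af <- function(af) {
  long <- tidyr::pivot_longer(af, -"year", names_to = "series",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "year", y = "airborne fraction", colour = NULL) +
    ggplot2::theme_minimal()
}
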