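# broom-style accessors and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trajectory into long format
#'
#' @param x a `mito_trajectory`
#' @param what `"states"` (default) or `"fluxes"`
#' @param ... unused
#' @return long tibble: `time`, `variable`, `value`.
#' @export
tidy.mito_trajectory <- function(x, what = c("states", "fluxes"), ...) {
  what <- match.arg(what)
  cols <- if (what == "states") state_names() else flux_names()
  tidyr::pivot_longer(x[, c("time", cols)], -"time",
                      names_to = "variable", values_to = "value")
}

#' One-row summary of a trajectory
#'
#' Regime classification plus final state highlights.
#'
#' @param x a `mito_trajectory`
#' @param transient discarded before classification (s)
#' @param ... passed to [classify_and_measure()]
#' @return one-row tibble.
#' @export
glance.mito_trajectory <- function(x, transient = min(5000, max(x$time) / 2),
                                   ...) {
  cm <- classify_and_measure(x, transient = transient, ...)
  st <- cm$state_stats
  g <- function(v) st$mean[st$variable == v]
  tibble::tibble(regime = cm$regime, period = cm$period,
                 n_periods = cm$n_periods,
                 Cac_mean = g("Cac"), ATPc_mean = g("ATPc"),
                 DPsi_mean = g("DPsi"),
                 t_end = max(x$time))
}

#' Tidy a scan
#'
#' A scan is already tabular; this returns it as a plain tibble (drops
#' attributes), for composing with dplyr.
#'
#' @param x a `mito_scan`
#' @param ... unused
#' @return tibble.
#' @export
tidy.mito_scan <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' One-row summary of a scan
#'
#' @param x a `mito_scan`
#' @param ... unused
#' @return tibble with grid extent, number of oscillatory points, the
#'   efficiency maximum and its location.
#' @export
glance.mito_scan <- function(x, ...) {
  osc <- x$regime == "oscillatory"
  imax <- which.max(x$eta)
  tibble::tibble(
    param = x$param[1], n_points = nrow(x), n_oscillatory = sum(osc),
    eta_max = x$eta[imax], eta_argmax = x$value[imax],
    Tsigma_max = max(x$Tsigma, na.rm = TRUE)
  )
}

#' Plot a trajectory
#'
#' Cytosolic Ca2+ and ATP time courses (the signaling/energy pair), faceted.
#'
#' @param object a `mito_trajectory`
#' @param vars variables to display
#' @param ... unused
#' @return a ggplot.
#' @export
autoplot.mito_trajectory <- function(object, vars = c("Cac", "ATPc"), ...) {
  d <- tidy.mito_trajectory(object)
  d <- d[d$variable %in% vars, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' Plot a scan
#'
#' Efficiency (or another ledger column) against the scanned parameter,
#' with regime shown by point shape (filled = oscillatory).
#'
#' @param object a `mito_scan`
#' @param y column to display (default `eta`)
#' @param ... unused
#' @return a ggplot.
#' @export
autoplot.mito_scan <- function(object, y = "eta", ...) {
  d <- tidy.mito_scan(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data[[y]],
                                  shape = .data$regime)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::scale_shape_manual(values = c(steady = 1, oscillatory = 16,
                                           transient = 4)) +
    ggplot2::labs(x = d$param[1], y = y)
}

#' Efficiency-dissipation portrait of a scan
#'
#' @param scan a `mito_scan`
#' @return a ggplot of efficiency against total dissipation.
#' @export
plot_efficiency_dissipation <- function(scan) {
  d <- tidy.mito_scan(scan)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$Tsigma, y = .data$eta,
                                  shape = .data$regime)) +
    ggplot2::geom_path(linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::scale_shape_manual(values = c(steady = 1, oscillatory = 16,
                                           transient = 4)) +
    ggplot2::labs(x = "total dissipation (mM/s x J/mol)", y = "efficiency")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
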