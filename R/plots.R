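#' Plot a morphometric cohort
#'
#' Per-embryo growth curves faceted by quantity, with the cohort mean
#' overlaid.
#'
#' @param object A `morpho_cohort` tibble.
#' @param quantities Character vector of columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.morpho_cohort <- function(object,
                                   quantities = c("N", "s", "Vt", "Vl", "Vo", "Sl"),
                                   ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = dplyr::all_of(intersect(quantities, names(object))),
    names_to = "quantity", values_to = "value"
  )
  grp <- if ("side" %in% names(long)) "side" else "embryo_id"
  ggplot(long, aes(x = .data$t, y = .data$value)) +
    geom_line(aes(group = interaction(.data$embryo_id, .data[[grp]]),
      colour = .data[[grp]]
    ), alpha = 0.5) +
    facet_wrap(~quantity, scales = "free_y") +
    labs(x = "time (hpf)", y = NULL) +
    theme_minimal()
}

#' Plot a simulated vesicle trajectory
#'
#' Radius, wall thickness, pressure and flux against time, with event
#' times marked.
#'
#' @param object A `vesicle_trajectory` from [simulate_vesicle()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vesicle_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("t", "R", "h", "P", "Omega")],
    cols = c("R", "h", "P", "Omega"),
    names_to = "variable", values_to = "value"
  )
  gg <- ggplot(long, aes(x = .data$t, y = .data$value)) +
    geom_line() +
    facet_wrap(~variable, scales = "free_y") +
    labs(x = "time (hpf)", y = NULL) +
    theme_minimal()
  evs <- attr(object, "events")
  if (length(evs) > 0) {
    ev_t <- vapply(evs, function(e) e$t, numeric(1))
    gg <- gg + geom_vline(xintercept = ev_t, linetype = "dashed", colour = "grey40")
  }
  gg
}

#' Plot the flux-deficit regression
#'
#' Pooled excess flux against fractional volume deficit with the fitted
#' catch-up line.
#'
#' @param object A `flux_deficit_fit` from [flux_deficit_regression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flux_deficit_fit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$deficit, y = .data$excess_flux)) +
    geom_point(alpha = 0.6) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "firebrick") +
    labs(
      x = expression(Delta * V[l] / V[l]),
      y = expression(tilde(Omega) - Omega ~ "(um/hr)"),
      subtitle = sprintf("kappa_hat = %.2f", object$kappa_hat)
    ) +
    theme_minimal()
}

#' Plot a pressure trace with its stages
#'
#' @param object A `pressure_trace` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pressure_trace <- function(object, ...) {
  ggplot(object, aes(x = .data$t_s, y = .data$P_pa, colour = .data$stage)) +
    geom_line() +
    scale_colour_brewer(palette = "Dark2") +
    labs(x = "time (s)", y = "pressure (Pa)") +
    theme_minimal()
}

#' Plot a surface-area growth decomposition
#'
#' Stretching and division contributions with the break-even time marked.
#'
#' @param object A `surface_decomposition` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.surface_decomposition <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("t", "stretch_term", "division_term", "total_rate")],
    cols = -"t", names_to = "term", values_to = "rate"
  )
  gg <- ggplot(long, aes(x = .data$t, y = .data$rate, colour = .data$term)) +
    geom_line() +
    labs(x = "time (hpf)", y = expression(dS[l] / dt ~ "(um2/hr)")) +
    theme_minimal()
  be <- break_even_time(object)
  if (!is.na(be)) {
    gg <- gg + geom_vline(xintercept = be, linetype = "dashed")
  }
  gg
}
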