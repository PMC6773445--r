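#' Local quadratic fit for smoothed values and derivatives
#'
#' Fits a least-squares quadratic polynomial to the points within
#' `half_window` hours of each evaluation time and returns the fitted value
#' and first derivative there. At the ends of the series the window simply
#' loses its missing side (it shrinks one-sidedly); estimates computed from
#' such asymmetric windows are flagged `edge = TRUE` as lower-confidence.
#'
#' @param t,y Sample times (hours) and values.
#' @param t_eval Times at which to evaluate (defaults to `t`).
#' @param half_window Half-width of the fitting window, hours.
#' @return Tibble with columns `t`, `value`, `deriv`, `n_points`, `edge`.
#' @export
#' @examples
#' t <- 0:10
#' quadratic_window_fit(t, 2 * t^2 + 3 * t + 1, half_window = 3)
quadratic_window_fit <- function(t, y, t_eval = NULL, half_window = 3) {
  check_number(t, "t")
  check_number(half_window, "half_window", lower = 0, strict_lower = TRUE)
  if (length(t) != length(y)) abort_bad_arg("`t` and `y` must have equal length.")
  keep <- !is.na(y)
  t_all <- t[keep]
  y_all <- y[keep]
  if (is.null(t_eval)) t_eval <- t_all
  purrr::map_dfr(t_eval, function(t0) {
    inside <- abs(t_all - t0) <= half_window + 1e-9
    n <- sum(inside)
    if (n < 3) {
      abort_bad_arg(sprintf(
        "Fewer than 3 points within %.3g h of t = %.3g.", half_window, t0
      ))
    }
    x <- t_all[inside] - t0
    fit <- stats::lm.fit(cbind(1, x, x^2), y_all[inside])
    b <- fit$coefficients
    tibble::tibble(
      t = t0,
      value = b[[1]],
      deriv = b[[2]],
      n_points = n,
      edge = min(x) > -half_window + 1e-9 | max(x) < half_window - 1e-9
    )
  })
}

# Average over embryos when an embryo_id column is present, then return
# the per-time mean series of the requested columns.
cohort_mean_series <- function(data, cols) {
  check_columns(data, c("t", cols), "data")
  if ("embryo_id" %in% names(data)) {
    data <- data %>%
      dplyr::group_by(.data$t) %>%
      dplyr::summarise(
        dplyr::across(dplyr::all_of(cols), ~ mean(.x, na.rm = TRUE)),
        .groups = "drop"
      )
  }
  dplyr::arrange(tibble::as_tibble(data[, c("t", cols)]), .data$t)
}

#' Transepithelial fluid flux from lumen volume and surface area
#'
#' Computes the fluid influx per unit lumenal surface area,
#' `Omega(t) = (dVl/dt) / Sl(t)` in um/hr, with the volume derivative and
#' the smoothed surface area both estimated by local quadratic fitting.
#' When the input contains several embryos the cohort mean curves are used.
#'
#' @param data Data frame with columns `t` (hpf), `Vl` (pl), `Sl` (um^2),
#'   optionally `embryo_id`.
#' @param half_window Quadratic fitting half-window, hours.
#' @return A `flux_series` tibble with columns `t`, `Omega` (um/hr), and
#'   `edge` (asymmetric-window flag).
#' @export
#' @examples
#' cohort <- generate_wildtype_cohort(generator_spec(n_embryos = 5))
#' flux <- compute_flux(cohort)
#' mean(flux$Omega[flux$t >= 21])
compute_flux <- function(data, half_window = 3) {
  series <- cohort_mean_series(data, c("Vl", "Sl"))
  vfit <- quadratic_window_fit(series$t, series$Vl, half_window = half_window)
  sfit <- quadratic_window_fit(series$t, series$Sl, half_window = half_window)
  if (any(sfit$value <= 0)) {
    abort_bad_arg("Fitted `Sl` must be positive at every evaluated time.")
  }
  out <- tibble::tibble(
    t = vfit$t,
    Omega = vfit$deriv * UM3_PER_PL / sfit$value,
    edge = vfit$edge
  )
  class(out) <- c("flux_series", class(out))
  out
}

#' Tissue growth rate decomposed into division and cell-size terms
#'
#' Splits the tissue growth rate `j = dVt/dt` (with `Vt = N * s`) into the
#' proliferation term `s * dN/dt` and the cell-size term `N * ds/dt`. In
#' early growth these offset each other (tissue volume nearly constant);
#' rows where the net rate is small compared to the gross terms are flagged
#' `offsetting`.
#'
#' @param data Data frame with columns `t`, `N`, `s` (pl), optionally
#'   `embryo_id`.
#' @param half_window Quadratic fitting half-window, hours.
#' @return Tibble with columns `t`, `division_term`, `size_term`, `j`
#'   (pl/hr) and `offsetting`.
#' @export
tissue_growth_decomposition <- function(data, half_window = 3) {
  series <- cohort_mean_series(data, c("N", "s"))
  nfit <- quadratic_window_fit(series$t, series$N, half_window = half_window)
  sfit <- quadratic_window_fit(series$t, series$s, half_window = half_window)
  division <- sfit$value * nfit$deriv
  size <- nfit$value * sfit$deriv
  j <- division + size
  gross <- abs(division) + abs(size)
  tibble::tibble(
    t = nfit$t,
    division_term = division,
    size_term = size,
    j = j,
    offsetting = abs(j) < 0.2 * gross,
    edge = nfit$edge
  )
}

#' Lumenal surface-area growth decomposed into stretching and division
#'
#' With `Sl = psi * N` (mean apical cell area times cell number), the
#' surface growth rate splits as `dSl/dt = N dpsi/dt + psi dN/dt`: cell
#' stretching versus proliferation of apical endfeet. The break-even time
#' is the interpolated instant at which the division term first exceeds
#' the stretching term.
#'
#' @param data Data frame with columns `t`, `Sl`, `N`, optionally
#'   `embryo_id`; `psi` is derived as `Sl / N`.
#' @param half_window Quadratic fitting half-window, hours.
#' @return A `surface_decomposition` tibble with columns `t`,
#'   `stretch_term`, `division_term`, `total_rate` (um^2/hr) and an
#'   attribute `break_even_time` (hpf; `NA` with a message when the terms
#'   never cross inside the span).
#' @export
#' @examples
#' cohort <- generate_wildtype_cohort(generator_spec())
#' dec <- surface_decomposition(cohort)
#' break_even_time(dec)
surface_decomposition <- function(data, half_window = 3) {
  series <- cohort_mean_series(data, c("Sl", "N"))
  series$psi <- series$Sl / series$N
  nfit <- quadratic_window_fit(series$t, series$N, half_window = half_window)
  pfit <- quadratic_window_fit(series$t, series$psi, half_window = half_window)
  sfit <- quadratic_window_fit(series$t, series$Sl, half_window = half_window)
  out <- tibble::tibble(
    t = nfit$t,
    stretch_term = nfit$value * pfit$deriv,
    division_term = pfit$value * nfit$deriv,
    total_rate = sfit$deriv,
    edge = nfit$edge
  )
  be <- estimate_break_even(out)
  if (is.na(be)) {
    rlang::inform("No division/stretching crossing inside the series span; break-even time is NA.")
  }
  class(out) <- c("surface_decomposition", class(out))
  attr(out, "break_even_time") <- be
  out
}

#' @rdname surface_decomposition
#' @param x A `surface_decomposition` object.
#' @export
break_even_time <- function(x) {
  attr(x, "break_even_time")
}

# Break-even estimate: where the division term overtakes the stretching
# term. On noisy data the single local crossing is fragile, so the term
# difference is fitted with a quadratic in time over the well-supported
# (non-edge) points and the upward zero-crossing of the fit is reported;
# degenerate cases (one term always ahead) are resolved exactly.
estimate_break_even <- function(dec) {
  diff_terms <- dec$division_term - dec$stretch_term
  t <- dec$t
  if (all(diff_terms > 0)) {
    return(t[1])
  }
  if (all(diff_terms <= 0)) {
    return(NA_real_)
  }
  use <- if (sum(!dec$edge) >= 5) !dec$edge else rep(TRUE, length(t))
  fit <- stats::lm(diff_terms[use] ~ stats::poly(t[use], 2, raw = TRUE))
  grid <- seq(min(t), max(t), length.out = 2001)
  f <- cbind(1, grid, grid^2) %*% coef(fit)
  up <- which(f[-1] > 0 & f[-length(f)] <= 0)
  if (length(up) > 0) {
    i <- up[length(up)]
    return(grid[i] - f[i] * (grid[i + 1] - grid[i]) / (f[i + 1] - f[i]))
  }
  # fitted curve never crosses upward inside the span: fall back to the
  # interpolated local crossing of the raw terms
  raw_up <- which(diff_terms[-1] > 0 & diff_terms[-length(diff_terms)] <= 0)
  if (length(raw_up) == 0) {
    return(NA_real_)
  }
  i <- raw_up[1]
  t[i] - diff_terms[i] * (t[i + 1] - t[i]) / (diff_terms[i + 1] - diff_terms[i])
}

#' Left/right asymmetry of a paired puncture experiment
#'
#' Normalized differences between the control and punctured sides:
#' `dVl_rel = (Vl_control - Vl_punctured) / Vl_control` and the same for
#' the mean wall thickness of the thinning (medial + lateral) regions;
#' the stiff poles are excluded.
#'
#' @param pair A `paired_experiment` from [generate_puncture_experiment()],
#'   or any tibble with a `side` column (`"control"`/`"punctured"`) and
#'   columns `t`, `Vl`, `h_medial`, `h_lateral`.
#' @return Tibble with columns `t`, `dVl_rel`, `dh_rel`.
#' @export
asymmetry_metrics <- function(pair) {
  check_columns(pair, c("side", "t", "Vl", "h_medial", "h_lateral"), "pair")
  ctrl <- pair[pair$side == "control", ]
  pun <- pair[pair$side == "punctured", ]
  merged <- dplyr::inner_join(
    ctrl[, c("t", "Vl", "h_medial", "h_lateral")],
    pun[, c("t", "Vl", "h_medial", "h_lateral")],
    by = "t", suffix = c("_c", "_p")
  )
  if (any(merged$Vl_c <= 0)) {
    abort_bad_arg("Control lumen volume must be positive at all time points.")
  }
  h_c <- (merged$h_medial_c + merged$h_lateral_c) / 2
  h_p <- (merged$h_medial_p + merged$h_lateral_p) / 2
  tibble::tibble(
    t = merged$t,
    dVl_rel = (merged$Vl_c - merged$Vl_p) / merged$Vl_c,
    dh_rel = (h_c - h_p) / h_c
  )
}

#' Flux-deficit regression (catch-up gain)
#'
#' Pools post-puncture time points across paired experiments and regresses
#' the excess regeneration flux `Omega_punctured - Omega_control` (um/hr)
#' on the fractional lumen-volume deficit `(Vl_c - Vl_p)/Vl_c`. The slope
#' estimates the catch-up gain kappa of the linear pressure-flux feedback;
#' published experiments put it around 3-5.
#'
#' @param pairs A `paired_experiment` or a list of them.
#' @param half_window Quadratic fitting half-window for the flux, hours.
#'   The default (2 h) is narrower than the kinetics default so that the
#'   informative high-deficit phase right after the puncture contributes:
#'   estimates whose window straddles the puncture discontinuity are
#'   excluded, as the local quadratic is not a valid model across a jump.
#' @param calibrate If `TRUE` (default) the noisy per-time deficits are
#'   replaced by their smooth per-pair time trend (quadratic in time)
#'   before the final least squares — a regression-calibration step that
#'   removes most of the attenuation caused by measurement noise in the
#'   regressor. `FALSE` regresses on the observed deficits directly.
#' @param min_points Minimum pooled points required.
#' @return A `flux_deficit_fit` object; see [tidy()], [glance()] and
#'   `autoplot()` methods. The slope is available as `$kappa_hat`.
#' @export
#' @examples
#' pairs <- lapply(1:5, function(i) {
#'   generate_puncture_experiment(generator_spec(seed = i), seed = i)
#' })
#' fit <- flux_deficit_regression(pairs)
#' fit$kappa_hat
flux_deficit_regression <- function(pairs, half_window = 2,
                                    calibrate = TRUE, min_points = 5) {
  if (inherits(pairs, "paired_experiment") || is.data.frame(pairs)) {
    pairs <- list(pairs)
  }
  pooled <- purrr::imap_dfr(pairs, function(pair, i) {
    check_columns(pair, c("side", "t", "Vl", "Sl"), "pair")
    events <- attr(pair, "events")
    t_punc <- if (!is.null(events) && any(events$kind == "puncture")) {
      min(events$t[events$kind == "puncture"])
    } else {
      -Inf
    }
    ctrl <- pair[pair$side == "control", ]
    pun <- pair[pair$side == "punctured", ]
    f_c <- compute_flux(ctrl, half_window = half_window)
    f_p <- compute_flux(pun, half_window = half_window)
    # deficit from locally smoothed volumes, so that measurement noise in
    # the regressor does not attenuate the slope
    v_c <- quadratic_window_fit(ctrl$t, ctrl$Vl, half_window = half_window)
    v_p <- quadratic_window_fit(pun$t, pun$Vl, half_window = half_window)
    merged <- dplyr::inner_join(f_c, f_p, by = "t", suffix = c("_c", "_p"))
    merged$Vl_c <- v_c$value[match(merged$t, v_c$t)]
    merged$Vl_p <- v_p$value[match(merged$t, v_p$t)]
    # exclude windows straddling the puncture jump and the lower-confidence
    # one-sided windows at the series ends
    merged <- merged[merged$t >= t_punc + half_window & !merged$edge_c, ]
    tibble::tibble(
      pair = i,
      t = merged$t,
      elapsed = merged$t - t_punc,
      deficit = (merged$Vl_c - merged$Vl_p) / merged$Vl_c,
      excess_flux = merged$Omega_p - merged$Omega_c
    )
  })
  if (nrow(pooled) < min_points) {
    abort_bad_arg(sprintf("Need at least %d pooled points.", min_points))
  }
  if (stats::sd(pooled$deficit) < 1e-12) {
    abort_bad_arg("Degenerate design: all volume deficits are equal.")
  }
  if (calibrate && length(unique(pooled$elapsed)) >= 4 &&
    all(is.finite(pooled$elapsed))) {
    # recovery trajectories share a common decay profile in time since
    # puncture; projecting the noisy deficits onto that profile gives a
    # regressor free of per-measurement noise
    pooled$deficit_used <- unname(stats::fitted(
      stats::lm(pooled$deficit ~ stats::poly(pooled$elapsed, 2))
    ))
  } else {
    pooled$deficit_used <- pooled$deficit
  }
  if (stats::sd(pooled$deficit_used) < 1e-12) {
    abort_bad_arg("Degenerate design: all volume deficits are equal.")
  }
  fit <- stats::lm(excess_flux ~ deficit_used, data = pooled)
  structure(
    list(
      kappa_hat = unname(coef(fit)[["deficit_used"]]),
      intercept = unname(coef(fit)[["(Intercept)"]]),
      fit = fit,
      data = pooled
    ),
    class = "flux_deficit_fit"
  )
}

#' @export
print.flux_deficit_fit <- function(x, ...) {
  cat("<flux_deficit_fit>\n")
  cat(sprintf(
    "  kappa_hat = %.3g um/hr per unit fractional deficit (intercept %.3g)\n",
    x$kappa_hat, x$intercept
  ))
  cat(sprintf(
    "  %d pooled points from %d pair(s)\n",
    nrow(x$data), length(unique(x$data$pair))
  ))
  invisible(x)
}

#' @export
tidy.flux_deficit_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "kappa"),
    estimate = as.numeric(s[, 1]),
    std.error = as.numeric(s[, 2]),
    statistic = as.numeric(s[, 3]),
    p.value = as.numeric(s[, 4])
  )
}

#' @export
glance.flux_deficit_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    kappa_hat = x$kappa_hat,
    r.squared = s$r.squared,
    sigma = s$sigma,
    nobs = nrow(x$data)
  )
}

#' Summarize cohort kinetics as a machine-readable report
#'
#' Convenience wrapper running the flux computation and both growth
#' decompositions on a cohort, returning the headline kinetic quantities.
#'
#' @param cohort A `morpho_cohort` tibble.
#' @param half_window Quadratic fitting half-window, hours.
#' @param flux_window Time window (hpf) over which the mean flux is taken.
#' @return Named list with `flux_mean`, `break_even_time`,
#'   `tissue_growth_late` (mean j after 28 hpf, pl/hr) and the windows.
#' @export
kinetics_report <- function(cohort, half_window = 3, flux_window = c(21, 45)) {
  flux <- compute_flux(cohort, half_window = half_window)
  dec <- surface_decomposition(cohort, half_window = half_window)
  tg <- tissue_growth_decomposition(cohort, half_window = half_window)
  in_win <- flux$t >= flux_window[1] & flux$t <= flux_window[2]
  list(
    flux_mean = mean(flux$Omega[in_win]),
    flux_window = flux_window,
    break_even_time = break_even_time(dec),
    tissue_growth_late = mean(tg$j[tg$t >= 28]),
    half_window = half_window
  )
}
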