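#' Laplace wall stress of a thin pressurized spherical shell
#'
#' Force balance on a hemisphere of a thin spherical pressure vessel gives
#' the in-plane tissue stress `sigma = P * R / (2 * h)`.
#'
#' @param P Lumenal pressure, Pa.
#' @param R Average shell radius, um.
#' @param h Wall thickness, um (must be > 0).
#' @return Stress in Pa.
#' @export
#' @examples
#' laplace_stress(P = 116, R = 36, h = 13)
laplace_stress <- function(P, R, h) {
  check_number(R, "R", lower = 0, strict_lower = TRUE)
  check_number(h, "h", lower = 0, strict_lower = TRUE)
  P * R / (2 * h)
}

#' Stokes viscous stress of a spherically expanding wall
#'
#' For a viscous wall deforming in spherical geometry the shear stress is
#' `sigma = 4 * mu * (1/R) * dR/dt`.
#'
#' @param mu Wall viscosity, Pa·s.
#' @param R Average shell radius, um.
#' @param Rdot Radial growth rate. Interpreted in um/s by default; set
#'   `rdot_unit = "um/hr"` for hourly rates.
#' @param rdot_unit Unit of `Rdot`.
#' @return Stress in Pa.
#' @export
#' @examples
#' stokes_stress(mu = 6.26e6, R = 36, Rdot = 2.31e-4)
stokes_stress <- function(mu, R, Rdot, rdot_unit = c("um/s", "um/hr")) {
  rdot_unit <- rlang::arg_match(rdot_unit)
  check_number(R, "R", lower = 0, strict_lower = TRUE)
  if (rdot_unit == "um/hr") Rdot <- Rdot / SEC_PER_HR
  4 * mu * Rdot / R
}

#' Effective wall viscosity from pressure, geometry and growth rate
#'
#' Equating the Laplace stress `P R / (2 h)` with the Stokes viscous stress
#' `4 mu Rdot / R` yields the effective tissue viscosity
#' `mu = P R^2 / (8 h Rdot)`. With interval-averaged probe and imaging data
#' this gives ~6.3e6 Pa·s at 24-36 hpf rising to ~2.2e7 Pa·s at 36-48 hpf.
#'
#' @param P Lumenal pressure, Pa.
#' @param R Average shell radius, um.
#' @param h Wall thickness, um.
#' @param Rdot Radial growth rate (`rdot_unit`, default um/s; must be
#'   nonzero).
#' @param rdot_unit Unit of `Rdot`.
#' @return Viscosity in Pa·s.
#' @export
#' @examples
#' effective_viscosity(P = 116, R = 36, h = 13, Rdot = 2.31e-4)
effective_viscosity <- function(P, R, h, Rdot, rdot_unit = c("um/s", "um/hr")) {
  rdot_unit <- rlang::arg_match(rdot_unit)
  check_number(R, "R", lower = 0, strict_lower = TRUE)
  check_number(h, "h", lower = 0, strict_lower = TRUE)
  if (rdot_unit == "um/hr") Rdot <- Rdot / SEC_PER_HR
  if (any(Rdot == 0)) {
    abort_bad_arg("`Rdot` must be nonzero: viscosity is undefined for a static wall.")
  }
  P * R^2 / (8 * h * Rdot)
}

#' Propagate measurement error into the viscosity estimate
#'
#' Computes the standard deviation of the effective viscosity from the
#' means and SDs of its inputs. `mode = "paper"` applies the published
#' error-propagation form
#' `dmu/mu = (1/8) * sqrt((dP/P)^2 + 2 (dR/R)^2 + (dh/h)^2 + (dRdot/Rdot)^2)`,
#' which reproduces the published viscosity SD table; `mode = "standard"`
#' applies textbook first-order propagation for `mu = P R^2/(8 h Rdot)`,
#' `dmu/mu = sqrt((dP/P)^2 + 4 (dR/R)^2 + (dh/h)^2 + (dRdot/Rdot)^2)`.
#' Both are exposed because the published prefactor 1/8 and radius
#' coefficient 2 differ from the first-order result; neither is silently
#' "corrected".
#'
#' @param est Named list or one-row data frame with `P_mean`, `P_sd`,
#'   `R_mean`, `R_sd`, `h_mean`, `h_sd`, `Rdot_mean`, `Rdot_sd`
#'   (`Rdot` in um/s).
#' @param mode `"paper"` (default) or `"standard"`.
#' @return SD of the viscosity, Pa·s.
#' @export
#' @examples
#' propagate_viscosity_error(list(
#'   P_mean = 116, P_sd = 23.1, R_mean = 36, R_sd = 0.18,
#'   h_mean = 13, h_sd = 0.12, Rdot_mean = 2.31e-4, Rdot_sd = 0.73e-4
#' ))
propagate_viscosity_error <- function(est, mode = c("paper", "standard")) {
  mode <- rlang::arg_match(mode)
  need <- c(
    "P_mean", "P_sd", "R_mean", "R_sd",
    "h_mean", "h_sd", "Rdot_mean", "Rdot_sd"
  )
  missing <- setdiff(need, names(est))
  if (length(missing) > 0) {
    abort_bad_arg(paste0("`est` is missing: ", paste(missing, collapse = ", "), "."))
  }
  for (nm in c("P_mean", "R_mean", "h_mean", "Rdot_mean")) {
    check_number(est[[nm]], nm, lower = 0, strict_lower = TRUE)
  }
  for (nm in c("P_sd", "R_sd", "h_sd", "Rdot_sd")) {
    check_number(est[[nm]], nm, lower = 0)
  }
  mu <- effective_viscosity(est$P_mean, est$R_mean, est$h_mean, est$Rdot_mean)
  rel2 <- (est$P_sd / est$P_mean)^2 +
    (est$h_sd / est$h_mean)^2 +
    (est$Rdot_sd / est$Rdot_mean)^2
  rel_mu <- switch(mode,
    paper = sqrt(rel2 + 2 * (est$R_sd / est$R_mean)^2) / 8,
    standard = sqrt(rel2 + 4 * (est$R_sd / est$R_mean)^2)
  )
  mu * rel_mu
}

#' Interval-averaged wall measurements for the viscosity estimate
#'
#' The two wild-type measurement intervals (24-36 and 36-48 hpf) with
#' interval means and SDs of lumenal pressure, average radius, wall
#' thickness and radial growth rate, as used to estimate the effective
#' wall viscosity.
#'
#' @return Tibble with columns `interval`, `P_mean`, `P_sd` (Pa),
#'   `R_mean`, `R_sd` (um), `h_mean`, `h_sd` (um), `Rdot_mean`, `Rdot_sd`
#'   (um/s).
#' @export
viscosity_interval_data <- function() {
  tibble::tibble(
    interval = c("24-36", "36-48"),
    P_mean = c(116, 166), P_sd = c(23.1, 23.4),
    R_mean = c(36, 48), R_sd = c(0.18, 0.22),
    h_mean = c(13, 10), h_sd = c(0.12, 0.21),
    Rdot_mean = c(2.31e-4, 2.15e-4), Rdot_sd = c(0.73e-4, 0.95e-4)
  )
}

#' Effective-viscosity table with propagated errors
#'
#' Applies [effective_viscosity()] and [propagate_viscosity_error()] to
#' each row of an interval summary table.
#'
#' @param data Tibble like [viscosity_interval_data()].
#' @param error_mode Passed to [propagate_viscosity_error()].
#' @return The input with `mu` and `mu_sd` columns appended (Pa·s).
#' @export
#' @examples
#' viscosity_table(viscosity_interval_data())
viscosity_table <- function(data = viscosity_interval_data(),
                            error_mode = c("paper", "standard")) {
  error_mode <- rlang::arg_match(error_mode)
  check_columns(data, c(
    "P_mean", "P_sd", "R_mean", "R_sd",
    "h_mean", "h_sd", "Rdot_mean", "Rdot_sd"
  ), "data")
  data %>%
    dplyr::mutate(
      mu = effective_viscosity(.data$P_mean, .data$R_mean, .data$h_mean, .data$Rdot_mean),
      mu_sd = purrr::pmap_dbl(
        list(
          .data$P_mean, .data$P_sd, .data$R_mean, .data$R_sd,
          .data$h_mean, .data$h_sd, .data$Rdot_mean, .data$Rdot_sd
        ),
        function(P_mean, P_sd, R_mean, R_sd, h_mean, h_sd, Rdot_mean, Rdot_sd) {
          propagate_viscosity_error(
            list(
              P_mean = P_mean, P_sd = P_sd, R_mean = R_mean, R_sd = R_sd,
              h_mean = h_mean, h_sd = h_sd,
              Rdot_mean = Rdot_mean, Rdot_sd = Rdot_sd
            ),
            mode = error_mode
          )
        }
      )
    )
}

#' Viscoelastic wall material
#'
#' A Maxwell element for the epithelial wall: elastic on short time scales
#' (modulus `k`, also accepted as `G`), viscous on long time scales
#' (viscosity `mu`), with relaxation time `tau = mu / k`. The wall stiffens
#' through development; `stiffening_rate` applies an exponential ramp
#' `exp(rate * (t - t_ref))` to both `mu` and `k` (leaving `tau` fixed),
#' with the default rate matching the ~3.5-fold viscosity rise between the
#' 24-36 and 36-48 hpf measurement intervals.
#'
#' @param mu Wall viscosity, Pa·s.
#' @param k Elastic modulus, Pa. `G` is accepted as a synonym (one of the
#'   two must be given, or the default is used).
#' @param G Synonym for `k`.
#' @param region Optional region label (`"bulk"`, `"medial"`, `"lateral"`,
#'   `"poles"`).
#' @param stiffening_rate Exponential stiffening rate, 1/hr.
#' @param t_ref Reference time (hpf) at which `mu` and `k` apply.
#' @return A `wall_material` object with fields `mu` (Pa·hr, internal
#'   units), `k`, `tau` (hr), `region`, `stiffening_rate`, `t_ref`.
#' @export
#' @examples
#' wall_material()
#' wall_material(mu = 2e7, k = 500)
wall_material <- function(mu = 6.26e6, k = NULL, G = NULL,
                          region = "bulk",
                          stiffening_rate = log(22.2 / 6.26) / 12,
                          t_ref = 30) {
  if (is.null(k)) k <- if (!is.null(G)) G else 200
  check_number(mu, "mu", lower = 0, strict_lower = TRUE)
  check_number(k, "k", lower = 0, strict_lower = TRUE)
  mu_hr <- mu / SEC_PER_HR
  structure(
    list(
      mu = mu_hr, # Pa·hr
      mu_pa_s = mu,
      k = k,
      tau = mu_hr / k, # hr
      region = region,
      stiffening_rate = stiffening_rate,
      t_ref = t_ref
    ),
    class = "wall_material"
  )
}

#' @export
print.wall_material <- function(x, ...) {
  cat("<wall_material>\n")
  cat(sprintf(
    "  mu = %.3g Pa·s, k = %.3g Pa, tau = %.3g hr (%s region)\n",
    x$mu_pa_s, x$k, x$tau, x$region
  ))
  if (x$stiffening_rate != 0) {
    cat(sprintf(
      "  stiffening exp(%.3g/hr) about t = %g hpf\n",
      x$stiffening_rate, x$t_ref
    ))
  }
  invisible(x)
}

material_at <- function(material, t) {
  f <- exp(material$stiffening_rate * (t - material$t_ref))
  list(mu = material$mu * f, k = material$k * f, tau = material$tau)
}

#' Strain response of a Maxwell element to a stress history
#'
#' Integrates the Maxwell constitutive law
#' `epsilon_dot = (sigma_dot + sigma / tau) / E` (elastic modulus `E`,
#' relaxation time `tau`) over a sampled stress history with trapezoidal
#' quadrature, assuming zero stress before the first sample. A step stress
#' therefore produces the instantaneous elastic jump `sigma / E` followed
#' by viscous creep at rate `sigma / (E * tau)`.
#'
#' @param material A [wall_material()] (its `k` and `tau` are used; the
#'   stiffening ramp is not applied — the element is evaluated at fixed
#'   properties).
#' @param data Data frame with columns `t` (hr) and `sigma` (Pa) on a
#'   uniform grid.
#' @return The input with a `strain` column appended (dimensionless).
#' @export
#' @examples
#' mat <- wall_material(mu = 3.6e6, k = 100) # tau = 10 hr
#' t <- seq(0, 5, by = 0.01)
#' creep <- maxwell_response(mat, data.frame(t = t, sigma = 50))
maxwell_response <- function(material, data) {
  stopifnot(inherits(material, "wall_material"))
  check_columns(data, c("t", "sigma"), "data")
  if (material$tau <= 0) abort_bad_arg("`tau` must be positive.")
  t <- data$t
  sigma <- data$sigma
  if (length(t) > 2) {
    dt <- diff(t)
    if (max(abs(dt - dt[1])) > 1e-8 * max(abs(dt))) {
      abort_bad_arg("`t` must be a uniform grid.")
    }
  }
  E <- material$k
  tau <- material$tau
  # cumulative trapezoid of sigma; the elastic term includes the jump from
  # the assumed sigma = 0 pre-history
  n <- length(t)
  integ <- c(0, cumsum((sigma[-1] + sigma[-n]) / 2 * diff(t)))
  data$strain <- sigma / E + integ / (E * tau)
  tibble::as_tibble(data)
}

#' Relative regional material properties from puncture assays
#'
#' Ranks wall regions by relative compliance using staged puncture
#' measurements: the elastic indicator is the fractional thickening at
#' puncture, `(h_post - h_pre) / h_pre`, proportional to `1/k`; the
#' viscous indicator is the normalized decay rate of that response across
#' stages (irreversible remodelling), proportional to `1/mu`. Both are
#' relative measures — no absolute moduli are inferred.
#'
#' @param data Tibble with columns `region`, `stage` (hpf), `h_pre`,
#'   `h_post` (um), e.g. from [generate_material_assay()]; replicate rows
#'   per region/stage are averaged.
#' @return List with `by_stage` (tibble `region`, `stage`,
#'   `elastic_indicator`) and `by_region` (tibble `region`,
#'   `elastic_indicator` (stage mean), `viscous_indicator`).
#' @export
estimate_material_from_puncture <- function(data) {
  check_columns(data, c("region", "stage", "h_pre", "h_post"), "data")
  if (any(data$h_pre <= 0)) abort_bad_arg("`h_pre` must be positive.")
  if (length(unique(data$stage)) < 2) {
    abort_bad_arg("Need measurements at >= 2 stages to separate viscous drift.")
  }
  by_stage <- data %>%
    dplyr::group_by(.data$region, .data$stage) %>%
    dplyr::summarise(
      elastic_indicator = mean((.data$h_post - .data$h_pre) / .data$h_pre),
      .groups = "drop"
    )
  by_region <- purrr::map_dfr(split(by_stage, by_stage$region), function(g) {
    slope <- -unname(coef(stats::lm(g$elastic_indicator ~ g$stage))[2])
    e0 <- g$elastic_indicator[which.min(g$stage)]
    tibble::tibble(
      region = g$region[1],
      elastic_indicator = mean(g$elastic_indicator),
      viscous_indicator = if (abs(e0) < 1e-12) 0 else max(0, slope / e0)
    )
  })
  by_region <- dplyr::arrange(by_region, dplyr::desc(.data$elastic_indicator))
  list(by_stage = by_stage, by_region = by_region)
}
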