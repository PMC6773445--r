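#' Transport parameters of the pressure-flux feedback law
#'
#' The flux law is `Omega = Omega0 - K * P`: a pressure-free osmotic influx
#' `Omega0` down-regulated linearly by lumenal pressure with permeability
#' coefficient `K`. The homeostatic pressure `P0` is the fixed point at
#' which influx balances wall creep. Solute bookkeeping follows the
#' isotonic assumption `M = Omega * c`. `kappa` is the phenomenological
#' catch-up gain (excess flux per unit fractional volume deficit) that the
#' feedback produces after a puncture.
#'
#' @param Omega0 Pressure-free influx, um/hr.
#' @param K Permeability coefficient, um/(hr·Pa); must satisfy
#'   `Omega0 > K * P0` so wild-type flux is positive.
#' @param P0 Homeostatic pressure, Pa.
#' @param c Lumenal solute concentration, mM.
#' @param kappa Catch-up gain, um/hr per unit fractional deficit.
#' @return A `transport_params` object; `M` (solute transport rate,
#'   mol/(um^2 hr)) is derived from the isotonic relation.
#' @export
#' @examples
#' transport_params()
transport_params <- function(Omega0 = 2.8, K = 0.013, P0 = 140,
                             c = 150, kappa = 4) {
  check_number(Omega0, "Omega0", lower = 0)
  check_number(K, "K", lower = 0)
  check_number(P0, "P0", lower = 0)
  if (K * P0 > 0 && Omega0 <= K * P0) {
    abort_bad_arg("Need `Omega0 > K * P0`: wild-type flux must be positive.")
  }
  c_mol_um3 <- c * 1e-18 # mM = 1e-3 mol/L = 1e-18 mol/um^3
  structure(
    list(
      Omega0 = Omega0, K = K, P0 = P0,
      c = c_mol_um3, c_mM = c,
      M = Omega0 * c_mol_um3, # mol/(um^2 hr), isotonic
      kappa = kappa
    ),
    class = "transport_params"
  )
}

#' @export
print.transport_params <- function(x, ...) {
  cat("<transport_params>\n")
  cat(sprintf(
    "  Omega0 = %.3g um/hr, K = %.3g um/(hr·Pa), P0 = %.3g Pa, kappa = %.3g\n",
    x$Omega0, x$K, x$P0, x$kappa
  ))
  invisible(x)
}

#' Modify transport/material parameters for a drug treatment
#'
#' Ouabain (Na,K-ATPase inhibition) scales the osmotic influx `Omega0` by
#' `1 - dose_scale`; cytochalasin D softens the wall, scaling `mu` and `k`
#' by `1 - dose_scale` (floored at 0.1 so the Maxwell element stays
#' well-posed), which raises the realized flux through the feedback
#' closure.
#'
#' @param params A [transport_params()].
#' @param material A [wall_material()].
#' @param kind `"ouabain"` or `"cytochalasin"`.
#' @param dose_scale Dose on a 0-1 scale.
#' @return List with modified `params` and `material`.
#' @export
apply_drug <- function(params, material,
                       kind = c("ouabain", "cytochalasin"),
                       dose_scale = 1) {
  kind <- rlang::arg_match(kind)
  check_number(dose_scale, "dose_scale", lower = 0, upper = 1)
  if (kind == "ouabain") {
    params$Omega0 <- params$Omega0 * (1 - dose_scale)
    params$M <- params$Omega0 * params$c
  } else {
    f <- max(0.1, 1 - dose_scale)
    material$mu <- material$mu * f
    material$mu_pa_s <- material$mu_pa_s * f
    material$k <- material$k * f
    # tau = mu / k unchanged
  }
  list(params = params, material = material)
}

default_j_schedule <- function() {
  # tissue volume constant to 28 hpf, then linear gain of 132 pl by 45 hpf
  function(t) ifelse(t < 28, 0, 132 / 17)
}

#' Simulate hydraulic vesicle growth under pressure-flux feedback
#'
#' Forward-integrates the coupled lumen/wall dynamics with a fixed-step
#' explicit scheme: fluid influx `dVl/dt = Sl * (Omega0 - K * P)` expands
#' the lumen; the wall is a Maxwell element whose stress obeys
#' `dsigma/dt = 4 k eps_dot - sigma / tau` with strain rate
#' `eps_dot = (1/R) dR/dt`; lumenal pressure follows the thin-shell Laplace
#' balance `P = 2 h sigma / R`; and tissue mass is conserved,
#' `dVt/dt = j(t)`, with the wall thickness recomputed from the exact
#' sphere-equivalent shell at every step. In steady growth this closure is
#' equivalent to the quasi-static pressure
#' `P* = Omega0 / (K + R^2 / (8 mu h))`.
#'
#' Events: a `puncture` sets pressure to zero, releases the stored elastic
#' strain and removes `loss_fraction` of the lumen volume at conserved
#' tissue volume; the barrier reseals after `reseal_min` minutes and
#' pressure rebuilds through the closure, transiently elevating the flux
#' (catch-up growth). `ouabain` and `cytochalasin` apply [apply_drug()]
#' from their event time onward.
#'
#' @param params A [transport_params()].
#' @param material A [wall_material()].
#' @param j_schedule Function of time returning the tissue growth rate
#'   (pl/hr); defaults to the wild-type schedule (zero before 28 hpf,
#'   linear gain after).
#' @param init Optional list/one-row data frame with initial `Vl`, `Vt`
#'   (pl); defaults to the wild-type state at the start of `t_span`
#'   (114 pl lumen, 246 pl tissue at 30 hpf).
#' @param events Tibble with columns `t`, `kind`
#'   (`"puncture"`/`"ouabain"`/`"cytochalasin"`) and optional list column
#'   `params` (puncture: `loss_fraction`, `reseal_min`; drugs:
#'   `dose_scale`).
#' @param t_span Simulated time span, hpf.
#' @param dt Time step, hr; must satisfy `dt <= tau / 20` (stability
#'   guard for the stiffest relaxation in the run).
#' @return A `vesicle_trajectory` tibble with columns `t`, `R`, `h` (um),
#'   `P` (Pa), `sigma` (Pa), `Omega` (um/hr), `Vl`, `Vt` (pl),
#'   `strain_elastic`, plus attributes `events`, `params`, `material`.
#' @export
#' @examples
#' traj <- simulate_vesicle(t_span = c(30, 36), dt = 0.01)
#' tail(traj, 2)
simulate_vesicle <- function(params = transport_params(),
                             material = wall_material(),
                             j_schedule = default_j_schedule(),
                             init = NULL,
                             events = NULL,
                             t_span = c(30, 48),
                             dt = 0.005) {
  stopifnot(inherits(params, "transport_params"), inherits(material, "wall_material"))
  if (material$mu <= 0) abort_bad_arg("`mu` must be positive.")
  if (is.null(init)) init <- list(Vl = 114, Vt = 246.1)
  check_number(init$Vl, "init$Vl", lower = 0, strict_lower = TRUE)
  check_number(init$Vt, "init$Vt", lower = 0, strict_lower = TRUE)
  if (dt > material$tau / 20) {
    abort_bad_arg(sprintf(
      "Step dt = %g hr too coarse for tau = %.3g hr; need dt <= tau/20.",
      dt, material$tau
    ))
  }
  # the stress/pressure feedback relaxes at rate ~ 8 k K h / R^2 + 1/tau;
  # the explicit scheme needs to resolve it
  g0 <- shell_geom(init$Vl, init$Vt)
  k_max <- material$k * exp(max(0, material$stiffening_rate * (t_span[2] - material$t_ref)))
  lam <- 8 * k_max * params$K * g0$h / g0$R^2 + 1 / material$tau
  if (dt > 1 / lam) {
    abort_bad_arg(sprintf(
      "Step dt = %g hr too coarse for the feedback relaxation rate %.3g/hr.",
      dt, lam
    ))
  }
  if (!is.null(events)) {
    check_columns(events, c("t", "kind"), "events")
    if (!"params" %in% names(events)) events$params <- list(list())
    events <- events[order(events$t), ]
  }

  ts <- seq(t_span[1], t_span[2], by = dt)
  n <- length(ts)
  Vl <- init$Vl
  Vt <- init$Vt
  g <- shell_geom(Vl, Vt)
  # start on the quasi-static branch: stress consistent with the closure
  # (an explicit init$sigma overrides, e.g. to probe stability)
  m0 <- material_at(material, ts[1])
  P_init <- params$Omega0 / (params$K + g$R^2 / (8 * m0$mu * g$h))
  sigma <- init$sigma %||% (P_init * g$R / (2 * g$h))
  open_until <- -Inf
  punctured_open <- FALSE
  ev_idx <- 1

  out <- matrix(NA_real_, n, 9)
  colnames(out) <- c("t", "R", "h", "P", "sigma", "Omega", "Vl", "Vt", "strain_elastic")
  applied <- list()

  for (i in seq_len(n)) {
    t_i <- ts[i]
    # fire events scheduled at or before this step
    while (!is.null(events) && ev_idx <= nrow(events) &&
      events$t[ev_idx] <= t_i + dt / 2) {
      ev <- events[ev_idx, ]
      p <- ev$params[[1]]
      if (ev$kind == "puncture") {
        if (punctured_open) abort_bad_arg("Puncture while the wound is already open.")
        loss <- p$loss_fraction %||% 0.35
        reseal <- (p$reseal_min %||% 5) / 60
        check_number(loss, "loss_fraction", lower = 0, upper = 1)
        # loss_fraction is the total observed volume drop (elastic recoil
        # plus fluid leakage are not separately observable); the stored
        # elastic stress is released with the wound
        Vl <- Vl * (1 - loss)
        sigma <- 0
        open_until <- t_i + reseal
        punctured_open <- TRUE
        g <- shell_geom(Vl, Vt)
      } else {
        mod <- apply_drug(params, material, kind = ev$kind, dose_scale = p$dose_scale %||% 1)
        params <- mod$params
        material <- mod$material
      }
      applied[[length(applied) + 1]] <- list(t = t_i, kind = ev$kind, params = p)
      ev_idx <- ev_idx + 1
    }
    if (punctured_open && t_i >= open_until) punctured_open <- FALSE

    m <- material_at(material, t_i)
    P <- if (punctured_open) 0 else max(0, 2 * g$h * sigma / g$R)
    Omega <- params$Omega0 - params$K * P
    if (punctured_open) Omega <- 0 # no barrier, no net osmotic influx

    out[i, ] <- c(
      t_i, g$R, g$h, P, sigma, Omega, Vl, Vt,
      sigma / (4 * m$k)
    )
    if (i == n) break

    Vl2 <- max(1e-9, Vl + dt * 4 * pi * g$Rl^2 * Omega / UM3_PER_PL)
    Vt2 <- Vt + dt * j_schedule(t_i)
    g2 <- shell_geom(Vl2, Vt2)
    eps_dot <- (g2$R - g$R) / (dt * g$R)
    sigma <- if (punctured_open) 0 else max(0, sigma + dt * (4 * m$k * eps_dot - sigma / m$tau))
    Vl <- Vl2
    Vt <- Vt2
    g <- g2
  }

  traj <- tibble::as_tibble(as.data.frame(out))
  class(traj) <- c("vesicle_trajectory", class(traj))
  attr(traj, "events") <- applied
  attr(traj, "params") <- params
  attr(traj, "material") <- material
  traj
}

shell_geom <- function(Vl, Vt) {
  Rl <- radius_from_volume_pl(Vl)
  Ro <- radius_from_volume_pl(Vl + Vt)
  list(Rl = Rl, Ro = Ro, R = (Ro + Rl) / 2, h = Ro - Rl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit feedback-model parameters to an observed trajectory
#'
#' Bounded least squares of the simulated radius trajectory (and pressure,
#' when observed) against data, over a chosen subset of free parameters.
#' Confidence intervals come from residual-resampling bootstrap. `K` is
#' only identifiable when the data contain pressure or a perturbation;
#' asking for it otherwise is an error rather than a silent fit.
#'
#' @param observed A `vesicle_trajectory` or data frame with columns `t`,
#'   `R` (um) and optionally `P` (Pa), spanning at least 10 time points.
#' @param free Character subset of `c("Omega0", "K", "mu")`.
#' @param params,material Starting values; see [transport_params()],
#'   [wall_material()].
#' @param bounds Named list of `c(lower, upper)` per free parameter.
#' @param events,j_schedule,dt Passed to [simulate_vesicle()].
#' @param n_boot Bootstrap replicates (0 to skip CIs).
#' @param seed Integer seed for the bootstrap.
#' @return A `vesicle_fit` with `estimates`, `ci`, `residual_sd`; see
#'   [tidy()]/[glance()].
#' @export
fit_vesicle_parameters <- function(observed,
                                   free = "Omega0",
                                   params = transport_params(),
                                   material = wall_material(),
                                   bounds = NULL,
                                   events = NULL,
                                   j_schedule = default_j_schedule(),
                                   dt = 0.02,
                                   n_boot = 0,
                                   seed = 1L) {
  check_columns(observed, c("t", "R"), "observed")
  if (nrow(observed) < 10) {
    abort_bad_arg("Need at least 10 observed time points.")
  }
  free <- match.arg(free, c("Omega0", "K", "mu"), several.ok = TRUE)
  has_P <- "P" %in% names(observed) && any(!is.na(observed$P))
  has_perturbation <- !is.null(events) && nrow(events) > 0
  if ("K" %in% free && !has_P && !has_perturbation) {
    abort_bad_arg(paste0(
      "`K` is not identifiable from an unperturbed radius trajectory ",
      "without pressure data; supply `P` or a perturbation."
    ))
  }
  default_bounds <- list(
    Omega0 = c(0.1, 20), K = c(1e-4, 1), mu = c(1e5, 1e9)
  )
  bounds <- utils::modifyList(default_bounds, bounds %||% list())
  t_span <- range(observed$t)

  make_args <- function(theta) {
    p <- params
    m <- material
    if ("Omega0" %in% names(theta)) {
      p$Omega0 <- theta[["Omega0"]]
      p$M <- p$Omega0 * p$c
    }
    if ("K" %in% names(theta)) p$K <- theta[["K"]]
    if ("mu" %in% names(theta)) {
      scale <- theta[["mu"]] / m$mu_pa_s
      m$mu <- m$mu * scale
      m$mu_pa_s <- theta[["mu"]]
      m$tau <- m$mu / m$k
    }
    list(params = p, material = m)
  }
  objective <- function(theta_vec, target_R, target_P = NULL) {
    theta <- stats::setNames(theta_vec, free)
    a <- make_args(theta)
    sim <- try(
      simulate_vesicle(a$params, a$material,
        j_schedule = j_schedule,
        events = events, t_span = t_span, dt = dt
      ),
      silent = TRUE
    )
    if (inherits(sim, "try-error")) {
      return(1e10)
    }
    sim_R <- stats::approx(sim$t, sim$R, xout = observed$t)$y
    ss <- sum((sim_R - target_R)^2)
    if (!is.null(target_P)) {
      sim_P <- stats::approx(sim$t, sim$P, xout = observed$t)$y
      ok <- !is.na(target_P)
      # pressure in Pa and radius in um have comparable scales here; weight
      # pressure down so radius dominates unless P is the only signal
      ss <- ss + 0.01 * sum((sim_P[ok] - target_P[ok])^2)
    }
    ss
  }

  start <- vapply(free, function(nm) {
    switch(nm,
      Omega0 = params$Omega0,
      K = params$K,
      mu = material$mu_pa_s
    )
  }, numeric(1))
  lower <- vapply(free, function(nm) bounds[[nm]][1], numeric(1))
  upper <- vapply(free, function(nm) bounds[[nm]][2], numeric(1))
  target_P <- if (has_P) observed$P else NULL

  fit_once <- function(target_R) {
    if (length(free) == 1) {
      opt <- stats::optimize(
        function(x) objective(x, target_R, target_P),
        interval = c(lower, upper), tol = 1e-4 * (upper - lower)
      )
      stats::setNames(opt$minimum, free)
    } else {
      opt <- stats::optim(start, objective,
        target_R = target_R, target_P = target_P,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(factr = 1e10)
      )
      stats::setNames(opt$par, free)
    }
  }
  est <- fit_once(observed$R)
  a <- make_args(est)
  sim <- simulate_vesicle(a$params, a$material,
    j_schedule = j_schedule,
    events = events, t_span = t_span, dt = dt
  )
  fitted_R <- stats::approx(sim$t, sim$R, xout = observed$t)$y
  resid <- observed$R - fitted_R

  ci <- NULL
  if (n_boot > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
    on.exit(restore_seed(old_seed), add = TRUE)
    set.seed(as.integer(seed))
    boot <- replicate(n_boot, {
      y <- fitted_R + sample(resid, length(resid), replace = TRUE)
      fit_once(y)
    })
    boot <- matrix(boot, nrow = length(free))
    ci <- t(apply(boot, 1, stats::quantile, probs = c(0.025, 0.975)))
    rownames(ci) <- free
  }

  structure(
    list(
      estimates = est,
      ci = ci,
      residual_sd = stats::sd(resid),
      fitted = tibble::tibble(t = observed$t, R = observed$R, R_fit = fitted_R),
      free = free,
      n_boot = n_boot
    ),
    class = "vesicle_fit"
  )
}

#' @export
print.vesicle_fit <- function(x, ...) {
  cat("<vesicle_fit>\n")
  for (nm in x$free) {
    line <- sprintf("  %s = %.4g", nm, x$estimates[[nm]])
    if (!is.null(x$ci)) {
      line <- paste0(line, sprintf(" [%.4g, %.4g]", x$ci[nm, 1], x$ci[nm, 2]))
    }
    cat(line, "\n")
  }
  cat(sprintf("  residual sd = %.3g um over %d points\n", x$residual_sd, nrow(x$fitted)))
  invisible(x)
}

#' @export
tidy.vesicle_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = x$free,
    estimate = unname(x$estimates[x$free])
  )
  if (!is.null(x$ci)) {
    out$conf.low <- x$ci[x$free, 1]
    out$conf.high <- x$ci[x$free, 2]
  }
  out
}

#' @export
glance.vesicle_fit <- function(x, ...) {
  tibble::tibble(
    residual_sd = x$residual_sd,
    nobs = nrow(x$fitted),
    n_boot = x$n_boot
  )
}
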