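# Quantities drawn independently with noise; Vo, psi are then derived so the
# accounting identities Vo = Vl + Vt and Sl = psi * N hold exactly per embryo.
NOISY_QUANTITIES <- c(
  "N", "s", "Vt", "Vl", "Sl",
  "h_medial", "h_lateral", "h_poles", "P"
)

#' Generate a wild-type growth-curve cohort
#'
#' Draws per-embryo morphometric time series around smooth deterministic
#' backbone curves (monotone cubic interpolants through the calibration
#' anchors). Noise is additive Gaussian with the anchored, time-interpolated
#' standard deviation; half of the noise variance is a per-embryo random
#' effect shared across time points, mimicking embryo-to-embryo correlation,
#' and half is independent sampling noise. The derived quantities respect
#' the accounting identities exactly: `Vo = Vl + Vt` and `psi = Sl / N`.
#' Pressure `P` is reported only from 30 hpf (too low to probe earlier).
#'
#' @param spec A [generator_spec()].
#' @return A `morpho_cohort` tibble with columns `embryo_id`, `t` (hpf),
#'   `N`, `s` (pl), `Vt`, `Vl`, `Vo` (pl), `Sl` (um^2), `psi` (um^2),
#'   `h_medial`, `h_lateral`, `h_poles` (um) and `P` (Pa, `NA` before
#'   30 hpf).
#' @export
#' @examples
#' cohort <- generate_wildtype_cohort(generator_spec(n_embryos = 3))
#' dplyr::count(cohort, embryo_id)
generate_wildtype_cohort <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  tq <- seq(spec$t_start, spec$t_end, by = spec$sampling_interval)
  withr_seed <- spec$seed
  old_seed <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(withr_seed)

  backbones <- lapply(
    stats::setNames(NOISY_QUANTITIES, NOISY_QUANTITIES),
    function(q) backbone_for(spec, q)
  )
  out <- purrr::map_dfr(seq_len(spec$n_embryos), function(e) {
    draw_embryo_series(backbones, tq, spec$noise_sd_scale,
      embryo_id = sprintf("wt_%02d", e)
    )
  })
  new_morpho_cohort(out)
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

draw_embryo_series <- function(backbones, tq, noise_scale, embryo_id,
                               z_embryo = NULL) {
  if (is.null(z_embryo)) {
    z_embryo <- stats::rnorm(length(backbones))
    names(z_embryo) <- names(backbones)
  }
  vals <- purrr::imap(backbones, function(b, nm) {
    mu <- b$fn(tq)
    sdv <- b$sd(tq) * noise_scale
    z_t <- stats::rnorm(length(tq))
    v <- mu + sdv * (sqrt(0.5) * z_embryo[[nm]] + sqrt(0.5) * z_t)
    pmax(v, 0)
  })
  p <- vals$P
  p[tq < 30] <- NA_real_
  tibble::tibble(
    embryo_id = embryo_id,
    t = tq,
    N = vals$N,
    s = vals$s,
    Vt = vals$Vt,
    Vl = vals$Vl,
    Vo = vals$Vl + vals$Vt,
    Sl = vals$Sl,
    psi = vals$Sl / vals$N,
    h_medial = vals$h_medial,
    h_lateral = vals$h_lateral,
    h_poles = vals$h_poles,
    P = p
  )
}

new_morpho_cohort <- function(x) {
  class(x) <- c("morpho_cohort", class(x))
  x
}

#' Generate a paired puncture/regeneration experiment
#'
#' Produces left/right morphometric series for one embryo in which the right
#' (punctured) side loses `loss_fraction` of its lumen volume at
#' `t_puncture`, thickens its wall at conserved tissue volume, reseals
#' within `reseal_delay_min` minutes, and then regenerates with an excess
#' flux proportional to the fractional volume deficit,
#' `Omega_tilde - Omega = kappa * (Vl_control - Vl_punctured) / Vl_control`,
#' so that bilateral symmetry is restored at late times. Regional wall
#' thickening at the puncture instant is strongest medially and laterally
#' and weak at the poles, reflecting the softer thin regions.
#'
#' @param spec A [generator_spec()].
#' @param t_puncture Puncture time, hpf (must be inside the sampling span).
#' @param loss_fraction Fraction of lumen volume lost at puncture, in (0, 1).
#' @param kappa Catch-up gain, um/hr of excess flux per unit fractional
#'   volume deficit.
#' @param reseal_delay_min Time for the epithelial barrier to reseal, min.
#' @param seed Integer seed (defaults to the spec seed).
#' @return A `paired_experiment` tibble with a `side` column
#'   (`"control"`/`"punctured"`) and the same measurement columns as a
#'   [generate_wildtype_cohort()] cohort, carrying an `events` attribute.
#' @export
#' @examples
#' pair <- generate_puncture_experiment(generator_spec(), t_puncture = 30)
#' attr(pair, "events")
generate_puncture_experiment <- function(spec = generator_spec(),
                                         t_puncture = 30,
                                         loss_fraction = 0.35,
                                         kappa = 4,
                                         reseal_delay_min = 5,
                                         seed = spec$seed) {
  stopifnot(inherits(spec, "generator_spec"))
  check_number(loss_fraction, "loss_fraction", lower = 0, upper = 1, strict_lower = FALSE)
  if (loss_fraction >= 1) abort_bad_arg("`loss_fraction` must be < 1.")
  check_number(kappa, "kappa", lower = 0)
  if (t_puncture < spec$t_start || t_puncture > spec$t_end) {
    abort_bad_arg("`t_puncture` must lie within the sampling span.")
  }

  tq <- seq(spec$t_start, spec$t_end, by = spec$sampling_interval)
  old_seed <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(as.integer(seed))

  backbones <- lapply(
    stats::setNames(NOISY_QUANTITIES, NOISY_QUANTITIES),
    function(q) backbone_for(spec, q)
  )
  # the two sides share the embryo, hence the embryo-level random effect;
  # only the sampling noise is independent between ears
  z_embryo <- stats::rnorm(length(backbones))
  names(z_embryo) <- names(backbones)
  left <- draw_embryo_series(backbones, tq, spec$noise_sd_scale, "left", z_embryo)
  right <- draw_embryo_series(backbones, tq, spec$noise_sd_scale, "right", z_embryo)

  # Deterministic recovery of the punctured lumen on a fine grid, driven by
  # the control backbone flux plus the linear catch-up law.
  bb_Vl <- backbones$Vl$fn
  bb_Sl <- backbones$Sl$fn
  dt <- 0.05
  tf <- seq(t_puncture, spec$t_end, by = dt)
  vl_p <- numeric(length(tf))
  vl_p[1] <- bb_Vl(t_puncture) * (1 - loss_fraction)
  reseal_t <- t_puncture + reseal_delay_min / 60
  for (i in seq_len(length(tf) - 1)) {
    t_i <- tf[i]
    vl0 <- bb_Vl(t_i)
    omega0 <- bb_Vl(t_i, deriv = 1) * UM3_PER_PL / bb_Sl(t_i)
    deficit <- max(0, (vl0 - vl_p[i]) / vl0)
    omega <- if (t_i < reseal_t) 0 else omega0 + kappa * deficit
    # punctured-side area scales with its own (sphere-equivalent) lumen
    sl_p <- bb_Sl(t_i) * (vl_p[i] / vl0)^(2 / 3)
    vl_p[i + 1] <- vl_p[i] + dt * omega * sl_p / UM3_PER_PL
  }
  vl_ratio <- stats::approx(tf, vl_p / bb_Vl(tf), xout = tq, rule = 2)$y
  post <- tq >= t_puncture

  right$Vl[post] <- right$Vl[post] * vl_ratio[post]
  # Wall thickens at conserved Vt: thickness ~ Vt / Sl, and the punctured
  # side's surface shrinks with its lumen.  Poles are stiffer and respond
  # only weakly.
  thick_factor <- vl_ratio[post]^(-2 / 3)
  response <- c(h_medial = 1, h_lateral = 1, h_poles = 0.25)
  for (col in names(response)) {
    f <- 1 + response[[col]] * (thick_factor - 1)
    right[[col]][post] <- right[[col]][post] * f
  }
  right$Sl[post] <- right$Sl[post] * vl_ratio[post]^(2 / 3)
  right$Vo <- right$Vl + right$Vt
  right$psi <- right$Sl / right$N
  # open wound: no pressure while unsealed (sub-sample resolution; only
  # matters if a sample falls inside the reseal window)
  right$P[post & tq < reseal_t] <- 0

  left$embryo_id <- "pair_01"
  right$embryo_id <- "pair_01"
  left$side <- "control"
  right$side <- "punctured"
  out <- dplyr::bind_rows(left, right)
  out <- out[, c("embryo_id", "side", setdiff(names(out), c("embryo_id", "side")))]
  events <- tibble::tibble(
    t = c(t_puncture, reseal_t),
    kind = c("puncture", "reseal"),
    params = list(
      list(loss_fraction = loss_fraction, kappa = kappa),
      list()
    )
  )
  structure(
    new_morpho_cohort(out),
    events = events,
    class = c("paired_experiment", class(new_morpho_cohort(out)))
  )
}

#' Generate a drug/morpholino perturbation cohort
#'
#' Emulates the phenomenology of transport and cytoskeletal perturbations:
#' ouabain (Na,K-ATPase inhibition) and the atp1a1a morpholino scale the
#' fluid influx toward zero with dose, arresting lumen growth entirely at
#' full dose; cytochalasin D softens the wall so that the realized flux
#' rises two- to five-fold above wild type.
#'
#' @param spec A [generator_spec()].
#' @param kind One of `"ouabain"`, `"cytochalasin"`, `"morpholino"`.
#' @param dose_scale Dose on a 0-1 scale (0 = untreated).
#' @param t_treat Treatment time, hpf.
#' @return A `morpho_cohort` tibble (see [generate_wildtype_cohort()]) with
#'   a `treatment` attribute.
#' @export
#' @examples
#' arrested <- generate_perturbation_cohort(generator_spec(n_embryos = 3),
#'   kind = "ouabain", dose_scale = 1
#' )
generate_perturbation_cohort <- function(spec = generator_spec(),
                                         kind = c("ouabain", "cytochalasin", "morpholino"),
                                         dose_scale = 1,
                                         t_treat = 25) {
  kind <- rlang::arg_match(kind)
  check_number(dose_scale, "dose_scale", lower = 0, upper = 1)
  cohort <- generate_wildtype_cohort(spec)
  if (dose_scale == 0) {
    attr(cohort, "treatment") <- list(kind = kind, dose_scale = 0, t_treat = t_treat)
    return(cohort)
  }
  flux_factor <- switch(kind,
    ouabain = ,
    morpholino = 1 - dose_scale,
    cytochalasin = 1 + 3 * dose_scale
  )
  # deterministic perturbed lumen backbone: the realized flux (per unit of
  # the perturbed vesicle's own surface) is `flux_factor` times wild type,
  # dVl/dt = factor * Omega_wt(t) * Sl_wt(t) * (Vl/Vl_wt)^(2/3)
  bb_Vl <- backbone_for(spec, "Vl")$fn
  bb_Sl <- backbone_for(spec, "Sl")$fn
  dt <- 0.05
  tf <- seq(t_treat, spec$t_end, by = dt)
  vl_pert <- numeric(length(tf))
  vl_pert[1] <- bb_Vl(t_treat)
  for (i in seq_len(length(tf) - 1)) {
    t_i <- tf[i]
    omega_wt <- bb_Vl(t_i, deriv = 1) * UM3_PER_PL / bb_Sl(t_i)
    sl_pert <- bb_Sl(t_i) * (vl_pert[i] / bb_Vl(t_i))^(2 / 3)
    vl_pert[i + 1] <- vl_pert[i] + dt * flux_factor * omega_wt * sl_pert / UM3_PER_PL
  }
  tq <- sort(unique(cohort$t))
  ratio <- stats::approx(tf, vl_pert / bb_Vl(tf), xout = tq, rule = 2)$y
  ratio[tq < t_treat] <- 1
  r_of_t <- stats::setNames(ratio, tq)
  cohort <- cohort %>%
    dplyr::mutate(
      Vl = .data$Vl * r_of_t[as.character(.data$t)],
      Sl = .data$Sl * r_of_t[as.character(.data$t)]^(2 / 3),
      Vo = .data$Vl + .data$Vt,
      psi = .data$Sl / .data$N
    )
  cohort <- new_morpho_cohort(tibble::as_tibble(cohort))
  attr(cohort, "treatment") <- list(kind = kind, dose_scale = dose_scale, t_treat = t_treat)
  cohort
}

#' Generate a synthetic pressure-probe trace
#'
#' Builds a piecewise trace mimicking a probe insertion: flat baseline,
#' smooth saturating rise over `rise_time_s` seconds, stable plateau and an
#' abrupt withdrawal back to baseline, with additive Gaussian sensor noise.
#' Ground-truth stage labels are included so segmentation can be tested.
#'
#' @param P_baseline Baseline (bath) pressure, Pa.
#' @param P_plateau Plateau pressure, Pa (must be `>= P_baseline`).
#' @param rise_time_s Duration of the rise stage, s (default 30 s, the
#'   typical probe rise time of ~0.5 min).
#' @param noise_sd Sensor noise SD, Pa.
#' @param seed Integer seed.
#' @param baseline_s,plateau_s,tail_s Stage durations, s.
#' @param rate_hz Sampling rate, Hz.
#' @return A `pressure_trace` tibble with columns `t_s`, `P_pa`, `stage`
#'   (one of baseline/rise/plateau/withdrawal).
#' @export
#' @examples
#' trace <- generate_pressure_trace(P_plateau = 166, seed = 7)
#' extract_plateau_pressure(trace)$P_vesicle
generate_pressure_trace <- function(P_baseline = 0,
                                    P_plateau = 166,
                                    rise_time_s = 30,
                                    noise_sd = 2,
                                    seed = 1L,
                                    baseline_s = 30,
                                    plateau_s = 90,
                                    tail_s = 30,
                                    rate_hz = 10) {
  check_number(P_baseline, "P_baseline", lower = 0)
  if (P_plateau < P_baseline) {
    abort_bad_arg("`P_plateau` must be >= `P_baseline`.")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(rise_time_s, "rise_time_s", lower = 0, strict_lower = TRUE)

  old_seed <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(as.integer(seed))

  dt <- 1 / rate_hz
  t_rise_end <- baseline_s + rise_time_s
  t_plateau_end <- t_rise_end + plateau_s
  t_end <- t_plateau_end + tail_s
  t_s <- seq(0, t_end, by = dt)
  dP <- P_plateau - P_baseline
  p <- numeric(length(t_s))
  stage <- character(length(t_s))
  in_base <- t_s < baseline_s
  in_rise <- t_s >= baseline_s & t_s < t_rise_end
  in_plat <- t_s >= t_rise_end & t_s < t_plateau_end
  in_with <- t_s >= t_plateau_end
  p[in_base] <- P_baseline
  # smoothstep rise: continuous value and derivative at both ends
  u <- (t_s[in_rise] - baseline_s) / rise_time_s
  p[in_rise] <- P_baseline + dP * (3 * u^2 - 2 * u^3)
  p[in_plat] <- P_plateau
  p[in_with] <- P_baseline
  stage[in_base] <- "baseline"
  stage[in_rise] <- "rise"
  stage[in_plat] <- "plateau"
  stage[in_with] <- "withdrawal"
  if (dP == 0) {
    stage[!in_base] <- "baseline"
    stage[in_with] <- "withdrawal"
  }
  out <- tibble::tibble(
    t_s = t_s,
    P_pa = p + stats::rnorm(length(t_s), sd = noise_sd),
    stage = stage
  )
  class(out) <- c("pressure_trace", class(out))
  out
}

#' Generate a regional puncture material-property assay
#'
#' Emulates the staged puncture experiments used to rank regional wall
#' material properties: paired pre/post-puncture wall thickness per region
#' at several developmental stages. Medial and lateral walls are soft
#' (large elastic thickening at puncture, fast drift of the resting
#' thickness across stages); the poles are stiff.
#'
#' @param stages Puncture stages, hpf.
#' @param n_per_stage Embryos per stage.
#' @param noise_sd_scale Noise multiplier (0 = deterministic).
#' @param seed Integer seed.
#' @return Tibble with columns `region`, `stage`, `embryo`, `h_pre`,
#'   `h_post` (um).
#' @export
generate_material_assay <- function(stages = c(25, 30, 35, 40),
                                    n_per_stage = 5,
                                    noise_sd_scale = 1,
                                    seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  spec <- generator_spec(noise_sd_scale = 0)
  # elastic thickening fraction at puncture (prop. to 1/k) and per-stage
  # decay of the resting state (prop. to 1/mu)
  elastic <- c(medial = 0.40, lateral = 0.36, poles = 0.08)
  drift <- c(medial = 0.045, lateral = 0.040, poles = 0.008)
  grid <- tidyr::expand_grid(
    region = names(elastic),
    stage = stages,
    embryo = seq_len(n_per_stage)
  )
  h_bb <- list(
    medial = backbone_for(spec, "h_medial")$fn,
    lateral = backbone_for(spec, "h_lateral")$fn,
    poles = backbone_for(spec, "h_poles")$fn
  )
  grid %>%
    dplyr::mutate(
      h_pre = purrr::map2_dbl(.data$region, .data$stage, ~ h_bb[[.x]](.y)) *
        (1 + 0.02 * noise_sd_scale * stats::rnorm(dplyr::n())),
      h_post = .data$h_pre *
        (1 + elastic[.data$region] * exp(-drift[.data$region] * (.data$stage - stages[1]))) *
        (1 + 0.02 * noise_sd_scale * stats::rnorm(dplyr::n()))
    )
}
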