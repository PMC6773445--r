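test_that("no transport means no growth", {
  p <- transport_params(Omega0 = 0, K = 0, P0 = 0)
  traj <- simulate_vesicle(p, t_span = c(30, 36), dt = 0.01, j_schedule = function(t) 0)
  expect_equal(max(traj$R) - min(traj$R), 0, tolerance = 1e-9)
  expect_equal(max(abs(traj$Omega)), 0)
})

test_that("a rigid wall arrests growth at the pressure ceiling", {
  p <- transport_params(Omega0 = 2.8, K = 0.013, P0 = 140)
  stiff <- wall_material(mu = 1e13, k = 200, stiffening_rate = 0)
  traj <- simulate_vesicle(p, stiff,
    t_span = c(30, 40), dt = 0.005,
    j_schedule = function(t) 0
  )
  # P* -> Omega0 / K and Omega -> 0
  expect_equal(tail(traj$P, 1), p$Omega0 / p$K, tolerance = 0.02)
  expect_lt(tail(traj$Omega, 1), 0.05 * p$Omega0)
  expect_lt(tail(traj$R, 1) - traj$R[1], 1)
})

test_that("default wild-type run keeps flux near 1 um/hr at physiological pressure", {
  traj <- control_trajectory()
  expect_true(all(traj$Omega > 0.5 & traj$Omega < 1.3))
  expect_true(all(traj$P > 100 & traj$P < 250))
  expect_true(all(diff(traj$R) > 0))
})

test_that("tissue mass is conserved along every trajectory", {
  for (traj in list(control_trajectory(), punctured_trajectory())) {
    # Vt column integrates the supplied growth schedule
    expected_vt <- 246.1 + pmax(0, traj$t - 30) * 132 / 17
    expect_equal(traj$Vt, expected_vt, tolerance = 1e-6)
    # thin-shell mass bookkeeping: 4 pi R^2 h tracks Vt within 1%
    shell <- 4 * pi * traj$R^2 * traj$h / 1e3
    expect_equal(shell, traj$Vt, tolerance = 0.01)
  }
})

test_that("puncture drops the lumen, thickens the wall and conserves tissue", {
  ctrl <- control_trajectory()
  pun <- punctured_trajectory()
  i_pre <- max(which(pun$t < 32))
  i_post <- i_pre + 1
  expect_equal(pun$Vt[i_post], pun$Vt[i_pre], tolerance = 0.01)
  expect_lt(pun$R[i_post], pun$R[i_pre])
  expect_gt(pun$h[i_post], pun$h[i_pre])
  expect_equal(pun$P[i_post], 0)
  expect_equal(
    pun$Vl[i_post] / pun$Vl[i_pre], 0.65,
    tolerance = 0.01
  )
})

test_that("catch-up growth restores symmetry with elevated post-reseal flux", {
  ctrl <- control_trajectory()
  pun <- punctured_trajectory()
  post <- pun$t > 32 + 5 / 60
  ratio <- max(pun$Omega[post] / ctrl$Omega[post])
  expect_gte(ratio, 2)
  expect_lte(ratio, 5)
  deficit <- (ctrl$Vl - pun$Vl) / ctrl$Vl
  expect_lt(abs(tail(deficit, 1)), 0.05)
  # once resealed, the deficit shrinks through the recovery phase
  active <- post & deficit > 0.02
  expect_true(all(diff(deficit[active]) < 0))
})

test_that("the mechanistic catch-up slope matches the feedback gain", {
  ctrl <- control_trajectory()
  pun <- punctured_trajectory()
  post <- pun$t > 32 + 5 / 60
  deficit <- (ctrl$Vl - pun$Vl) / ctrl$Vl
  active <- post & deficit > 0.02
  slope <- unname(coef(lm(
    (pun$Omega - ctrl$Omega)[active] ~ deficit[active]
  ))[2])
  kappa <- transport_params()$kappa
  expect_equal(slope, kappa, tolerance = 0.25)
})

test_that("a puncture cannot be applied while the wound is open", {
  ev <- tibble::tibble(
    t = c(32, 32.02), kind = c("puncture", "puncture"),
    params = list(list(loss_fraction = 0.2), list(loss_fraction = 0.2))
  )
  expect_error(
    simulate_vesicle(events = ev, t_span = c(30, 33), dt = 0.005),
    "already open"
  )
})

test_that("ouabain arrests growth and prevents regeneration", {
  ev <- tibble::tibble(
    t = c(31, 32), kind = c("ouabain", "puncture"),
    params = list(list(dose_scale = 1), list(loss_fraction = 0.35))
  )
  traj <- simulate_vesicle(events = ev, t_span = c(30, 40), dt = 0.005)
  i_treat <- min(which(traj$t >= 31))
  # no further lumen growth (tissue keeps growing on its own schedule)
  expect_true(all(diff(traj$Vl[traj$t >= 31]) <= 1e-9))
  expect_lt(tail(traj$Vl, 1), 0.75 * traj$Vl[i_treat]) # never regenerates
})

test_that("cytochalasin softening raises the flux 2-5 fold", {
  ctrl <- control_trajectory()
  ev <- tibble::tibble(
    t = 34, kind = "cytochalasin",
    params = list(list(dose_scale = 0.8))
  )
  traj <- simulate_vesicle(events = ev)
  post <- traj$t > 34
  ratio <- max(traj$Omega[post] / ctrl$Omega[ctrl$t > 34])
  expect_gte(ratio, 2)
  expect_lte(ratio, 5)
})

test_that("a zero-dose drug event leaves the trajectory unchanged", {
  ctrl <- simulate_vesicle(t_span = c(30, 36), dt = 0.01)
  ev <- tibble::tibble(t = 33, kind = "ouabain", params = list(list(dose_scale = 0)))
  same <- simulate_vesicle(events = ev, t_span = c(30, 36), dt = 0.01)
  expect_equal(as.data.frame(same), as.data.frame(ctrl),
    tolerance = 1e-12, ignore_attr = TRUE
  )
  expect_error(
    apply_drug(transport_params(), wall_material(), kind = "aspirin"),
    "must be one of"
  )
})

test_that("the integrator is converged and guards its step size", {
  a <- simulate_vesicle(t_span = c(30, 40), dt = 0.01)
  b <- simulate_vesicle(t_span = c(30, 40), dt = 0.005)
  expect_equal(tail(a$R, 1), tail(b$R, 1), tolerance = 1e-3)
  expect_error(
    simulate_vesicle(dt = 2, material = wall_material(mu = 3.6e5, k = 100)),
    "too coarse"
  )
})

test_that("a pressure perturbation relaxes back to the quasi-static branch", {
  # negative-feedback stability: start the wall stress (hence P) off the
  # quasi-static branch; P must return to the branch of the trajectory's
  # own geometry, monotonically, from both sides
  params <- transport_params()
  material <- wall_material()
  ctrl <- simulate_vesicle(params, material, t_span = c(30, 38), dt = 0.005)
  sigma0 <- ctrl$sigma[1]
  quasi_static_P <- function(traj) {
    mu_t <- material$mu * exp(material$stiffening_rate * (traj$t - material$t_ref))
    params$Omega0 / (params$K + traj$R^2 / (8 * mu_t * traj$h))
  }
  # the stiffening wall makes even the control lag its (drifting) branch a
  # little; the perturbation is judged relative to that common lag
  ctrl_gap <- ctrl$P - quasi_static_P(ctrl)
  for (f in c(1.3, 0.7)) {
    pert <- simulate_vesicle(params, material,
      init = list(Vl = 114, Vt = 246.1, sigma = f * sigma0),
      t_span = c(30, 38), dt = 0.005
    )
    gap <- (pert$P - quasi_static_P(pert)) - ctrl_gap
    expect_equal(sign(gap[1]), sign(f - 1))
    expect_true(all(sign(gap) == sign(gap[1])))
    expect_true(all(diff(abs(gap)) < 0))
    expect_lt(abs(tail(gap, 1)), 0.2 * abs(gap[1]))
  }
})

test_that("self-fit recovers parameters exactly and flags non-identifiable asks", {
  obs <- simulate_vesicle(t_span = c(30, 45), dt = 0.02)
  obs_sub <- obs[seq(1, nrow(obs), length.out = 31), c("t", "R")]
  fit <- fit_vesicle_parameters(obs_sub, free = "Omega0", dt = 0.02)
  expect_equal(fit$estimates[["Omega0"]], 2.8, tolerance = 1e-3)
  expect_lt(fit$residual_sd, 1e-3)
  expect_error(
    fit_vesicle_parameters(obs_sub, free = c("Omega0", "K"), dt = 0.02),
    "not identifiable"
  )
  expect_error(
    fit_vesicle_parameters(obs_sub[1:5, ], free = "Omega0"),
    "at least 10"
  )
})

test_that("noisy radius data recover the influx parameter within 10%", {
  p0 <- transport_params(Omega0 = 1.5, P0 = 100)
  m0 <- wall_material(mu = 6e6)
  base <- simulate_vesicle(p0, m0, t_span = c(30, 45), dt = 0.02)
  obs <- base[seq(1, nrow(base), length.out = 31), c("t", "R")]
  set.seed(1)
  errs <- replicate(25, {
    noisy <- obs
    noisy$R <- noisy$R * (1 + 0.02 * rnorm(nrow(noisy)))
    fit <- fit_vesicle_parameters(noisy,
      free = "Omega0",
      params = p0, material = m0, dt = 0.05
    )
    (fit$estimates[["Omega0"]] - 1.5) / 1.5
  })
  expect_lt(median(abs(errs)), 0.1)
})

test_that("bootstrap intervals cover the point estimate", {
  p0 <- transport_params(Omega0 = 1.5, P0 = 100)
  m0 <- wall_material(mu = 6e6)
  base <- simulate_vesicle(p0, m0, t_span = c(30, 45), dt = 0.05)
  obs <- base[seq(1, nrow(base), length.out = 16), c("t", "R")]
  set.seed(2)
  obs$R <- obs$R * (1 + 0.01 * rnorm(nrow(obs)))
  fit <- fit_vesicle_parameters(obs,
    free = "Omega0", params = p0,
    material = m0, dt = 0.05, n_boot = 20, seed = 3
  )
  expect_lte(fit$ci["Omega0", 1], fit$estimates[["Omega0"]])
  expect_gte(fit$ci["Omega0", 2], fit$estimates[["Omega0"]])
  td <- tidy(fit)
  expect_true(all(c("conf.low", "conf.high") %in% names(td)))
})

test_that("simulator and regression agree on the catch-up gain", {
  # cross-method: the regression estimate from generator pairs and the
  # mechanistic slope from the simulator describe the same feedback
  ctrl <- control_trajectory()
  pun <- punctured_trajectory()
  post <- pun$t > 32 + 5 / 60
  deficit <- (ctrl$Vl - pun$Vl) / ctrl$Vl
  active <- post & deficit > 0.02
  slope_sim <- unname(coef(lm(
    (pun$Omega - ctrl$Omega)[active] ~ deficit[active]
  ))[2])
  fit <- flux_deficit_regression(puncture_pairs())
  se <- tidy(fit)$std.error[2]
  expect_lt(abs(slope_sim - fit$kappa_hat), 1 + 3 * se)
})
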