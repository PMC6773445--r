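test_that("identical specs generate identical cohorts", {
  a <- generate_wildtype_cohort(generator_spec(seed = 7L))
  b <- generate_wildtype_cohort(generator_spec(seed = 7L))
  expect_identical(a, b)
  c <- generate_wildtype_cohort(generator_spec(seed = 8L))
  expect_false(identical(a$Vl, c$Vl))
})

test_that("zero noise yields identical embryos on the backbone curves", {
  co <- generate_wildtype_cohort(generator_spec(noise_sd_scale = 0, n_embryos = 3))
  wide <- split(co[setdiff(names(co), "embryo_id")], co$embryo_id)
  expect_identical(wide[[1]], wide[[2]])
  expect_identical(wide[[2]], wide[[3]])
})

test_that("accounting identities hold exactly per embryo", {
  co <- default_cohort()
  expect_equal(co$Vo, co$Vl + co$Vt, tolerance = 1e-12)
  expect_equal(co$Sl, co$psi * co$N, tolerance = 1e-12)
  expect_true(all(co[c("N", "s", "Vt", "Vl", "Vo", "Sl")] >= 0))
  expect_true(all(is.na(co$P[co$t < 30])))
  expect_true(all(!is.na(co$P[co$t >= 30])))
})

test_that("cohort means are calibrated to the anchor values", {
  # grand mean over 20 seeds: SE shrinks by sqrt(20), so miscalibration of
  # the endpoint anchors would show up clearly
  anchors <- default_growth_anchors()
  at <- function(q, tt) anchors[anchors$quantity == q & anchors$t == tt, ]
  means <- sapply(1:20, function(s) {
    co <- generate_wildtype_cohort(generator_spec(seed = s))
    last <- co[co$t == 45, ]
    c(N = mean(last$N), Vl = mean(last$Vl), Vo = mean(last$Vo))
  })
  gm <- rowMeans(means)
  se <- function(q) at(q, 45)$sd / sqrt(10 * 20)
  expect_lt(abs(gm[["N"]] - 1106), 3 * se("N"))
  expect_lt(abs(gm[["Vl"]] - 440), 3 * se("Vl"))
  # Vo is derived as Vl + Vt; its backbone end point is 802.6 pl, within
  # the printed spread of 807 +/- 23
  expect_lt(abs(gm[["Vo"]] - 807), 23)
})

test_that("invalid generator specs are rejected", {
  bad_t <- default_growth_anchors()
  bad_t$t[1] <- 10
  expect_error(generator_spec(anchors = bad_t), "12-48")
  bad_sd <- default_growth_anchors()
  bad_sd$sd[3] <- -1
  expect_error(generator_spec(anchors = bad_sd), "non-negative")
  bad_n <- default_growth_anchors()
  bad_n$mean[bad_n$quantity == "N"][2] <- 100
  expect_error(generator_spec(anchors = bad_n), "non-decreasing")
  expect_error(generator_spec(noise_sd_scale = -1), "noise_sd_scale")
})

test_that("puncture conserves tissue, drops lumen, thickens wall, recovers", {
  pair <- generate_puncture_experiment(
    generator_spec(noise_sd_scale = 0),
    t_puncture = 30, loss_fraction = 0.35
  )
  ctrl <- pair[pair$side == "control", ]
  pun <- pair[pair$side == "punctured", ]
  i30 <- which(ctrl$t == 30)
  expect_equal(pun$Vt[i30], ctrl$Vt[i30], tolerance = 0.01)
  expect_equal(
    (ctrl$Vl[i30] - pun$Vl[i30]) / ctrl$Vl[i30], 0.35,
    tolerance = 1e-6
  )
  expect_gt(pun$h_medial[i30], ctrl$h_medial[i30])
  expect_gt(pun$h_lateral[i30], ctrl$h_lateral[i30])
  # poles are stiff: proportionally much weaker thickening
  pole_resp <- pun$h_poles[i30] / ctrl$h_poles[i30] - 1
  med_resp <- pun$h_medial[i30] / ctrl$h_medial[i30] - 1
  expect_lt(pole_resp, 0.5 * med_resp)
  # volume asymmetry decays monotonically to < 0.05 by the series end
  am <- asymmetry_metrics(pair)
  post <- am$t >= 30
  expect_true(all(diff(am$dVl_rel[post]) <= 1e-8))
  expect_lt(abs(am$dVl_rel[nrow(am)]), 0.05)
})

test_that("puncture recovery follows the linear catch-up law", {
  # independent oracle: re-integrate dVl/dt = (Omega_wt + kappa*deficit)*Sl
  # from the backbone curves with a simple Euler scheme
  spec <- generator_spec(noise_sd_scale = 0)
  kappa <- 4
  pair <- generate_puncture_experiment(spec,
    t_puncture = 30,
    loss_fraction = 0.35, kappa = kappa
  )
  pun <- pair[pair$side == "punctured", ]
  bb <- generate_wildtype_cohort(spec)
  vl_bb <- stats::splinefun(bb$t[1:30], bb$Vl[1:30])
  sl_bb <- stats::splinefun(bb$t[1:30], bb$Sl[1:30])
  dt <- 0.01
  tf <- seq(30, 45, by = dt)
  vl <- numeric(length(tf))
  vl[1] <- vl_bb(30) * 0.65
  for (i in seq_len(length(tf) - 1)) {
    t_i <- tf[i]
    om <- vl_bb(t_i, deriv = 1) * 1000 / sl_bb(t_i)
    def <- max(0, (vl_bb(t_i) - vl[i]) / vl_bb(t_i))
    om_t <- if (t_i < 30 + 5 / 60) 0 else om + kappa * def
    sl_p <- sl_bb(t_i) * (vl[i] / vl_bb(t_i))^(2 / 3)
    vl[i + 1] <- vl[i] + dt * om_t * sl_p / 1000
  }
  oracle <- stats::approx(tf, vl, xout = pun$t[pun$t >= 30])$y
  expect_equal(pun$Vl[pun$t >= 30], oracle, tolerance = 0.01)
})

test_that("degenerate punctures are no-ops and invalid ones error", {
  spec <- generator_spec(noise_sd_scale = 0)
  pair0 <- generate_puncture_experiment(spec, t_puncture = 30, loss_fraction = 0)
  am <- asymmetry_metrics(pair0)
  # only the 5-minute open-wound pause remains, a ~1% transient
  expect_lt(max(abs(am$dVl_rel)), 0.02)
  expect_error(
    generate_puncture_experiment(spec, t_puncture = 50),
    "span"
  )
  expect_error(
    generate_puncture_experiment(spec, loss_fraction = 1.2),
    "loss_fraction"
  )
})

test_that("pressure traces have the requested plateau and exact stages at zero noise", {
  tr <- generate_pressure_trace(
    P_baseline = 0, P_plateau = 166,
    noise_sd = 0, seed = 1
  )
  plat <- tr$P_pa[tr$stage == "plateau"]
  expect_true(all(plat == 166))
  expect_true(all(tr$P_pa[tr$stage == "baseline"] == 0))
  flat <- generate_pressure_trace(
    P_baseline = 50, P_plateau = 50,
    noise_sd = 0, seed = 1
  )
  expect_true(all(flat$P_pa == 50))
  expect_error(generate_pressure_trace(noise_sd = -1), "noise_sd")
  expect_error(generate_pressure_trace(P_baseline = 100, P_plateau = 50), "P_plateau")
})

test_that("ouabain at full dose arrests lumen growth", {
  oua <- generate_perturbation_cohort(
    generator_spec(noise_sd_scale = 0, seed = 3),
    kind = "ouabain", dose_scale = 1, t_treat = 25
  )
  vl <- oua$Vl[oua$embryo_id == "wt_01" & oua$t >= 25]
  expect_lt(max(vl) - min(vl), 1e-6)
})

test_that("cytochalasin raises the realized flux 2-5 fold", {
  cy <- generate_perturbation_cohort(
    generator_spec(seed = 2),
    kind = "cytochalasin", dose_scale = 1, t_treat = 25
  )
  wt <- generate_wildtype_cohort(generator_spec(seed = 2))
  f_cy <- compute_flux(cy)
  f_wt <- compute_flux(wt)
  win <- f_cy$t >= 29 & f_cy$t <= 41
  ratio <- mean(f_cy$Omega[win]) / mean(f_wt$Omega[win])
  expect_gte(ratio, 2)
  expect_lte(ratio, 5)
})

test_that("zero dose reproduces the wild-type cohort", {
  d0 <- generate_perturbation_cohort(generator_spec(seed = 5), "ouabain", 0)
  wt <- generate_wildtype_cohort(generator_spec(seed = 5))
  expect_equal(as.data.frame(d0), as.data.frame(wt), ignore_attr = TRUE)
  expect_error(
    generate_perturbation_cohort(generator_spec(), "unknown-drug"),
    "must be one of"
  )
})

test_that("cohorts round-trip through the tidy CSV format", {
  co <- generate_wildtype_cohort(generator_spec(n_embryos = 2, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(
    as.data.frame(back[order(back$embryo_id, back$t), names(co)]),
    as.data.frame(co),
    tolerance = 1e-8
  )
})
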