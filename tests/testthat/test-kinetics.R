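test_that("quadratic windows recover polynomials exactly", {
  t <- 0:12
  fit <- quadratic_window_fit(t, 2 * t^2 + 3 * t + 1, half_window = 3)
  expect_equal(fit$value, 2 * t^2 + 3 * t + 1, tolerance = 1e-9)
  expect_equal(fit$deriv, 4 * t + 3, tolerance = 1e-9)
  const <- quadratic_window_fit(t, rep(5, length(t)), half_window = 3)
  expect_equal(const$deriv, rep(0, length(t)), tolerance = 1e-10)
  expect_error(
    quadratic_window_fit(c(0, 5, 10), c(1, 2, 3), t_eval = 5, half_window = 1),
    "Fewer than 3"
  )
})

test_that("derivatives of noisy linear data are accurate at SNR 10", {
  # Monte-Carlo oracle: slope 2 with noise sd = range/10 / ... signal sd
  # over the window ~ 2*3; noise sd 0.6 gives SNR 10 on the signal
  set.seed(11)
  errs <- replicate(100, {
    t <- 0:20
    y <- 2 * t + rnorm(length(t), sd = 0.6)
    fit <- quadratic_window_fit(t, y, t_eval = 10, half_window = 3)
    (fit$deriv - 2) / 2
  })
  expect_lt(median(abs(errs)), 0.1)
  expect_lt(abs(mean(errs)), 0.05)
})

test_that("window width does not matter on noise-free quadratic data", {
  t <- 0:20
  y <- 0.5 * t^2 - t + 3
  f2 <- quadratic_window_fit(t, y, t_eval = 10, half_window = 2)
  f4 <- quadratic_window_fit(t, y, t_eval = 10, half_window = 4)
  f6 <- quadratic_window_fit(t, y, t_eval = 10, half_window = 6)
  expect_equal(f2$deriv, f4$deriv, tolerance = 1e-9)
  expect_equal(f4$deriv, f6$deriv, tolerance = 1e-9)
})

test_that("flux is zero for a constant lumen and positive for growth", {
  t <- 16:45
  flat <- tibble::tibble(t = t, Vl = 200, Sl = 15000)
  expect_equal(max(abs(compute_flux(flat)$Omega)), 0, tolerance = 1e-10)
  co <- default_cohort()
  fl <- compute_flux(co)
  expect_true(all(fl$Omega[fl$t >= 18] > 0))
})

test_that("flux equals the radial growth rate for a sphere", {
  # R(t) = R0 + c*t exactly: Omega must equal c (lumen conservation)
  c_rate <- 1.2
  t <- seq(16, 45, by = 1)
  R <- 20 + c_rate * (t - 16)
  sphere <- tibble::tibble(
    t = t,
    Vl = 4 / 3 * pi * R^3 / 1e3,
    Sl = 4 * pi * R^2
  )
  fl <- compute_flux(sphere)
  inner <- !fl$edge
  expect_equal(fl$Omega[inner], rep(c_rate, sum(inner)), tolerance = 0.01)
  # Eq-8 equivalence: same rate via shell radii + quadratic fit
  g <- shell_from_volumes(Vl = sphere$Vl, Vo = sphere$Vl + 100)
  rfit <- quadratic_window_fit(t, g$Rl, half_window = 3)
  expect_equal(fl$Omega[inner], rfit$deriv[inner], tolerance = 0.01)
})

test_that("mean cohort flux is about 1 um/hr and errors are caught", {
  fl <- compute_flux(default_cohort())
  expect_equal(mean(fl$Omega[fl$t >= 21 & fl$t <= 45]), 1, tolerance = 0.25)
  bad <- tibble::tibble(t = 16:45, Vl = 100, Sl = -(16:45))
  expect_error(compute_flux(bad), "positive")
})

test_that("tissue growth decomposes into offsetting early terms", {
  co <- noisefree_cohort()
  tg <- tissue_growth_decomposition(co)
  early <- tg$t >= 17 & tg$t <= 26
  # early growth: division offset by cell-size decrease, |j| small relative
  # to the gross term magnitudes
  expect_lt(
    mean(abs(tg$j[early])),
    0.2 * mean(abs(tg$division_term[early]) + abs(tg$size_term[early]))
  )
  expect_true(all(tg$offsetting[tg$t >= 17 & tg$t <= 24]))
  # decomposition closure: terms sum to the fitted derivative of N*s
  # within 1% of the gross term scale (j itself crosses zero)
  tg2 <- tissue_growth_decomposition(co, half_window = 2)
  prod_fit <- quadratic_window_fit(co$t, co$N * co$s, half_window = 2)
  inner <- !tg2$edge
  gross <- max(abs(tg2$division_term) + abs(tg2$size_term))
  expect_lt(max(abs(tg2$j[inner] - prod_fit$deriv[inner])), 0.01 * gross)
})

test_that("tissue growth terms behave in degenerate designs", {
  t <- 16:45
  s_const <- tibble::tibble(t = t, N = 400 + 10 * t, s = 0.4)
  tg <- tissue_growth_decomposition(s_const)
  expect_equal(tg$j, 0.4 * rep(10, length(t)), tolerance = 1e-8)
  n_const <- tibble::tibble(t = t, N = 500, s = 0.6 - 0.005 * t)
  tg2 <- tissue_growth_decomposition(n_const)
  expect_true(all(tg2$j < 0))
  expect_equal(tg2$j, 500 * rep(-0.005, length(t)), tolerance = 1e-8)
})

test_that("surface decomposition closes and finds the break-even near 33 hpf", {
  co <- default_cohort()
  dec <- surface_decomposition(co)
  inner <- !dec$edge
  expect_equal(
    (dec$stretch_term + dec$division_term)[inner],
    dec$total_rate[inner],
    tolerance = 0.02
  )
  expect_equal(break_even_time(dec), 33, tolerance = 2 / 33)
  # noise-free closure is tighter
  dec0 <- surface_decomposition(noisefree_cohort())
  expect_equal(
    (dec0$stretch_term + dec0$division_term)[!dec0$edge],
    dec0$total_rate[!dec0$edge],
    tolerance = 0.01
  )
})

test_that("surface decomposition flags absent or immediate crossings", {
  t <- 16:45
  n_const <- tibble::tibble(t = t, N = 500, Sl = 1000 + 100 * (t - 16))
  expect_message(
    dec <- surface_decomposition(n_const),
    "break-even time is NA"
  )
  expect_true(is.na(break_even_time(dec)))
  expect_equal(max(abs(dec$division_term)), 0, tolerance = 1e-9)
  psi_const <- tibble::tibble(t = t, N = 500 + 10 * (t - 16))
  psi_const$Sl <- 20 * psi_const$N
  dec2 <- surface_decomposition(psi_const)
  expect_equal(max(abs(dec2$stretch_term)), 0, tolerance = 1e-6)
  expect_equal(break_even_time(dec2), t[1])
})

test_that("asymmetry metrics are zero for identical sides and track the loss", {
  co <- noisefree_cohort()
  fake_pair <- dplyr::bind_rows(
    dplyr::mutate(co, side = "control"),
    dplyr::mutate(co, side = "punctured")
  )
  am <- asymmetry_metrics(fake_pair)
  expect_equal(max(abs(am$dVl_rel)), 0)
  expect_equal(max(abs(am$dh_rel)), 0)
  pair <- generate_puncture_experiment(
    generator_spec(noise_sd_scale = 0),
    t_puncture = 30, loss_fraction = 0.35
  )
  am2 <- asymmetry_metrics(pair)
  expect_equal(am2$dVl_rel[am2$t == 30], 0.35, tolerance = 1e-6)
  expect_lt(am2$dh_rel[am2$t == 30], 0) # wall thickens on the punctured side
})

test_that("flux-deficit regression recovers the generator catch-up gain", {
  fit <- flux_deficit_regression(puncture_pairs())
  expect_gte(fit$kappa_hat, 3)
  expect_lte(fit$kappa_hat, 5)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$estimate[td$term == "kappa"], fit$kappa_hat)
  gl <- glance(fit)
  expect_gt(gl$r.squared, 0.3)
})

test_that("kappa recovery is unbiased across replicate experiments", {
  khat <- sapply(1:6, function(rep) {
    pairs <- lapply(1:10, function(i) {
      s <- 1000L + 100L * rep + i
      generate_puncture_experiment(generator_spec(seed = s),
        t_puncture = 30, seed = s
      )
    })
    flux_deficit_regression(pairs)$kappa_hat
  })
  expect_equal(median(khat), 4, tolerance = 0.15)
})

test_that("noise-free pairs give kappa close to the generating value", {
  pairs <- lapply(1:3, function(i) {
    generate_puncture_experiment(
      generator_spec(noise_sd_scale = 0, seed = i),
      t_puncture = 30, seed = i
    )
  })
  fit <- flux_deficit_regression(pairs)
  expect_equal(fit$kappa_hat, 4, tolerance = 0.15)
})

test_that("unpunctured pairs show no deficit-flux association", {
  # proper pairs (shared embryo effect) with a zero-loss puncture: the
  # deficit is pure measurement noise and explains nothing
  pairs <- lapply(21:30, function(s) {
    generate_puncture_experiment(generator_spec(seed = s),
      t_puncture = 30, loss_fraction = 0, seed = s
    )
  })
  fit <- flux_deficit_regression(pairs, calibrate = FALSE)
  expect_lt(glance(fit)$r.squared, 0.2)
})

test_that("degenerate regression designs error", {
  pair <- puncture_pairs()[[1]]
  expect_error(
    flux_deficit_regression(pair, min_points = 1000),
    "at least"
  )
})
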