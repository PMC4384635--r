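test_that("initial rate recovers slopes and ignores offsets", {
  ts <- tibble::tibble(time_s = seq(0, 300, 10), signal = 0.02 * seq(0, 300, 10))
  r <- suppressWarnings(initial_rate(ts)) # exact line: sigma ~ 0
  expect_equal(r$rate_per_min, 1.2, tolerance = 1e-12)
  expect_equal(r$n_points, 16) # only the 150-s window enters

  flat <- tibble::tibble(time_s = seq(0, 300, 10), signal = 5)
  expect_equal(suppressWarnings(initial_rate(flat))$rate_per_min, 0)

  # constant offset leaves the slope untouched
  ts_off <- ts
  ts_off$signal <- ts_off$signal + 7.5
  expect_equal(suppressWarnings(initial_rate(ts_off))$rate_per_min, r$rate_per_min)

  # noisy line: slope within 3 SE of the generator slope
  set.seed(5)
  tgrid <- seq(0, 145, length.out = 30)
  noisy <- tibble::tibble(time_s = tgrid, signal = 0.05 * tgrid + rnorm(30, 0, 0.1))
  rn <- initial_rate(noisy)
  expect_lt(abs(rn$rate_per_min - 3), 3 * rn$se_per_min)

  expect_error(initial_rate(tibble::tibble(time_s = c(0, 200, 400),
                                           signal = 1:3), window = 150),
               "at least 3")
})

test_that("activation slope flags curvature and preserves fold ratios", {
  tt <- seq(0, 100, 5)
  lin <- tibble::tibble(time_s = tt, activity = 0.3 * tt + 1)
  s <- suppressWarnings(activation_slope(lin))
  expect_equal(s$slope, 0.3, tolerance = 1e-10)
  expect_false(s$nonlinear)

  conv <- tibble::tibble(time_s = tt, activity = tt^2)
  expect_true(activation_slope(conv)$nonlinear)

  # two noisy series whose true slopes differ sixfold
  set.seed(21)
  a <- tibble::tibble(time_s = tt, activity = 0.6 * tt + rnorm(length(tt), 0, 0.5))
  b <- tibble::tibble(time_s = tt, activity = 0.1 * tt + rnorm(length(tt), 0, 0.5))
  ratio <- activation_slope(a)$slope / activation_slope(b)$slope
  expect_lt(abs(ratio - 6) / 6, 0.2)

  expect_error(activation_slope(lin[1:2, ]), "at least 3")
})

test_that("Michaelis-Menten fitting recovers Km for the PLC-gamma2 peptide scale", {
  truth_km <- 925e-6
  ds <- gen_mm_dataset(Vmax = 10, Km = truth_km, noise_sd = 0)
  fit <- fit_michaelis_menten(ds$data)
  expect_equal(fit$estimate[["Km"]], truth_km, tolerance = 1e-4)
  expect_equal(fit$estimate[["Vmax"]], 10, tolerance = 1e-4)

  # half-maximal rate at S = Km is a property of the fitted curve
  v_at_km <- fit$estimate[["Vmax"]] * truth_km / (fit$estimate[["Km"]] + truth_km)
  expect_equal(v_at_km, fit$estimate[["Vmax"]] / 2, tolerance = 1e-4)

  # 5% noise: recovery within 2 SE
  dn <- gen_mm_dataset(Vmax = 10, Km = truth_km, noise_sd = 0.5, seed = 8)
  fn <- fit_michaelis_menten(dn$data)
  expect_lt(abs(fn$estimate[["Km"]] - truth_km), 2 * fn$se[["Km"]])

  # first-order optimality: residuals orthogonal to the model gradient
  res <- dn$data$rate - fn$estimate[["Vmax"]] * dn$data$substrate /
    (fn$estimate[["Km"]] + dn$data$substrate)
  g_vmax <- dn$data$substrate / (fn$estimate[["Km"]] + dn$data$substrate)
  g_km <- -fn$estimate[["Vmax"]] * dn$data$substrate /
    (fn$estimate[["Km"]] + dn$data$substrate)^2
  scale <- sqrt(sum(res^2)) * sqrt(sum(g_vmax^2))
  expect_lt(abs(sum(res * g_vmax)) / scale, 1e-6)
  expect_lt(abs(sum(res * g_km)) / (sqrt(sum(res^2)) * sqrt(sum(g_km^2))), 1e-6)

  # a single substrate level carries no curvature information
  expect_error(
    fit_michaelis_menten(tibble::tibble(substrate = rep(1e-3, 4), rate = 5)),
    "unidentifiable")

  expect_identical(tidy(fit)$term, c("Vmax", "Km"))
  expect_true(glance(fit)$converged)
})

test_that("logistic EC50 fitting is exact, scale-free and deterministic", {
  doses <- c(0, 10^seq(-6.5, -3.5, length.out = 9))
  dr <- tibble::tibble(dose = doses,
                       response = logistic_response(doses, 20e-6, hill = 1,
                                                    floor = 0.1, ceiling = 0.9))
  fit <- fit_ec50(dr)
  expect_equal(fit$estimate[["ec50"]], 20e-6, tolerance = 1e-6)
  expect_equal(fit$estimate[["hill"]], 1, tolerance = 1e-5)

  # affine response transforms leave the EC50 unchanged
  dr2 <- dr; dr2$response <- 3 * dr$response + 2
  expect_equal(fit_ec50(dr2)$estimate[["ec50"]], fit$estimate[["ec50"]],
               tolerance = 1e-8)

  # repeated identical calls agree bitwise (no hidden randomness)
  expect_identical(fit_ec50(dr)$estimate, fit$estimate)

  # 2% noise: recovery within 2 SE
  set.seed(13)
  drn <- dr
  drn$response <- dr$response + rnorm(nrow(dr), 0, 0.02 * diff(range(dr$response)))
  fitn <- fit_ec50(drn)
  expect_lt(abs(fitn$estimate[["ec50"]] - 20e-6), 2 * fitn$se[["ec50"]])

  # non-monotone beyond noise triggers a warning
  bad <- dr
  bad$response[9] <- 0.05 # near-ceiling point collapses to the floor
  expect_warning(fit_ec50(bad), "non-monotone")

  expect_error(fit_ec50(dr[1:4, ]), "at least 5")
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("mechanistic dose-response yields an EC50 matching its own half-response", {
  doses <- c(0, 10^seq(-7, -3, length.out = 17))
  ds <- gen_dose_response(peripheral_kd = 7e-6, onrate_ceiling = 10,
                          doses = doses, readout_time = 600, total0 = 2e-6)
  fit <- fit_ec50(ds$data)
  truth <- ds$truth[ds$truth$dose > 0, ]
  half <- min(truth$response) + diff(range(truth$response)) / 2
  half_dose <- stats::approx(truth$response, truth$dose, xout = half)$y
  expect_lt(abs(fit$estimate[["ec50"]] - half_dose) / half_dose, 0.2)

  # dose extremes reproduce the two kinetic scenarios
  base <- simulate_progress(rate_parameters("no_IP6"), 2e-6, c(0, 300, 600))
  sat <- simulate_progress(rate_parameters("with_IP6"), 2e-6, c(0, 300, 600))
  expect_equal(ds$truth$response[1], base$phospho_fraction[3], tolerance = 1e-6)
  expect_equal(ds$truth$response[nrow(ds$truth)], sat$phospho_fraction[3],
               tolerance = 2e-2) # 1 mM is ~143 x Kd, occupancy 0.993
})
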