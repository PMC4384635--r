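test_that("rate parameter defaults, overrides and errors", {
  p0 <- rate_parameters("no_IP6")
  expect_equal(p0$k1, 1e4)
  expect_equal(p0$k3, 1e4)
  expect_equal(p0$k_minus1, 20)
  expect_equal(p0$k_minus3, 20)
  expect_equal(p0$k2, 0.1)
  expect_equal(p0$k4, 1.0)
  expect_identical(p0$label, "no_IP6")

  p1 <- rate_parameters("with_IP6")
  expect_equal(p1$k1, 1e5)
  expect_equal(p1$k3, 1e5)

  poff <- rate_parameters("no_IP6", k2 = 0, k4 = 0)
  expect_equal(poff$k2, 0)
  expect_equal(poff$k4, 0)
  expect_equal(poff$k1, 1e4) # untouched defaults survive overrides

  expect_error(rate_parameters("maybe_IP6"))
  expect_error(rate_parameters("no_IP6", k2 = -1), "non-negative")
  expect_error(rate_parameters("no_IP6", k9 = 1), "unknown")
})

test_that("dimer Kd and the equilibrium dimer fraction closed form", {
  expect_equal(dimer_kd(rate_parameters("no_IP6")), 2e-3)
  expect_equal(dimer_kd(rate_parameters("with_IP6")), 2e-4)
  p <- rate_parameters("no_IP6", k1 = 1e5)
  expect_equal(dimer_kd(p), dimer_kd(rate_parameters("no_IP6")) / 10)
  expect_error(dimer_kd(rate_parameters("no_IP6", k1 = 0)), "positive")

  # Kd = 8 * total0: M = total0 * (sqrt(128) - 8) / 4, fraction = 3 - 2 sqrt(2)
  expect_equal(equilibrium_dimer_fraction(1e-6, 8e-6), 3 - 2 * sqrt(2),
               tolerance = 1e-12)

  # micromolar protein against a millimolar Kd: tiny dimer population,
  # cross-checked by numeric root finding on the mass balance
  frac <- equilibrium_dimer_fraction(1e-6, 2e-3)
  root <- stats::uniroot(function(M) M + 2 * M^2 / 2e-3 - 1e-6,
                         c(0, 1e-6), tol = 1e-18)$root
  expect_equal(frac, 1 - root / 1e-6, tolerance = 1e-6)
  expect_lt(abs(frac - 1e-3), 2e-4)

  # no-association limit
  expect_lt(equilibrium_dimer_fraction(1e-6, 1e6), 1e-11)
  expect_error(equilibrium_dimer_fraction(0, 1e-3), "positive")
  expect_error(equilibrium_dimer_fraction(1e-6, -1), "positive")
})

test_that("progress curves conserve monomer units and stay physical", {
  # all rates zero: frozen state
  p0 <- rate_parameters("no_IP6", k1 = 0, k_minus1 = 0, k2 = 0,
                        k3 = 0, k_minus3 = 0, k4 = 0)
  curve <- simulate_progress(p0, 1e-6, seq(0, 100, 10))
  expect_true(all(curve$M_uM == 1))
  expect_true(all(curve$phospho_fraction == 0))
  expect_warning(expect_true(is.na(time_to_half(curve))), "never reaches")

  # randomized rate draws: conservation, non-negativity, monotone fraction
  set.seed(11)
  t_grid <- c(0, 10^seq(-1, 3, length.out = 30))
  for (i in 1:8) {
    p <- rate_parameters(
      sample(c("no_IP6", "with_IP6"), 1),
      k1 = 10^stats::runif(1, 3, 6), k_minus1 = 10^stats::runif(1, 0, 2),
      k2 = 10^stats::runif(1, -2, 0), k3 = 10^stats::runif(1, 3, 6),
      k_minus3 = 10^stats::runif(1, 0, 2), k4 = 10^stats::runif(1, -1, 1)
    )
    total_um <- stats::runif(1, 0.5, 5)
    curve <- simulate_progress(p, total_um * 1e-6, t_grid)
    cons <- curve$M_uM + curve$P_uM + 2 * curve$MM_uM + 2 * curve$PM_uM
    expect_lt(max(abs(cons - total_um) / total_um), 1e-6)
    expect_true(all(curve$M_uM >= 0 & curve$P_uM >= 0 &
                      curve$MM_uM >= 0 & curve$PM_uM >= 0))
    expect_true(all(diff(curve$phospho_fraction) >= -1e-9))
  }
})

test_that("adaptive solution matches the fixed-step Euler reference", {
  t_grid <- seq(0, 200, length.out = 41)
  for (sc in c("no_IP6", "with_IP6")) {
    p <- rate_parameters(sc)
    ad <- simulate_progress(p, 1e-6, t_grid)
    eu <- simulate_progress_euler(p, 1e-6, t_grid, h = 1e-3)
    expect_lt(progress_mixed_err(ad, eu, 1), 1e-3)
  }
})

test_that("phospho_fraction and time_to_half behave on edge cases", {
  curve <- simulate_progress(rate_parameters("with_IP6"), 1e-6, seq(0, 900, 5))
  pf <- phospho_fraction(curve)
  expect_equal(pf$phospho_fraction[1], 0)
  expect_true(all(pf$phospho_fraction >= 0 & pf$phospho_fraction <= 1))

  # step curve: interpolation puts the crossing at the window midpoint
  jump <- btkinetics:::new_progress(
    tibble::tibble(time_s = c(0, 10), M_uM = c(1, 0), P_uM = c(0, 1),
                   MM_uM = 0, PM_uM = 0, phospho_fraction = c(0, 1)),
    total0 = 1e-6, params = rate_parameters("no_IP6")
  )
  expect_equal(time_to_half(jump), 5)

  # long-time limit approaches complete phosphorylation
  late <- simulate_progress(rate_parameters("with_IP6"), 1e-6, c(0, 5000))
  expect_gt(late$phospho_fraction[2], 0.999)
})

test_that("autocatalytic feedback makes activation sigmoidal", {
  t_grid <- c(0, 10^seq(-2, 4, length.out = 200))
  total0 <- 1e-6

  # defaults (k4 > k2): the phospho-rate peaks well into the run
  curve <- simulate_progress(rate_parameters("no_IP6"), total0, t_grid)
  rate <- diff(curve$phospho_fraction) / diff(curve$time_s)
  t_mid <- (t_grid[-1] + t_grid[-length(t_grid)]) / 2
  expect_gt(t_mid[which.max(rate)], 10)

  # feedback off (k4 = k2, k3 = k1): the rate peaks during the fast
  # encounter-complex pre-equilibration, within the first second
  pflat <- rate_parameters("no_IP6", k4 = 0.1)
  curve2 <- simulate_progress(pflat, total0, t_grid)
  rate2 <- diff(curve2$phospho_fraction) / diff(curve2$time_s)
  expect_lt(t_mid[which.max(rate2)], 1)

  # catalysis off: complex pool equilibrates to the closed-form dimer fraction
  pdim <- rate_parameters("no_IP6", k2 = 0, k4 = 0)
  eq <- simulate_progress(pdim, total0, c(0, 1, 10))
  expected_mm_um <- equilibrium_dimer_fraction(total0, dimer_kd(pdim)) *
    (total0 * 1e6) / 2
  expect_equal(eq$MM_uM[3], expected_mm_um, tolerance = 1e-3)
})

test_that("IP6 accelerates activation far more than the 10x on-rate change", {
  t_grid <- seq(0, 1e4, length.out = 401)
  t50 <- vapply(c("no_IP6", "with_IP6"), function(sc) {
    time_to_half(simulate_progress(rate_parameters(sc), 1e-6, t_grid))
  }, numeric(1))
  expect_false(any(is.na(t50)))
  expect_lt(t50[["with_IP6"]] / t50[["no_IP6"]], 0.2)
})

test_that("progress curves survive a CSV round trip", {
  curve <- simulate_progress(rate_parameters("with_IP6"), 1e-6, seq(0, 100, 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_progress_csv(curve, path)
  back <- read_progress_csv(path)
  expect_named(back, c("time_s", "M_uM", "P_uM", "MM_uM", "PM_uM",
                       "phospho_fraction"))
  expect_equal(back$P_uM, curve$P_uM, tolerance = 1e-12)
})
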