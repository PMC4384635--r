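#' Seeded synthetic assay generators
#'
#' Each generator is a pure function of its arguments including the seed:
#' identical calls return identical data. Observations carry additive
#' i.i.d. Gaussian noise; the noiseless truth is always returned alongside
#' so recovery tests never peek beyond the observation table. The default
#' noise scale in the package's studies is 2% of the dynamic range of the
#' noiseless signal.
#'
#' @name synthetic-data
NULL

check_noise <- function(noise_sd) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("`noise_sd` must be a single non-negative number", call. = FALSE)
  }
}

#' Generate a noisy kinase-activity progress dataset
#'
#' Simulates the trans-autophosphorylation scheme, maps the phospho-fraction
#' to an activity signal (`signal = scale * fraction`), and adds Gaussian
#' noise — emulating a continuous coupled-assay readout of activation.
#'
#' @param params a [rate_parameters()] object.
#' @param total0 total Btk, molar.
#' @param t_grid output times, seconds, starting at 0.
#' @param noise_sd Gaussian noise standard deviation, in signal units.
#' @param seed integer seed.
#' @param scale signal per unit phospho-fraction.
#' @return A list with `data` (tibble `time_s`, `signal`), `truth` (the
#'   noiseless `btk_progress` curve) and `meta` (noise model, seed,
#'   parameters).
#' @export
gen_progress_dataset <- function(params, total0, t_grid, noise_sd = 0.02,
                                 seed = 1, scale = 1) {
  check_noise(noise_sd)
  truth <- simulate_progress(params, total0, t_grid)
  sig <- scale * truth$phospho_fraction
  set.seed(seed)
  obs <- sig + stats::rnorm(length(sig), 0, noise_sd)
  list(
    data = tibble::tibble(time_s = truth$time_s, signal = obs),
    truth = truth,
    meta = list(noise = "additive gaussian", noise_sd = noise_sd,
                seed = seed, scale = scale, scenario = params$label,
                total0 = total0)
  )
}

#' Generate a noisy ITC isotherm dataset
#'
#' Forward-simulates the one-site isotherm and adds Gaussian noise to the
#' per-injection heats.
#'
#' @param params a [binding_parameters()] object.
#' @param experiment an [itc_experiment()].
#' @param noise_sd Gaussian noise sd in kcal per mole of injectant.
#' @param seed integer seed.
#' @return A list with `data` (noisy `itc_isotherm` tibble), `truth`
#'   (noiseless isotherm) and `meta`.
#' @export
gen_isotherm_dataset <- function(params, experiment = itc_experiment(),
                                 noise_sd = NULL, seed = 1) {
  truth <- simulate_isotherm(params, experiment)
  if (is.null(noise_sd)) noise_sd <- 0.02 * max(abs(truth$heat_kcal_per_mol))
  check_noise(noise_sd)
  set.seed(seed)
  noisy <- truth
  noisy$heat_kcal_per_mol <- truth$heat_kcal_per_mol +
    stats::rnorm(nrow(truth), 0, noise_sd)
  list(
    data = noisy, truth = truth,
    meta = list(noise = "additive gaussian", noise_sd = noise_sd, seed = seed,
                params = unclass(params))
  )
}

#' Mechanistic IP6 dose-response generator
#'
#' Produces a dose-response curve from the mechanism rather than from a
#' logistic form: peripheral-site occupancy `theta = dose / (Kd + dose)`
#' scales the dimerization on-rates linearly between the basal value and
#' `ceiling` times it (`k1 = k3 = k_base * (1 + (ceiling - 1) * theta)`),
#' and the response is the phospho-fraction at `readout_time` from the
#' kinetic scheme. At dose 0 this reproduces the basal ("no_IP6") scenario;
#' far above `Kd` it reproduces the fully IP6-stimulated one.
#'
#' @param peripheral_kd peripheral-site dissociation constant, molar
#'   (residual-site affinity is in the 5-10 uM range).
#' @param onrate_ceiling fold increase of the on-rate at saturation.
#' @param doses vector of IP6 concentrations, molar, non-negative.
#' @param readout_time time at which the phospho-fraction is read, seconds.
#' @param total0 total Btk, molar.
#' @param k_base basal on-rate, per-molar per-second.
#' @param noise_sd Gaussian noise sd on the response (fraction units).
#' @param seed integer seed.
#' @return A list with `data` (tibble `dose`, `response`), `truth` (tibble
#'   with the noiseless response and occupancy) and `meta` (includes the
#'   occupancy-to-rate mapping used).
#' @export
gen_dose_response <- function(peripheral_kd = 7e-6, onrate_ceiling = 10,
                              doses = 10^seq(-7, -3, length.out = 12),
                              readout_time = 600, total0 = 2e-6,
                              k_base = 1e4, noise_sd = 0, seed = 1) {
  check_noise(noise_sd)
  if (any(doses < 0)) stop("doses must be non-negative", call. = FALSE)
  if (readout_time <= 0) stop("`readout_time` must be positive", call. = FALSE)
  theta <- doses / (peripheral_kd + doses)
  resp <- vapply(theta, function(th) {
    k_on <- k_base * (1 + (onrate_ceiling - 1) * th)
    p <- rate_parameters("no_IP6", k1 = k_on, k3 = k_on)
    curve <- simulate_progress(p, total0, c(0, readout_time / 2, readout_time))
    curve$phospho_fraction[nrow(curve)]
  }, numeric(1))
  set.seed(seed)
  obs <- resp + stats::rnorm(length(resp), 0, noise_sd)
  list(
    data = tibble::tibble(dose = doses, response = obs),
    truth = tibble::tibble(dose = doses, occupancy = theta, response = resp),
    meta = list(peripheral_kd = peripheral_kd, onrate_ceiling = onrate_ceiling,
                readout_time = readout_time, total0 = total0, k_base = k_base,
                occupancy_to_rate = "linear in occupancy",
                noise = "additive gaussian", noise_sd = noise_sd, seed = seed)
  )
}

#' Generate a Michaelis-Menten rate dataset
#'
#' @param Vmax maximal rate, per minute.
#' @param Km Michaelis constant, molar.
#' @param substrate_grid substrate concentrations, molar.
#' @param noise_sd Gaussian noise sd in rate units.
#' @param seed integer seed.
#' @return A list with `data` (tibble `substrate`, `rate`), `truth` and
#'   `meta`.
#' @export
gen_mm_dataset <- function(Vmax, Km,
                           substrate_grid = 925e-6 * c(0.125, 0.25, 0.5, 1, 2, 4, 8, 16),
                           noise_sd = 0, seed = 1) {
  check_noise(noise_sd)
  stopifnot(Vmax > 0, Km > 0, all(substrate_grid >= 0))
  v <- Vmax * substrate_grid / (Km + substrate_grid)
  set.seed(seed)
  obs <- v + stats::rnorm(length(v), 0, noise_sd)
  list(
    data = tibble::tibble(substrate = substrate_grid, rate = obs),
    truth = tibble::tibble(substrate = substrate_grid, rate = v),
    meta = list(Vmax = Vmax, Km = Km, noise = "additive gaussian",
                noise_sd = noise_sd, seed = seed)
  )
}
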