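#' One-site binding parameters
#'
#' The three fitted parameters of a single-class-of-sites ITC model —
#' stoichiometry `N`, association constant `Ka`, and binding enthalpy
#' `dH` — plus the experiment temperature.
#'
#' @param N sites per macromolecule (dimensionless, > 0).
#' @param Ka association constant, per molar (> 0).
#' @param dH binding enthalpy, kcal/mol.
#' @param temperature kelvin; 293.15 K (20 degrees C) matches the titration
#'   conditions used throughout.
#' @return A list of class `binding_parameters`.
#' @examples
#' binding_parameters(N = 1.1, Ka = 4.2e6, dH = -1.1)
#' @export
binding_parameters <- function(N, Ka, dH, temperature = 293.15) {
  if (!is.numeric(N) || N <= 0) stop("`N` must be positive", call. = FALSE)
  if (!is.numeric(Ka) || Ka <= 0) stop("`Ka` must be positive", call. = FALSE)
  if (!is.numeric(dH) || !is.finite(dH)) stop("`dH` must be finite", call. = FALSE)
  if (!is.numeric(temperature) || temperature <= 0) stop("`temperature` must be positive", call. = FALSE)
  structure(list(N = N, Ka = Ka, dH = dH, temperature = temperature),
            class = "binding_parameters")
}

#' ITC titration schedule and cell contents
#'
#' Defaults follow the titrations reproduced here: 20 uM macromolecule in
#' the cell, 300 uM ligand in the syringe, an initial 0.5 ul injection
#' (simulated but excluded from analysis) followed by 14 injections of 3 ul
#' at 180 s spacing, at 20 degrees C. `cell_volume` is the active (sensed)
#' cell volume, not the loaded volume.
#'
#' @param cell_volume active cell volume, liters.
#' @param cell_conc macromolecule concentration in the cell, molar.
#' @param syringe_conc ligand concentration in the syringe, molar.
#' @param injections ordered injection volumes, liters.
#' @param spacing seconds between injections (metadata only).
#' @param discard_first if `TRUE`, the first injection is simulated (it
#'   changes the cell contents) but flagged unused for fitting.
#' @return A list of class `itc_experiment`.
#' @export
itc_experiment <- function(cell_volume = 200e-6,
                           cell_conc = 20e-6,
                           syringe_conc = 300e-6,
                           injections = c(0.5e-6, rep(3e-6, 14)),
                           spacing = 180,
                           discard_first = TRUE) {
  if (any(injections <= 0)) stop("injection volumes must be positive", call. = FALSE)
  if (cell_volume <= 0 || cell_conc <= 0 || syringe_conc <= 0) {
    stop("volumes and concentrations must be positive", call. = FALSE)
  }
  structure(list(cell_volume = cell_volume, cell_conc = cell_conc,
                 syringe_conc = syringe_conc, injections = injections,
                 spacing = spacing, discard_first = discard_first),
            class = "itc_experiment")
}

# Numerically stable smaller root of
#   B^2 - B (N*Mt + Xt + 1/Ka) + N*Mt*Xt = 0,
# the bound-ligand concentration for one class of N sites.
solve_bound <- function(N, Ka, Mt, Xt) {
  s <- N * Mt + Xt + 1 / Ka
  disc <- s^2 - 4 * N * Mt * Xt
  disc[disc < 0] <- 0 # guard tiny negative from cancellation
  2 * N * Mt * Xt / (s + sqrt(disc))
}

#' Simulate a one-site ITC isotherm
#'
#' Forward (Wiseman-type) model for a fixed-volume calorimeter cell: each
#' injection displaces its own volume of cell contents, so both the
#' macromolecule and the accumulated ligand are diluted by `(1 - v/V0)`
#' before the injected ligand is added. The single-site equilibrium is then
#' solved exactly (stable quadratic root) and the heat of the injection is
#' `dH` times the change in moles of bound ligand within the active volume,
#' normalized per mole of injectant.
#'
#' @param params a [binding_parameters()].
#' @param experiment an [itc_experiment()].
#' @return A tibble of class `itc_isotherm` with columns `injection_index`,
#'   `volume_ul`, `molar_ratio` (total ligand over total macromolecule in
#'   the cell), `heat_kcal_per_mol` (per mole of injectant) and `used`
#'   (`FALSE` for a discarded first injection). The experiment is carried
#'   as attribute `experiment`, the generating parameters as `params`.
#' @examples
#' iso <- simulate_isotherm(binding_parameters(1.1, 4.2e6, -1.1), itc_experiment())
#' iso
#' @export
simulate_isotherm <- function(params, experiment = itc_experiment()) {
  stopifnot(inherits(params, "binding_parameters"), inherits(experiment, "itc_experiment"))
  V0 <- experiment$cell_volume
  Mt <- experiment$cell_conc
  Xs <- experiment$syringe_conc
  inj <- experiment$injections
  n <- length(inj)
  Xt <- 0
  B_prev <- 0
  heat <- ratio <- numeric(n)
  for (i in seq_len(n)) {
    d <- 1 - inj[i] / V0
    Mt <- Mt * d
    Xt <- Xt * d + Xs * inj[i] / V0
    B <- solve_bound(params$N, params$Ka, Mt, Xt)
    # displaced complex leaves the cell unsensed; heat reflects new binding only
    heat[i] <- params$dH * V0 * (B - B_prev * d) / (Xs * inj[i])
    ratio[i] <- Xt / Mt
    B_prev <- B
  }
  used <- rep(TRUE, n)
  if (isTRUE(experiment$discard_first)) used[1] <- FALSE
  out <- tibble::tibble(
    injection_index = seq_len(n),
    volume_ul = inj * 1e6,
    molar_ratio = ratio,
    heat_kcal_per_mol = heat,
    used = used
  )
  structure(out, experiment = experiment, params = params,
            class = c("itc_isotherm", class(tibble::tibble())))
}

# model heats (used injections only) for a parameter vector, reusing the
# experiment bookkeeping of simulate_isotherm
model_heats <- function(N, Ka, dH, experiment) {
  iso <- simulate_isotherm(binding_parameters(N, Ka, dH), experiment)
  iso$heat_kcal_per_mol[iso$used]
}

#' Fit the one-site binding model to an isotherm
#'
#' Unweighted least squares of simulated against observed per-injection
#' heats over `(N, Ka, dH)`, with `Ka` handled on the log10 scale.
#' Initialization is by a coarse profile search: on a grid of `(N, log10
#' Ka)` the optimal `dH` is solved linearly (the model is linear in `dH`),
#' and the best grid point seeds a Levenberg-Marquardt refinement. Standard
#' errors come from the local curvature at the optimum; `Ka`'s is obtained
#' from the log-scale error by the delta method. The derived quantities
#' `Kd = 1e9 / Ka` (nM) and `dS = (dH + RT ln Ka)/T` (cal/mol/K) are
#' populated from the fitted parameters.
#'
#' An isotherm with no heat signal (all |heats| below `flat_tol`) yields an
#' explicit no-binding outcome rather than a fit, mirroring titrations in
#' which binding is reduced to an undetectable level.
#'
#' @param isotherm an `itc_isotherm` tibble, or any tibble with columns
#'   `heat_kcal_per_mol` and optionally `used`, carrying an
#'   [itc_experiment()] as attribute `experiment` (or supplied via
#'   `experiment`).
#' @param init optional [binding_parameters()] start; when omitted the
#'   profile search above chooses the start.
#' @param experiment overrides the experiment attribute if given.
#' @param temperature kelvin, for the entropy identity.
#' @param flat_tol heat magnitude (kcal/mol of injectant) below which the
#'   isotherm is declared flat.
#' @return An object of class `itc_fit`: a list with `binding_detected`,
#'   `estimate` (named vector N, Ka, dH), `se`, derived `Kd_nM` and
#'   `dS_cal_mol_K`, `residual_norm`, `df_residual`, `converged`, the data
#'   and experiment. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
fit_one_site <- function(isotherm, init = NULL, experiment = NULL,
                         temperature = 293.15, flat_tol = 1e-4) {
  experiment <- experiment %||% attr(isotherm, "experiment")
  if (is.null(experiment)) stop("no `experiment` attached or supplied", call. = FALSE)
  used <- if ("used" %in% names(isotherm)) isotherm$used else rep(TRUE, nrow(isotherm))
  y <- isotherm$heat_kcal_per_mol[used]
  if (length(y) < 5) stop("need at least 5 usable injections", call. = FALSE)

  no_binding <- function(reason) {
    structure(list(binding_detected = FALSE, reason = reason,
                   estimate = NULL, se = NULL, Kd_nM = NA_real_,
                   dS_cal_mol_K = NA_real_, residual_norm = NA_real_,
                   df_residual = NA_integer_, converged = FALSE,
                   data = isotherm, experiment = experiment,
                   temperature = temperature),
              class = "itc_fit")
  }
  if (max(abs(y)) < flat_tol) return(no_binding("flat isotherm: no heat signal"))

  if (is.null(init)) {
    grid <- expand.grid(N = c(0.5, 0.75, 1, 1.25, 1.5, 2),
                        logKa = seq(3, 12, by = 0.5))
    best <- NULL
    for (i in seq_len(nrow(grid))) {
      g <- model_heats(grid$N[i], 10^grid$logKa[i], 1, experiment)
      denom <- sum(g^2)
      if (denom <= 0) next
      dH_i <- sum(g * y) / denom
      sse <- sum((y - dH_i * g)^2)
      if (is.null(best) || sse < best$sse) {
        best <- list(N = grid$N[i], logKa = grid$logKa[i], dH = dH_i, sse = sse)
      }
    }
    start <- c(N = best$N, logKa = best$logKa, dH = best$dH)
  } else {
    stopifnot(inherits(init, "binding_parameters"))
    start <- c(N = init$N, logKa = log10(init$Ka), dH = init$dH)
  }

  resid_fn <- function(p) {
    if (p[["N"]] <= 0) return(rep(1e6, length(y)))
    y - model_heats(p[["N"]], 10^p[["logKa"]], p[["dH"]], experiment)
  }
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fn,
    lower = c(N = 1e-3, logKa = 0, dH = -Inf),
    upper = c(N = 10, logKa = 15, dH = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  converged <- fit$info %in% 1:4
  if (!converged) return(no_binding(paste("optimizer did not converge:", fit$message)))

  p <- fit$par
  est <- c(N = unname(p[["N"]]), Ka = unname(10^p[["logKa"]]), dH = unname(p[["dH"]]))
  dof <- length(y) - 3L
  sigma2 <- if (dof > 0) fit$deviance / dof else NA_real_
  se <- rep(NA_real_, 3)
  cov_log <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  if (!is.null(cov_log) && all(is.finite(diag(cov_log))) && all(diag(cov_log) >= 0)) {
    se_p <- sqrt(diag(cov_log))
    se <- c(se_p[["N"]], log(10) * est[["Ka"]] * se_p[["logKa"]], se_p[["dH"]])
  }
  names(se) <- c("N", "Ka", "dH")

  structure(list(
    binding_detected = TRUE, reason = NULL,
    estimate = est, se = se,
    se_logKa = if (!is.null(cov_log)) sqrt(cov_log[["logKa", "logKa"]]) else NA_real_,
    Kd_nM = kd_from_ka(est[["Ka"]]),
    dS_cal_mol_K = entropy_from_thermo(est[["dH"]], est[["Ka"]], temperature),
    residual_norm = sqrt(fit$deviance),
    df_residual = dof, converged = TRUE,
    data = isotherm, experiment = experiment, temperature = temperature
  ), class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  if (!x$binding_detected) {
    cat("One-site ITC fit: NO BINDING DETECTED (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat("One-site ITC fit\n")
  cat(sprintf("  N  = %.3g +/- %.2g\n", x$estimate[["N"]], x$se[["N"]]))
  cat(sprintf("  Ka = %.3g +/- %.2g M^-1\n", x$estimate[["Ka"]], x$se[["Ka"]]))
  cat(sprintf("  dH = %.3g +/- %.2g kcal/mol\n", x$estimate[["dH"]], x$se[["dH"]]))
  cat(sprintf("  Kd = %.3g nM, dS = %.3g cal/mol/K (T = %.2f K)\n",
              x$Kd_nM, x$dS_cal_mol_K, x$temperature))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_one_site
#' @param x,object an `itc_fit`.
#' @param ... unused.
#' @method tidy itc_fit
#' @export
tidy.itc_fit <- function(x, ...) {
  if (!x$binding_detected) return(tibble::tibble(
    term = character(), estimate = numeric(), std.error = numeric()))
  tibble::tibble(term = names(x$estimate),
                 estimate = unname(x$estimate),
                 std.error = unname(x$se[names(x$estimate)]))
}

#' @rdname fit_one_site
#' @method glance itc_fit
#' @export
glance.itc_fit <- function(x, ...) {
  tibble::tibble(
    binding_detected = x$binding_detected,
    converged = x$converged,
    residual.norm = x$residual_norm,
    df.residual = x$df_residual,
    Kd_nM = x$Kd_nM,
    dS_cal_mol_K = x$dS_cal_mol_K
  )
}

#' @rdname fit_one_site
#' @method autoplot itc_fit
#' @export
autoplot.itc_fit <- function(object, ...) {
  dat <- object$data
  p <- ggplot2::ggplot(dat[dat$used, ],
                       ggplot2::aes(x = .data$molar_ratio, y = .data$heat_kcal_per_mol)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "molar ratio (ligand / macromolecule)",
                  y = "heat (kcal per mol injectant)")
  if (object$binding_detected) {
    e <- object$estimate
    model <- simulate_isotherm(
      binding_parameters(e[["N"]], e[["Ka"]], e[["dH"]]), object$experiment)
    p <- p + ggplot2::geom_line(data = model[model$used, ], colour = "steelblue")
  }
  p
}

#' Binding entropy from enthalpy and association constant
#'
#' The thermodynamic identity `dS = (dH + R T ln Ka) / T` with
#' `R = 1.9872e-3` kcal/(mol K); the result is reported in cal/(mol K), the
#' unit conventionally printed alongside ITC fits.
#'
#' @param dH binding enthalpy, kcal/mol.
#' @param Ka association constant, per molar.
#' @param temperature kelvin.
#' @return Entropy in cal/(mol K).
#' @examples
#' entropy_from_thermo(-1.1, 4.2e6, 293.15) # ~26.6
#' @export
entropy_from_thermo <- function(dH, Ka, temperature = 293.15) {
  if (any(Ka <= 0)) stop("`Ka` must be positive", call. = FALSE)
  if (any(temperature <= 0)) stop("`temperature` must be positive", call. = FALSE)
  R <- 1.9872e-3 # kcal / (mol K)
  1000 * (dH + R * temperature * log(Ka)) / temperature
}

#' Dissociation constant in nanomolar from an association constant
#'
#' @param Ka association constant, per molar.
#' @return `1e9 / Ka`, nanomolar.
#' @examples
#' kd_from_ka(4.2e6) # ~238 nM
#' @export
kd_from_ka <- function(Ka) {
  if (any(Ka <= 0)) stop("`Ka` must be positive", call. = FALSE)
  1e9 / Ka
}

#' Write / read an isotherm as CSV
#'
#' Columns `injection_index, volume_ul, molar_ratio, heat_kcal_per_mol,
#' used`.
#'
#' @param isotherm an `itc_isotherm` tibble.
#' @param path file path.
#' @export
write_isotherm_csv <- function(isotherm, path) {
  utils::write.csv(as.data.frame(isotherm), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_isotherm_csv
#' @export
read_isotherm_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
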