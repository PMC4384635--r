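#' Initial rate of a coupled kinase assay time series
#'
#' Ordinary least-squares slope (with intercept) of the signal over the
#' early linear window of the progress curve — by default the first 150 s —
#' converted from per-second to per-minute. The intercept absorbs any
#' constant signal offset, so the estimate is offset-invariant.
#'
#' @param ts a data frame with columns `time_s` and `signal` (signal in
#'   turnover units; slope is reported in the same units per minute).
#' @param window length of the regression window in seconds.
#' @return A one-row tibble: `rate_per_min`, `se_per_min`, `n_points`,
#'   `window_s`.
#' @examples
#' ts <- tibble::tibble(time_s = 0:150, signal = 0.02 * (0:150))
#' initial_rate(ts) # 1.2 per minute
#' @export
initial_rate <- function(ts, window = 150) {
  stopifnot(is.data.frame(ts), all(c("time_s", "signal") %in% names(ts)))
  if (any(diff(ts$time_s) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  sel <- ts[ts$time_s <= window, ]
  if (nrow(sel) < 3) stop("need at least 3 points within the window", call. = FALSE)
  if (diff(range(sel$time_s)) == 0) stop("zero time span in window", call. = FALSE)
  fit <- stats::lm(signal ~ time_s, data = sel)
  sm <- summary(fit)$coefficients
  tibble::tibble(
    rate_per_min = sm["time_s", "Estimate"] * 60,
    se_per_min = sm["time_s", "Std. Error"] * 60,
    n_points = nrow(sel),
    window_s = window
  )
}

#' Activation-rate slope with a non-linearity caveat
#'
#' Activation time courses are only approximately linear early on; the
#' slope over a user-chosen early window is reported together with a flag
#' raised when adding a quadratic term significantly improves the fit
#' (partial F-test), marking the slope as a rough measure only.
#'
#' @param series a data frame with columns `time_s` and `activity`.
#' @param window optional window in seconds; default uses all points.
#' @param alpha significance level for the curvature test.
#' @return A one-row tibble: `slope`, `se`, `nonlinear` (logical),
#'   `p_curvature`, `n_points`.
#' @export
activation_slope <- function(series, window = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(series), all(c("time_s", "activity") %in% names(series)))
  sel <- if (is.null(window)) series else series[series$time_s <= window, ]
  if (nrow(sel) < 3) stop("need at least 3 time points", call. = FALSE)
  lin <- stats::lm(activity ~ time_s, data = sel)
  sm <- summary(lin)$coefficients
  p_curv <- NA_real_
  nonlinear <- FALSE
  if (nrow(sel) >= 4) {
    quad <- stats::lm(activity ~ time_s + I(time_s^2), data = sel)
    an <- stats::anova(lin, quad)
    p_curv <- an[["Pr(>F)"]][2]
    # exactly-linear data leaves the quadratic term undefined or the F-test
    # degenerate; only a finite significant p flags curvature
    nonlinear <- is.finite(p_curv) && p_curv < alpha
  }
  tibble::tibble(
    slope = sm["time_s", "Estimate"],
    se = sm["time_s", "Std. Error"],
    nonlinear = nonlinear,
    p_curvature = p_curv,
    n_points = nrow(sel)
  )
}

#' Fit the Michaelis-Menten rate law
#'
#' Nonlinear least squares on `v = Vmax * S / (Km + S)`, initialized from
#' the Hanes-Woolf linearization (`S/v` against `S`). Reports
#' local-curvature standard errors. Designs without curvature information —
#' fewer than two distinct positive substrate levels — are rejected as
#' unidentifiable.
#'
#' @param data a data frame with columns `substrate` (molar) and `rate`
#'   (per-minute turnover).
#' @return An object of class `mm_fit` with `estimate` (Vmax, Km), `se`,
#'   `residual_norm`, `df_residual`, `converged` and the data. Supports
#'   `tidy()`, `glance()` and `autoplot()`.
#' @examples
#' S <- c(1e-4, 3e-4, 9e-4, 2.7e-3)
#' d <- tibble::tibble(substrate = S, rate = 10 * S / (925e-6 + S))
#' fit_michaelis_menten(d)
#' @export
fit_michaelis_menten <- function(data) {
  stopifnot(is.data.frame(data), all(c("substrate", "rate") %in% names(data)))
  if (any(data$substrate < 0)) stop("substrate concentrations must be >= 0", call. = FALSE)
  pos <- data[data$substrate > 0 & data$rate > 0, ]
  if (length(unique(data$substrate)) < 2 || nrow(pos) < 2) {
    stop("Km unidentifiable: need at least two distinct positive substrate levels",
         call. = FALSE)
  }
  if (nrow(data) < 4) stop("need at least 4 substrate levels", call. = FALSE)
  # Hanes-Woolf: S/v = Km/Vmax + S/Vmax
  hw <- stats::lm(I(substrate / rate) ~ substrate, data = pos)
  vmax0 <- 1 / stats::coef(hw)[["substrate"]]
  km0 <- stats::coef(hw)[["(Intercept)"]] * vmax0
  if (!is.finite(vmax0) || vmax0 <= 0) vmax0 <- max(data$rate)
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(pos$substrate)
  fit <- minpack.lm::nls.lm(
    par = c(Vmax = vmax0, Km = km0),
    fn = function(p) data$rate - p[["Vmax"]] * data$substrate / (p[["Km"]] + data$substrate),
    lower = c(Vmax = 0, Km = 0),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-14)
  )
  converged <- fit$info %in% 1:4
  if (!converged) stop("Michaelis-Menten fit did not converge: ", fit$message, call. = FALSE)
  dof <- nrow(data) - 2L
  sigma2 <- if (dof > 0) fit$deviance / dof else NA_real_
  se <- tryCatch(sqrt(diag(sigma2 * solve(fit$hessian))),
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  structure(list(
    estimate = c(Vmax = fit$par[["Vmax"]], Km = fit$par[["Km"]]),
    se = c(Vmax = unname(se["Vmax"]), Km = unname(se["Km"])),
    residual_norm = sqrt(fit$deviance), df_residual = dof,
    converged = TRUE, data = tibble::as_tibble(data)
  ), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit\n")
  cat(sprintf("  Vmax = %.4g +/- %.2g per min\n", x$estimate[["Vmax"]], x$se[["Vmax"]]))
  cat(sprintf("  Km   = %.4g +/- %.2g M\n", x$estimate[["Km"]], x$se[["Km"]]))
  invisible(x)
}

#' @rdname fit_michaelis_menten
#' @param x,object an `mm_fit`.
#' @param ... unused.
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimate), estimate = unname(x$estimate),
                 std.error = unname(x$se))
}

#' @rdname fit_michaelis_menten
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(converged = x$converged, residual.norm = x$residual_norm,
                 df.residual = x$df_residual)
}

#' @rdname fit_michaelis_menten
#' @method autoplot mm_fit
#' @export
autoplot.mm_fit <- function(object, ...) {
  grid <- tibble::tibble(
    substrate = seq(0, max(object$data$substrate), length.out = 200))
  grid$rate <- object$estimate[["Vmax"]] * grid$substrate /
    (object$estimate[["Km"]] + grid$substrate)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$substrate, y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "substrate (M)", y = "rate (per min)")
}

# 4PL response at a dose vector; dose 0 anchors at the floor
logistic4 <- function(dose, floor, ceiling, log10_ec50, hill) {
  resp <- rep(floor, length(dose))
  pos <- dose > 0
  resp[pos] <- floor + (ceiling - floor) /
    (1 + 10^(hill * (log10_ec50 - log10(dose[pos]))))
  resp
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Logistic fit on log10 dose with floor, ceiling, EC50 and Hill slope as
#' free parameters. A zero dose is kept (as a floor anchor) rather than
#' log-transformed. The EC50 is scale- and offset-invariant in the
#' response: rescaling the readout only moves floor and ceiling.
#'
#' @param dr a data frame with columns `dose` (molar, >= 0, distinct) and
#'   `response`.
#' @return An object of class `ec50_fit` with `estimate` (`ec50` in molar,
#'   `hill`, `floor`, `ceiling`), `se`, `residual_norm`, `df_residual`,
#'   `converged`, `monotone_warning` and the data. Supports `tidy()`,
#'   `glance()` and `autoplot()`.
#' @export
fit_ec50 <- function(dr) {
  stopifnot(is.data.frame(dr), all(c("dose", "response") %in% names(dr)))
  if (any(dr$dose < 0)) stop("doses must be non-negative", call. = FALSE)
  if (anyDuplicated(dr$dose)) stop("doses must be distinct", call. = FALSE)
  if (nrow(dr) < 5) stop("need at least 5 doses", call. = FALSE)
  dr <- dr[order(dr$dose), ]
  rng <- diff(range(dr$response))
  if (rng <= 0) stop("response has no dynamic range; EC50 unidentifiable", call. = FALSE)
  # rough monotonicity check beyond noise: count large downward steps
  steps <- diff(dr$response)
  monotone_warning <- any(steps < -0.25 * rng)
  if (monotone_warning) {
    warning("dose-response is non-monotone beyond noise level", call. = FALSE)
  }
  half <- min(dr$response) + rng / 2
  pos <- dr$dose > 0
  above <- which(dr$response >= half & pos)
  ec50_0 <- if (length(above)) dr$dose[above[1]] else stats::median(dr$dose[pos])
  start <- c(floor = min(dr$response), ceiling = max(dr$response),
             log10_ec50 = log10(ec50_0), hill = 1)
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) dr$response - logistic4(dr$dose, p[["floor"]], p[["ceiling"]],
                                             p[["log10_ec50"]], p[["hill"]]),
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-14, ptol = 1e-14)
  )
  if (!fit$info %in% 1:4) {
    stop("EC50 fit did not converge (plateau may be unidentifiable): ",
         fit$message, call. = FALSE)
  }
  p <- fit$par
  if (p[["log10_ec50"]] > log10(max(dr$dose)) + 1) {
    stop("EC50 beyond tested dose range: plateau unidentifiable", call. = FALSE)
  }
  dof <- nrow(dr) - 4L
  sigma2 <- if (dof > 0) fit$deviance / dof else NA_real_
  se_p <- tryCatch(sqrt(diag(sigma2 * solve(fit$hessian))),
                   error = function(e) stats::setNames(rep(NA_real_, 4), names(start)))
  ec50 <- 10^p[["log10_ec50"]]
  structure(list(
    estimate = c(ec50 = ec50, hill = p[["hill"]],
                 floor = p[["floor"]], ceiling = p[["ceiling"]]),
    se = c(ec50 = log(10) * ec50 * unname(se_p["log10_ec50"]),
           hill = unname(se_p["hill"]),
           floor = unname(se_p["floor"]), ceiling = unname(se_p["ceiling"])),
    se_log10_ec50 = unname(se_p["log10_ec50"]),
    residual_norm = sqrt(fit$deviance), df_residual = dof,
    converged = TRUE, monotone_warning = monotone_warning,
    data = tibble::as_tibble(dr)
  ), class = "ec50_fit")
}

#' @export
print.ec50_fit <- function(x, ...) {
  cat("Four-parameter logistic dose-response fit\n")
  cat(sprintf("  EC50 = %.3g M (+/- %.2g)\n", x$estimate[["ec50"]], x$se[["ec50"]]))
  cat(sprintf("  Hill = %.3g, floor = %.3g, ceiling = %.3g\n",
              x$estimate[["hill"]], x$estimate[["floor"]], x$estimate[["ceiling"]]))
  invisible(x)
}

#' @rdname fit_ec50
#' @param x,object an `ec50_fit`.
#' @param ... unused.
#' @method tidy ec50_fit
#' @export
tidy.ec50_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimate), estimate = unname(x$estimate),
                 std.error = unname(x$se))
}

#' @rdname fit_ec50
#' @method glance ec50_fit
#' @export
glance.ec50_fit <- function(x, ...) {
  tibble::tibble(converged = x$converged, residual.norm = x$residual_norm,
                 df.residual = x$df_residual,
                 monotone_warning = x$monotone_warning)
}

#' @rdname fit_ec50
#' @method autoplot ec50_fit
#' @export
autoplot.ec50_fit <- function(object, ...) {
  d <- object$data
  pos <- d[d$dose > 0, ]
  e <- object$estimate
  grid <- tibble::tibble(dose = 10^seq(log10(min(pos$dose)), log10(max(pos$dose)),
                                       length.out = 200))
  grid$response <- logistic4(grid$dose, e[["floor"]], e[["ceiling"]],
                             log10(e[["ec50"]]), e[["hill"]])
  ggplot2::ggplot(pos, ggplot2::aes(x = .data$dose, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (M)", y = "response")
}
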