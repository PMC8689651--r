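# Macromolecular rate theory (MMRT): transition state theory with a
# ground-to-transition-state heat capacity difference dCp, which makes
# the activation enthalpy and entropy temperature dependent:
#   ln k = ln(kappa*kB*T/h) - [dH_T0 + dCp*(T - T0)]/(R*T)
#                           + [dS_T0 + dCp*ln(T/T0)]/R
# Energies are kJ mol^-1 (kJ mol^-1 K^-1 for dS, dCp); rates s^-1.

#' MMRT parameter set
#'
#' @param dH_T0 activation enthalpy at the reference temperature, kJ mol^-1
#' @param dS_T0 activation entropy at the reference temperature,
#'   kJ mol^-1 K^-1
#' @param dCp heat capacity of activation, kJ mol^-1 K^-1 (negative values
#'   produce a rate optimum)
#' @param T0 reference temperature, kelvin
#' @param transmission dimensionless prefactor scale kappa (default 1)
#' @return list of class `mmrt_params`
#' @export
mmrt_params <- function(dH_T0, dS_T0, dCp, T0 = 348, transmission = 1) {
  .check_finite(c(dH_T0, dS_T0, dCp, T0, transmission), "MMRT parameters")
  if (T0 <= 0) .stopf("T0 must be positive kelvin")
  structure(list(dH_T0 = dH_T0, dS_T0 = dS_T0, dCp = dCp, T0 = T0,
                 transmission = transmission),
            class = "mmrt_params")
}

#' Evaluate the MMRT model: ln k as a function of temperature
#'
#' @param params an `mmrt_params` (or a list with the same fields)
#' @param T temperature, kelvin, positive
#' @return ln of the rate in s^-1 at each `T`
#' @export
#' @examples
#' p <- mmrt_params(dH_T0 = 50, dS_T0 = 0, dCp = 0, T0 = 300)
#' mmrt_ln_rate(p, 300)   # ln(kB*300/h) - 50000/(R*300)
mmrt_ln_rate <- function(params, T) {
  if (any(T <= 0)) .stopf("temperatures must be positive kelvin")
  dH <- params$dH_T0 * 1000; dS <- params$dS_T0 * 1000
  dCp <- params$dCp * 1000; T0 <- params$T0
  kappa <- if (is.null(params$transmission)) 1 else params$transmission
  log(kappa * .kB * T / .h) -
    (dH + dCp * (T - T0)) / (.Rgas * T) +
    (dS + dCp * log(T / T0)) / .Rgas
}

#' Fit the MMRT model to a temperature-rate series
#'
#' The fit target is `y = ln k - ln(kB*T/h)`, which is exactly linear in
#' the basis \{1, 1/T, ln T\}:
#' `y = a + b/T + c*ln(T)` with `dCp = R*c`, `dH_T0 = R*(T0*c - b)` and
#' `dS_T0 = R*a + dCp*(1 + ln T0)`. The fit is therefore solved in closed
#' form by (optionally weighted) linear least squares and mapped back to
#' the thermodynamic parameters at the requested `T0`, with the covariance
#' propagated exactly through the linear map. Fits with different `T0`
#' give identical dCp and identical predicted ln k everywhere.
#'
#' @param series a `temperature_rate_series` (at least 5 points)
#' @param T0 reference temperature, kelvin, at which dH and dS are reported
#' @param weighting "none" (default; multiplicative rate noise is
#'   homoscedastic in ln k) or "se" for inverse-variance weights built
#'   from the series' rate standard errors
#' @return object of class `mmrt_fit` with `params` (an `mmrt_params`),
#'   `vcov` (3x3 over dH_T0, dS_T0, dCp in kJ units), `se`,
#'   `residual_rms` (in ln k), `n`, `data`
#' @export
fit_mmrt <- function(series, T0 = 348, weighting = c("none", "se")) {
  stopifnot(inherits(series, "temperature_rate_series"))
  weighting <- match.arg(weighting)
  T <- series$temperature; k <- series$rate
  if (length(T) < 5) .stopf("MMRT fit needs at least 5 points, got %d", length(T))
  if (length(unique(T)) < 3) .stopf("rank-deficient design: <3 distinct temperatures")
  y <- log(k) - log(.kB * T / .h)
  X <- cbind(1, 1 / T, log(T))
  w <- if (weighting == "se") {
    if (is.null(series$rate_se)) .stopf("weighting='se' but series has no rate_se")
    1 / (series$rate_se / k)^2
  } else rep(1, length(T))
  fit <- stats::lm.wfit(X, y, w)
  beta <- fit$coefficients
  if (anyNA(beta)) .stopf("rank-deficient design")
  rss <- sum(w * fit$residuals^2)
  dof <- length(T) - 3
  XtWX <- crossprod(X * sqrt(w))
  cov_beta <- solve(XtWX) * rss / dof
  # map (a, b, c) -> (dH_T0, dS_T0, dCp), in kJ
  Rk <- .Rgas / 1000
  M <- rbind(dH_T0 = c(0, -Rk, Rk * T0),
             dS_T0 = c(Rk, 0, Rk * (1 + log(T0))),
             dCp   = c(0, 0, Rk))
  theta <- drop(M %*% beta)
  vc <- M %*% cov_beta %*% t(M)
  dimnames(vc) <- list(names(theta), names(theta))
  params <- mmrt_params(theta[["dH_T0"]], theta[["dS_T0"]], theta[["dCp"]],
                        T0 = T0)
  structure(list(params = params,
                 coefficients = theta,
                 vcov = vc,
                 se = sqrt(pmax(diag(vc), 0)),
                 residual_rms = sqrt(sum(fit$residuals^2) / length(T)),
                 rss = rss, n = length(T), weighting = weighting,
                 data = series),
            class = "mmrt_fit")
}

#' @export
print.mmrt_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("MMRT fit (n = %d, T0 = %g K)\n", x$n, p$T0))
  tab <- rbind(estimate = x$coefficients, se = x$se)
  colnames(tab) <- c("dH_T0 (kJ/mol)", "dS_T0 (kJ/mol/K)", "dCp (kJ/mol/K)")
  print(round(tab, 4))
  cat(sprintf("residual RMS in ln k: %.4g\n", x$residual_rms))
  invisible(x)
}

#' @export
summary.mmrt_fit <- function(object, ...) {
  out <- list(fit = object,
              profile = thermo_profile(object$params,
                                       range(object$data$temperature)))
  class(out) <- "summary.mmrt_fit"
  out
}

#' @export
print.summary.mmrt_fit <- function(x, ...) {
  print(x$fit)
  cat("\nActivation thermodynamics at the data range edges:\n")
  print(round(as.data.frame(x$profile), 4))
  invisible(x)
}

#' @export
coef.mmrt_fit <- function(object, ...) object$coefficients

#' @export
vcov.mmrt_fit <- function(object, ...) object$vcov

#' @export
predict.mmrt_fit <- function(object, T = NULL, type = c("lnk", "k"), ...) {
  type <- match.arg(type)
  if (is.null(T)) T <- object$data$temperature
  lnk <- mmrt_ln_rate(object$params, T)
  if (type == "k") exp(lnk) else lnk
}

#' @export
residuals.mmrt_fit <- function(object, ...) {
  log(object$data$rate) - predict(object)
}

#' @export
plot.mmrt_fit <- function(x, n_grid = 200, ...) {
  T <- x$data$temperature
  grid <- seq(min(T), max(T), length.out = n_grid)
  plot(T, log(x$data$rate), xlab = "T (K)", ylab = "ln k",
       main = "MMRT fit", ...)
  graphics::lines(grid, mmrt_ln_rate(x$params, grid), col = "red")
  invisible(x)
}

#' Temperature-dependent activation thermodynamics from MMRT parameters
#'
#' `dH(T) = dH_T0 + dCp*(T - T0)`, `dS(T) = dS_T0 + dCp*ln(T/T0)`,
#' `dG(T) = dH(T) - T*dS(T)` (exact identity, same units as the inputs).
#'
#' @param params an `mmrt_params`
#' @param T temperature grid, kelvin
#' @return data frame of class `thermo_profile` with columns
#'   `temperature`, `dH`, `dS`, `dG`
#' @export
thermo_profile <- function(params, T) {
  if (any(T <= 0)) .stopf("temperatures must be positive kelvin")
  dH <- params$dH_T0 + params$dCp * (T - params$T0)
  dS <- params$dS_T0 + params$dCp * log(T / params$T0)
  out <- data.frame(temperature = T, dH = dH, dS = dS, dG = dH - T * dS)
  class(out) <- c("thermo_profile", "data.frame")
  out
}

#' Temperature at which an MMRT rate curve peaks
#'
#' For sufficiently negative `dCp` the MMRT ln k curve has a unique
#' interior maximum. In the linear basis,
#' `ln k = ln(kB*T/h) + a + b/T + c*ln(T)`, stationarity gives
#' `1/T - b/T^2 + c/T = 0`, i.e. `T_opt = b/(1 + c)`. Solved analytically
#' here.
#'
#' @param params an `mmrt_params` with negative dCp
#' @return optimum temperature, kelvin
#' @export
mmrt_t_opt <- function(params) {
  dCp <- params$dCp * 1000; dH <- params$dH_T0 * 1000
  if (dCp >= 0) .stopf("an interior rate optimum requires dCp < 0")
  b <- (-dH + dCp * params$T0) / .Rgas
  c_ <- dCp / .Rgas
  T_opt <- b / (1 + c_)
  if (T_opt <= 0) .stopf("no positive optimum for these parameters")
  T_opt
}

#' Kinetic isotope effect profile from paired MMRT fits
#'
#' Fits the protiated and deuterated series independently with
#' [fit_mmrt()] and forms `KIE(T) = exp(ln k_H(T) - ln k_D(T))` on a
#' temperature grid. The isotope effect on the heat capacity of
#' activation is `ddCp = dCp(D) - dCp(H)`, with its standard error from
#' the two fit SEs in quadrature (the fits are independent).
#'
#' @param series_H protiated `temperature_rate_series`
#' @param series_D deuterated series for the same substrate (labels must
#'   match)
#' @param T0 reference temperature for both fits, kelvin
#' @param T_grid temperature grid for the KIE curve; defaults to 100
#'   points spanning the union of the two series
#' @return object of class `kie_profile` with `T_grid`, `kie`, `ddCp`,
#'   `ddCp_se`, `minus_ddCp` (the same number with the sign flipped, as
#'   isotope effects on dCp are often quoted as -ddCp), and the two fits
#' @export
fit_kie_pair <- function(series_H, series_D, T0 = 348, T_grid = NULL) {
  sub_H <- attr(series_H, "substrate"); sub_D <- attr(series_D, "substrate")
  if (!identical(sub_H, sub_D))
    .stopf("substrate labels differ: '%s' vs '%s'", sub_H, sub_D)
  fit_H <- fit_mmrt(series_H, T0 = T0)
  fit_D <- fit_mmrt(series_D, T0 = T0)
  if (is.null(T_grid)) {
    rng <- range(c(series_H$temperature, series_D$temperature))
    T_grid <- seq(rng[1], rng[2], length.out = 100)
  }
  kie <- exp(mmrt_ln_rate(fit_H$params, T_grid) -
               mmrt_ln_rate(fit_D$params, T_grid))
  ddCp <- fit_D$params$dCp - fit_H$params$dCp
  ddCp_se <- sqrt(fit_H$se[["dCp"]]^2 + fit_D$se[["dCp"]]^2)
  structure(list(T_grid = T_grid, kie = kie,
                 ddCp = ddCp, ddCp_se = ddCp_se, minus_ddCp = -ddCp,
                 fit_H = fit_H, fit_D = fit_D, substrate = sub_H),
            class = "kie_profile")
}

#' @export
print.kie_profile <- function(x, ...) {
  cat(sprintf("KIE profile%s: %d grid points, KIE range %.3f-%.3f\n",
              if (nzchar(x$substrate)) paste0(" (", x$substrate, ")") else "",
              length(x$T_grid), min(x$kie), max(x$kie)))
  cat(sprintf("ddCp = dCp(D) - dCp(H) = %.3f +/- %.3f kJ/mol/K (-ddCp = %.3f)\n",
              x$ddCp, x$ddCp_se, x$minus_ddCp))
  invisible(x)
}

#' @export
predict.kie_profile <- function(object, T, ...) {
  exp(mmrt_ln_rate(object$fit_H$params, T) -
        mmrt_ln_rate(object$fit_D$params, T))
}

#' Residual-resampling bootstrap confidence intervals for an MMRT fit
#'
#' Resamples the ln k residuals with replacement, adds them back onto the
#' fitted curve, refits, and reports 2.5/97.5 percentile intervals for
#' (dH_T0, dS_T0, dCp). Deterministic given `seed`.
#'
#' @param fit an `mmrt_fit`
#' @param n_boot number of bootstrap replicates (at least 100)
#' @param seed integer seed
#' @return list with `ci` (3 x 2 matrix of percentiles), `draws`
#'   (n_boot x 3), `n_boot`, `seed`
#' @export
bootstrap_ci <- function(fit, n_boot = 1000, seed = 1) {
  stopifnot(inherits(fit, "mmrt_fit"), n_boot >= 100)
  res <- residuals(fit)
  fitted_lnk <- predict(fit)
  T <- fit$data$temperature
  if (all(abs(res) < 1e-12)) {
    .warnf("degenerate residuals (all ~zero): returning zero-width CIs")
    ci <- cbind(`2.5%` = fit$coefficients, `97.5%` = fit$coefficients)
    return(list(ci = ci, draws = NULL, n_boot = n_boot, seed = seed))
  }
  draws <- matrix(NA_real_, n_boot, 3,
                  dimnames = list(NULL, c("dH_T0", "dS_T0", "dCp")))
  for (b in seq_len(n_boot)) {
    set.seed(.split_seed(seed, b))
    lnk_b <- fitted_lnk + sample(res, length(res), replace = TRUE)
    ser_b <- temperature_rate_series(T, exp(lnk_b))
    draws[b, ] <- fit_mmrt(ser_b, T0 = fit$params$T0)$coefficients
  }
  ci <- t(apply(draws, 2, stats::quantile, probs = c(0.025, 0.975)))
  list(ci = ci, draws = draws, n_boot = n_boot, seed = seed)
}
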