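# Michaelis-Menten fitting, with the uncompetitive single-Ki substrate
# inhibition form v = Vmax*S / (K_M + S + S^2/K_i) where needed.

#' Evaluate the Michaelis-Menten rate law
#'
#' Without inhibition `Vmax*S/(K_M + S)`; with a finite `Ki`,
#' `Vmax*S/(K_M + S + S^2/Ki)` (uncompetitive substrate inhibition).
#' With inhibition the rate has a unique interior maximum at
#' `S* = sqrt(K_M * Ki)`.
#'
#' @param S substrate concentration, mM, non-negative
#' @param Vmax maximal rate
#' @param Km Michaelis constant, mM, positive
#' @param Ki substrate-inhibition constant, mM, positive, or NULL for the
#'   plain hyperbola
#' @return rate at each `S`
#' @export
#' @examples
#' eval_michaelis(2, Vmax = 10, Km = 2)   # Vmax/2 at S = Km
eval_michaelis <- function(S, Vmax, Km, Ki = NULL) {
  if (any(S < 0)) .stopf("substrate concentrations must be non-negative")
  if (Vmax <= 0 || Km <= 0) .stopf("Vmax and Km must be positive")
  denom <- Km + S
  if (!is.null(Ki)) {
    if (Ki <= 0) .stopf("Ki must be positive")
    denom <- denom + S^2 / Ki
  }
  Vmax * S / denom
}

.fit_mm_form <- function(S, v, with_ki) {
  Vmax0 <- max(v) * 1.2
  Km0 <- max(S[which.min(abs(v - max(v) / 2))], min(S[S > 0]))
  ki_grid <- if (with_ki) c(max(S) * c(0.1, 0.5, 2, 10)) else NA
  best <- NULL
  for (ki0 in ki_grid) {
    par0 <- c(Vmax = Vmax0, Km = Km0, if (with_ki) c(Ki = ki0))
    fn <- function(par) {
      v - eval_michaelis(S, par["Vmax"], par["Km"],
                         if (with_ki) par["Ki"] else NULL)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = rep(1e-10, length(par0)),
                         fn = fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:4) {
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  best
}

#' Fit rate-concentration data to the Michaelis-Menten model
#'
#' Nonlinear least squares with multi-start initialisation. With
#' `inhibition = "auto"` both the plain hyperbola and the substrate
#' inhibition form are fitted and the inhibition form is kept only when
#' it wins on small-sample corrected AIC and its K_i is identifiable
#' (below `1e4 * K_M`). `k_cat = Vmax / enzyme_conc` when an enzyme
#' concentration is available (per-monomer active sites by default; the
#' caller controls the convention through the concentration it supplies).
#'
#' @param series a `rate_conc_series`
#' @param inhibition "auto", "on" or "off"
#' @param enzyme_conc enzyme concentration used to convert Vmax to k_cat;
#'   defaults to the series attribute
#' @return object of class `mm_fit` with `coefficients` (Vmax, Km,
#'   optionally Ki), `se`, `vcov`, `kcat`, `kcat_se`, `residual_rms`
#' @export
fit_michaelis <- function(series, inhibition = c("auto", "on", "off"),
                          enzyme_conc = NULL) {
  stopifnot(inherits(series, "rate_conc_series"))
  inhibition <- match.arg(inhibition)
  S <- series$conc; v <- series$rate
  n_distinct <- length(unique(S))
  need <- if (inhibition == "on") 6 else 5
  if (n_distinct < need)
    .stopf("need at least %d distinct concentrations, got %d", need, n_distinct)
  if (is.null(enzyme_conc)) enzyme_conc <- attr(series, "enzyme_conc")

  fit_plain <- if (inhibition != "on") .fit_mm_form(S, v, FALSE) else NULL
  fit_inhib <- if (inhibition != "off" && n_distinct >= 6)
    .fit_mm_form(S, v, TRUE) else NULL
  if (is.null(fit_plain) && is.null(fit_inhib))
    .stopf("Michaelis-Menten fit did not converge")

  pick_inhib <- switch(inhibition,
    off = FALSE,
    on = { if (is.null(fit_inhib)) .stopf("substrate-inhibition fit failed"); TRUE },
    auto = {
      if (is.null(fit_inhib)) FALSE
      else if (is.null(fit_plain)) TRUE
      else {
        a_p <- aicc(fit_plain$rss, length(v), 2)
        a_i <- aicc(fit_inhib$rss, length(v), 3)
        ki_hat <- fit_inhib$fit$par["Ki"]
        a_i < a_p && ki_hat < 1e4 * fit_inhib$fit$par["Km"]
      }
    })
  chosen <- if (pick_inhib) fit_inhib else fit_plain
  fit <- chosen$fit
  par <- fit$par
  rss <- chosen$rss
  dof <- length(v) - length(par)
  vc <- tryCatch(solve(fit$hessian) * rss / dof,
                 error = function(e) matrix(NA_real_, length(par), length(par)))
  dimnames(vc) <- list(names(par), names(par))
  se <- sqrt(pmax(diag(vc), 0))

  kcat <- kcat_se <- NA_real_
  if (is.finite(enzyme_conc) && enzyme_conc > 0) {
    kcat <- unname(par["Vmax"]) / enzyme_conc
    kcat_se <- unname(se["Vmax"]) / enzyme_conc
  }
  structure(list(coefficients = par, se = se, vcov = vc,
                 inhibition = pick_inhib,
                 kcat = kcat, kcat_se = kcat_se,
                 enzyme_conc = enzyme_conc,
                 residual_rms = sqrt(rss / length(v)), rss = rss,
                 n = length(v),
                 aicc = aicc(rss, length(v), length(par)),
                 data = series),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit",
      if (x$inhibition) "with substrate inhibition", "\n")
  print(round(rbind(estimate = x$coefficients, se = x$se), 5))
  if (is.finite(x$kcat))
    cat(sprintf("kcat: %.5g +/- %.3g (Vmax / enzyme conc %.3g)\n",
                x$kcat, x$kcat_se, x$enzyme_conc))
  if (x$inhibition) {
    cf <- x$coefficients
    cat(sprintf("rate optimum at S* = sqrt(Km*Ki) = %.4g mM\n",
                sqrt(cf["Km"] * cf["Ki"])))
  }
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) object$coefficients

#' @export
vcov.mm_fit <- function(object, ...) object$vcov

#' @export
predict.mm_fit <- function(object, S = NULL, ...) {
  if (is.null(S)) S <- object$data$conc
  cf <- object$coefficients
  eval_michaelis(S, cf["Vmax"], cf["Km"],
                 if (object$inhibition) cf["Ki"] else NULL)
}

#' Assemble per-temperature kcat fits into a temperature-rate series
#'
#' @param fits list of `mm_fit` objects, each fitted at one temperature
#'   (taken from the temperature attribute of each fit's data)
#' @param substrate substrate label for the assembled series
#' @param isotopologue isotopologue label
#' @return a `temperature_rate_series` of (T, kcat) sorted by temperature,
#'   with the per-fit kcat standard errors carried through unchanged
#' @export
build_temperature_series <- function(fits, substrate = "", isotopologue = "H") {
  stopifnot(all(vapply(fits, inherits, logical(1), "mm_fit")))
  temps <- vapply(fits, function(f) attr(f$data, "temperature"), numeric(1))
  if (anyNA(temps)) .stopf("every fit needs a temperature attribute")
  if (anyDuplicated(temps)) .stopf("duplicate temperatures")
  if (length(fits) < 5)
    .stopf("need at least 5 temperatures, got %d", length(fits))
  kcat <- vapply(fits, function(f) f$kcat, numeric(1))
  if (anyNA(kcat)) .stopf("every fit needs a kcat (supply enzyme_conc)")
  temperature_rate_series(temps, kcat,
                          rate_se = vapply(fits, function(f) f$kcat_se,
                                           numeric(1)),
                          substrate = substrate, isotopologue = isotopologue)
}
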