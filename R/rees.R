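# Red edge excitation shift (REES) quantification. Each excitation row of
# an excitation-emission matrix is collapsed to its center of spectral
# mass (CSM), the intensity-weighted mean emission wavelength; the CSM
# versus excitation curve is then summarised by an exponential
# ("QUBES"): CSM(lEx) = CSM0 + A * exp(R * dlEx), with dlEx the shift of
# the excitation wavelength above the bluest excitation used. A/R serves
# as a single flexibility metric: for an invariant CSM0, a larger A/R
# reports a broader equilibrium of emissive (conformational) states.

#' Center of spectral mass of an emission spectrum
#'
#' `CSM = sum(f_i * lambda_i) / sum(f_i)` over the emission range. The
#' result is invariant to uniform intensity scaling and always lies
#' within the emission wavelength range.
#'
#' @param emission emission wavelengths, nm
#' @param intensity fluorescence intensities (same length)
#' @param baseline if TRUE, subtract a constant baseline estimated as the
#'   mean intensity of the `baseline_n` reddest emission points
#' @param baseline_n number of red-edge points used for the baseline
#' @return CSM in nm
#' @export
#' @examples
#' compute_csm(c(340, 360), c(1, 1))  # 350
compute_csm <- function(emission, intensity, baseline = FALSE,
                        baseline_n = 10) {
  stopifnot(length(emission) == length(intensity))
  if (baseline) {
    n <- min(baseline_n, length(intensity))
    red <- order(emission, decreasing = TRUE)[seq_len(n)]
    intensity <- intensity - mean(intensity[red])
    intensity[intensity < 0] <- 0
  }
  tot <- sum(intensity)
  if (!is.finite(tot) || tot <= 0)
    .stopf("nonpositive total intensity")
  csm <- sum(intensity * emission) / tot
  stopifnot(csm >= min(emission), csm <= max(emission))
  csm
}

#' CSM versus excitation wavelength from an excitation-emission matrix
#'
#' @param x an `eem`
#' @param baseline,baseline_n passed to [compute_csm()]
#' @return data frame of class `csm_curve` with columns `excitation`,
#'   `csm` (excitation order preserved)
#' @export
csm_curve <- function(x, baseline = FALSE, baseline_n = 10) {
  stopifnot(inherits(x, "eem"))
  csm <- vapply(seq_along(x$excitation), function(i) {
    tryCatch(compute_csm(x$emission, x$intensity[i, ], baseline, baseline_n),
             error = function(e)
               .stopf("CSM failed at excitation %g nm: %s",
                      x$excitation[i], conditionMessage(e)))
  }, numeric(1))
  out <- data.frame(excitation = x$excitation, csm = csm)
  attr(out, "label") <- x$label
  class(out) <- c("csm_curve", "data.frame")
  out
}

#' Fit the QUBES exponential to a CSM curve
#'
#' Model: `CSM(lEx) = CSM0 + A * exp(R * dlEx)` with
#' `dlEx = lEx - min(lEx)`, so `A` is the amplitude above CSM0 at the
#' bluest excitation and `R > 0` the red-edge curvature. Fitted by
#' Levenberg-Marquardt with multi-start over R. A curve whose variance is
#' below `flat_tol^2` is reported as flat: `A = 0`, `CSM0 = mean(csm)`,
#' R unidentifiable.
#'
#' @param curve a `csm_curve` (at least 6 excitation points)
#' @param flat_tol SD threshold (nm) below which the curve is treated as
#'   flat
#' @return object of class `qubes_fit` with `coefficients` (csm0, A, R),
#'   `se`, `AR` (= A/R, nm^2), `AR_se` (delta method), `residual_rms`,
#'   `flat` flag
#' @export
fit_qubes <- function(curve, flat_tol = 1e-6) {
  stopifnot(inherits(curve, "csm_curve"))
  lex <- curve$excitation; csm <- curve$csm
  if (length(lex) < 6) .stopf("QUBES fit needs at least 6 points, got %d",
                              length(lex))
  dl <- lex - min(lex)
  if (stats::sd(csm) < flat_tol) {
    cf <- c(csm0 = mean(csm), A = 0, R = NA_real_)
    return(structure(list(coefficients = cf,
                          se = c(csm0 = 0, A = 0, R = NA_real_),
                          vcov = NULL, AR = NA_real_, AR_se = NA_real_,
                          residual_rms = stats::sd(csm), flat = TRUE,
                          data = curve),
                     class = "qubes_fit"))
  }
  span <- max(dl)
  best <- NULL
  for (R0 in c(0.02, 0.05, 0.1, 0.2, 0.5, 1) / (span / 18)) {
    # linear solve for (csm0, A) given R, then refine all three
    X <- cbind(1, exp(R0 * dl))
    lf <- stats::lm.fit(X, csm)
    par0 <- c(csm0 = unname(lf$coefficients[1]), A = unname(lf$coefficients[2]),
              R = R0)
    fn <- function(par) csm - (par["csm0"] + par["A"] * exp(par["R"] * dl))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0,
                         lower = c(-Inf, -Inf, 1e-6),
                         upper = c(Inf, Inf, 5),
                         fn = fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:4) {
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) .stopf("QUBES fit did not converge")
  fit <- best$fit
  cf <- fit$par
  dof <- length(csm) - 3
  vc <- tryCatch(solve(fit$hessian) * best$rss / dof,
                 error = function(e) matrix(NA_real_, 3, 3))
  dimnames(vc) <- list(names(cf), names(cf))
  se <- sqrt(pmax(diag(vc), 0))
  AR <- unname(cf["A"] / cf["R"])
  # delta method: var(A/R) = (1/R)^2 varA + (A/R^2)^2 varR - 2*(A/R^3) covAR
  AR_se <- if (all(is.finite(vc[2:3, 2:3]))) {
    g <- c(1 / cf["R"], -cf["A"] / cf["R"]^2)
    sqrt(max(drop(t(g) %*% vc[c("A", "R"), c("A", "R")] %*% g), 0))
  } else NA_real_
  structure(list(coefficients = cf, se = se, vcov = vc,
                 AR = AR, AR_se = AR_se,
                 residual_rms = sqrt(best$rss / length(csm)),
                 flat = FALSE, data = curve),
            class = "qubes_fit")
}

#' @export
print.qubes_fit <- function(x, ...) {
  if (x$flat) {
    cat(sprintf("QUBES fit: flat curve, CSM0 = %.3f nm, A = 0, R unidentifiable\n",
                x$coefficients["csm0"]))
    return(invisible(x))
  }
  print(round(rbind(estimate = x$coefficients, se = x$se), 5))
  cat(sprintf("A/R = %.4g +/- %.3g nm^2 (larger A/R is reported as less rigid)\n",
              x$AR, x$AR_se))
  invisible(x)
}

#' @export
coef.qubes_fit <- function(object, ...) object$coefficients

#' @export
predict.qubes_fit <- function(object, excitation = NULL, ...) {
  if (is.null(excitation)) excitation <- object$data$excitation
  dl <- excitation - min(object$data$excitation)
  cf <- object$coefficients
  if (object$flat) return(rep(unname(cf["csm0"]), length(excitation)))
  unname(cf["csm0"] + cf["A"] * exp(cf["R"] * dl))
}
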