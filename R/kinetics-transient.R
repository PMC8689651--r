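# Stopped-flow transient fitting: sum of (optionally stretched)
# exponentials, offset + sum_i A_i * exp(-(k_i * t)^b_i).
# The stretch exponent b applies inside the power so k_i keeps units of
# s^-1 for any b; b = 1 is a pure exponential.

#' Evaluate a multi-exponential (optionally stretched) transient model
#'
#' Computes `offset + sum_i A_i * exp(-(k_i * t)^b_i)`.
#'
#' @param t time, seconds, non-negative
#' @param A per-phase amplitudes, AU
#' @param k per-phase rate constants, s^-1, positive
#' @param b per-phase stretch exponents (recycled), in (0, 1.5]; 1 is a
#'   pure exponential
#' @param offset baseline absorbance, AU
#' @return model absorbance at each `t`
#' @export
#' @examples
#' eval_transient(0, A = 1, k = 1)          # 1
#' eval_transient(2, A = 2, k = 0.5, b = 0.8, offset = 0.1)
eval_transient <- function(t, A, k, b = 1, offset = 0) {
  .check_finite(c(A, k, b, offset), "transient parameters")
  if (any(t < 0)) .stopf("t must be non-negative")
  if (any(k <= 0)) .stopf("rate constants must be positive")
  if (length(b) == 1) b <- rep(b, length(A))
  if (any(b <= 0 | b > 1.5)) .stopf("stretch b must lie in (0, 1.5]")
  out <- rep(offset, length(t))
  for (i in seq_along(A)) out <- out + A[i] * exp(-(k[i] * t)^b[i])
  out
}

# linear solve of amplitudes + offset given fixed (k, b); returns rss and
# coefficients -- used to build good multi-start initial values
.transient_linfit <- function(time, y, k, b) {
  X <- cbind(1, vapply(seq_along(k),
                       function(i) exp(-(k[i] * time)^b[i]),
                       numeric(length(time))))
  fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(offset = fit$coefficients[1], A = fit$coefficients[-1],
       rss = sum(fit$residuals^2))
}

#' Fit a stopped-flow transient to a sum of exponentials
#'
#' Least-squares fit of `offset + sum_i A_i exp(-(k_i t)^b_i)` with one or
#' two phases. Initialisation is multi-start: rate guesses are log-spaced
#' over the observed time window (8 per phase by default), amplitudes and
#' offset are solved linearly for each guess, and the best start is
#' refined by Levenberg-Marquardt. Phases in the result are ordered by
#' decreasing amplitude fraction (ties broken by descending rate).
#'
#' @param transient an `absorbance_transient`
#' @param n_phases 1 or 2
#' @param allow_stretch if TRUE the stretch exponents b_i are fitted
#'   (bounded in (0, 1.5]); if FALSE they are fixed at 1
#' @param n_starts number of log-spaced rate guesses per phase
#' @param seed optional seed for jitter on the start grid (jitter is off
#'   when NULL, making the fit fully deterministic)
#' @return object of class `transient_fit` with components `coefficients`
#'   (A_i, k_i, b_i, offset), `se`, `amplitude_fractions`, `residual_rms`,
#'   `n_phases`, `aicc`, `at_bounds`, `data`
#' @export
fit_transient <- function(transient, n_phases = 1, allow_stretch = FALSE,
                          n_starts = 8, seed = NULL) {
  stopifnot(inherits(transient, "absorbance_transient"),
            n_phases %in% c(1, 2))
  time <- transient$time; y <- transient$absorbance
  tspan <- max(time) - min(time)
  kgrid <- exp(seq(log(0.2 / tspan), log(200 / tspan), length.out = n_starts))
  if (!is.null(seed)) {
    set.seed(seed)
    kgrid <- kgrid * exp(stats::rnorm(length(kgrid), 0, 0.1))
  }
  starts <- if (n_phases == 1) {
    lapply(kgrid, function(k1) k1)
  } else {
    out <- list()
    for (k1 in kgrid) for (r in c(3, 10, 30)) out <- c(out, list(c(k1, r * k1)))
    out
  }
  best <- NULL
  for (ks in starts) {
    lf <- .transient_linfit(time, y, ks, rep(1, length(ks)))
    if (!is.null(lf) && (is.null(best) || lf$rss < best$rss))
      best <- c(lf, list(k = ks))
  }
  if (is.null(best)) .stopf("transient fit failed: no valid start found")

  p <- n_phases
  par0 <- c(best$A, best$k, if (allow_stretch) rep(1, p), best$offset)
  nmA <- paste0("A", seq_len(p)); nmK <- paste0("k", seq_len(p))
  nmB <- paste0("b", seq_len(p))
  names(par0) <- c(nmA, nmK, if (allow_stretch) nmB, "offset")
  lower <- c(rep(-Inf, p), rep(1e-12, p), if (allow_stretch) rep(0.05, p), -Inf)
  upper <- c(rep(Inf, p), rep(Inf, p), if (allow_stretch) rep(1.5, p), Inf)

  resid_fun <- function(par) {
    A <- par[nmA]; k <- par[nmK]
    b <- if (allow_stretch) par[nmB] else rep(1, p)
    y - eval_transient(time, A, k, b, par["offset"])
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                       fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) {
    rss <- if (is.null(fit)) best$rss else sum(fit$fvec^2)
    .stopf("transient fit did not converge (best residual SS %.3g)", rss)
  }
  par <- fit$par
  A <- par[nmA]; k <- par[nmK]
  b <- if (allow_stretch) par[nmB] else rep(1, p)
  se <- tryCatch({
    covm <- solve(fit$hessian) * sum(fit$fvec^2) / (length(y) - length(par))
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, length(par)))
  names(se) <- names(par)

  frac <- abs(A) / sum(abs(A))
  ord <- order(-frac, -k)
  at_bounds <- any(abs(k - 1e-12) < 1e-12) ||
    (allow_stretch && any(b >= 1.5 - 1e-9 | b <= 0.05 + 1e-9))
  if (at_bounds) .warnf("transient fit: parameter at bound")

  coefs <- c(stats::setNames(A[ord], nmA), stats::setNames(k[ord], nmK),
             stats::setNames(b[ord], nmB), offset = unname(par["offset"]))
  se_out <- c(stats::setNames(se[nmA][ord], nmA),
              stats::setNames(se[nmK][ord], nmK),
              stats::setNames(if (allow_stretch) se[nmB][ord]
                              else rep(NA_real_, p), nmB),
              offset = unname(se["offset"]))
  rss <- sum(fit$fvec^2)
  structure(list(coefficients = coefs, se = se_out,
                 amplitude_fractions = stats::setNames(frac[ord], nmA),
                 residual_rms = sqrt(rss / length(y)),
                 rss = rss, n = length(y),
                 n_phases = p, allow_stretch = allow_stretch,
                 aicc = aicc(rss, length(y), length(par)),
                 at_bounds = at_bounds,
                 data = transient),
            class = "transient_fit")
}

#' @export
print.transient_fit <- function(x, ...) {
  cat(sprintf("Transient fit: %d phase(s)%s\n", x$n_phases,
              if (x$allow_stretch) " (stretched)" else ""))
  tab <- rbind(estimate = x$coefficients, se = x$se)
  print(round(tab, 6))
  cat("amplitude fractions:",
      paste(sprintf("%.4f", x$amplitude_fractions), collapse = ", "), "\n")
  cat(sprintf("residual RMS: %.3g AU, AICc: %.2f\n", x$residual_rms, x$aicc))
  invisible(x)
}

#' @export
coef.transient_fit <- function(object, ...) object$coefficients

#' @export
predict.transient_fit <- function(object, t = NULL, ...) {
  if (is.null(t)) t <- object$data$time
  p <- object$n_phases; cf <- object$coefficients
  eval_transient(t, cf[paste0("A", 1:p)], cf[paste0("k", 1:p)],
                 cf[paste0("b", 1:p)], cf["offset"])
}

#' @export
residuals.transient_fit <- function(object, ...) {
  object$data$absorbance - predict(object)
}

#' Choose between one- and two-exponential transient models
#'
#' Fits both phase counts and selects the one minimising the
#' small-sample corrected AIC (see [aicc()]); ties go to the single
#' exponential. If one fit fails the other is returned.
#'
#' @param transient an `absorbance_transient`
#' @param allow_stretch passed through to [fit_transient()]
#' @return list of class `phase_selection` with `n_phases`, named
#'   `criteria`, and the two `fits` (NULL where a fit failed)
#' @export
select_phase_count <- function(transient, allow_stretch = FALSE) {
  fits <- lapply(c(1, 2), function(p)
    tryCatch(suppressWarnings(
      fit_transient(transient, n_phases = p, allow_stretch = allow_stretch)),
      error = function(e) NULL))
  crit <- vapply(fits, function(f) if (is.null(f)) Inf else f$aicc, numeric(1))
  names(crit) <- c("1", "2")
  if (all(is.infinite(crit))) .stopf("both transient fits failed")
  n_phases <- if (crit[1] <= crit[2]) 1L else 2L
  structure(list(n_phases = n_phases, criteria = crit, fits = fits),
            class = "phase_selection")
}

#' @export
print.phase_selection <- function(x, ...) {
  cat(sprintf("Selected %d phase(s); AICc: 1-phase %.2f, 2-phase %.2f\n",
              x$n_phases, x$criteria[1], x$criteria[2]))
  invisible(x)
}
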