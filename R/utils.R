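# shared internal helpers

#' Small-sample corrected Akaike information criterion
#'
#' Computed from a least-squares residual sum of squares as
#' \code{n*log(rss/n) + 2*p + 2*p*(p+1)/(n-p-1)}, where `p` counts the
#' fitted mean-function parameters plus one for the error variance.
#' Used for all model-order choices (phase count, stretch on/off,
#' substrate inhibition on/off) so nested and non-nested comparisons are
#' handled uniformly.
#'
#' @param rss residual sum of squares
#' @param n number of observations
#' @param k number of mean-function parameters (excluding the variance)
#' @return the AICc value (smaller is better)
#' @export
aicc <- function(rss, n, k) {
  p <- k + 1
  if (n - p - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

# Deterministic per-point seed splitting: one base seed per generator call,
# each data point (or frame) gets its own derived seed so extending a grid
# never reshuffles earlier points. Derived seeds stay below 2^31.
.split_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 1009) %% 2147483647L)
}

.with_point_seed <- function(seed, i, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(.split_seed(seed, i))
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
  }
  eval.parent(substitute(expr))
}

# apply noise to a clean value vector, point-split by seed
.apply_noise <- function(x, kind = c("multiplicative-lognormal", "additive-gaussian"),
                         sigma = 0, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(sigma >= 0)
  if (sigma == 0) return(x)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    eps <- .with_point_seed(seed, i, stats::rnorm(1))
    out[i] <- if (kind == "multiplicative-lognormal") {
      x[i] * exp(sigma * eps)
    } else {
      x[i] + sigma * eps
    }
  }
  out
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.check_finite <- function(x, name) {
  if (!all(is.finite(x))) .stopf("non-finite values in '%s'", name)
  invisible(x)
}

# manifest attached to every generated object; 'created' is metadata only
# and never compared for reproducibility (the data are).
.manifest <- function(generator, params, seed) {
  list(generator = generator, params = params, seed = seed,
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

#' Retrieve the generator manifest of a synthetic object
#' @param x an object produced by one of the `gen_*` generators
#' @return list with generator name, parameters and seed, or NULL
#' @export
manifest <- function(x) attr(x, "manifest")
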