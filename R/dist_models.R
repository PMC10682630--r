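# Sampling-distribution specifications: lognormal concentrations and body
# weights, uniform (optionally triangular) water intake. All specs are plain
# S3 objects so they serialize cleanly into run configs.

# standard-normal 95th percentile, used by the median/P95 parameterization
Z95 <- stats::qnorm(0.95)

#' Lognormal distribution specification
#'
#' A lognormal spec is parameterized on the natural-log scale by `meanlog`
#' (mu) and `sdlog` (sigma); its median is `exp(meanlog)`. `sdlog = 0` is
#' admitted as an explicit point-mass degenerate (the spec is then flagged
#' `degenerate`), which is how single-detection point-source concentrations
#' are represented.
#'
#' @param meanlog Log-scale location mu (log of the variable's units).
#' @param sdlog Log-scale spread sigma (dimensionless), `>= 0`.
#' @return An object of class `lognormal_spec`.
#' @seealso [lognormal_from_mean_sd()], [lognormal_from_median_p95()],
#'   [fit_lognormal()]
#' @export
#' @examples
#' spec <- lognormal_spec(meanlog = 0, sdlog = 1)
#' dist_median(spec)  # exp(0) = 1
lognormal_spec <- function(meanlog, sdlog) {
  zero_mass <- is.numeric(meanlog) && length(meanlog) == 1L &&
    identical(meanlog, -Inf) && identical(as.numeric(sdlog), 0)
  if (!zero_mass &&
      (!is.numeric(meanlog) || length(meanlog) != 1L || !is.finite(meanlog)))
    stop("`meanlog` must be a single finite number (meanlog = -Inf is only ",
         "admitted with sdlog = 0, as an explicit point mass at zero)",
         call. = FALSE)
  if (!is.numeric(sdlog) || length(sdlog) != 1L || !is.finite(sdlog) || sdlog < 0)
    stop("`sdlog` must be a single finite number >= 0", call. = FALSE)
  structure(
    list(meanlog = as.numeric(meanlog), sdlog = as.numeric(sdlog),
         degenerate = sdlog == 0),
    class = c("lognormal_spec", "dist_spec")
  )
}

#' Uniform distribution specification
#'
#' Used for daily drinking-water intake, e.g. 0.5--2 L/day for adults and
#' 0.25--1 L/day for children aged 1--3.
#'
#' @param low,high Support bounds; `0 < low < high`.
#' @return An object of class `uniform_spec`.
#' @export
uniform_spec <- function(low, high) {
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
      length(high) != 1L || !is.finite(low) || !is.finite(high))
    stop("`low` and `high` must be single finite numbers", call. = FALSE)
  if (low <= 0 || high <= low)
    stop("uniform spec requires 0 < low < high", call. = FALSE)
  structure(list(low = as.numeric(low), high = as.numeric(high)),
            class = c("uniform_spec", "dist_spec"))
}

#' Triangular distribution specification
#'
#' Alternative intake model for sensitivity analyses where a most-likely
#' consumption volume is to be emphasized within the plausible range.
#'
#' @param low,mode,high Support bounds and mode; `0 < low <= mode <= high`,
#'   `low < high`.
#' @return An object of class `triangular_spec`.
#' @export
triangular_spec <- function(low, mode, high) {
  vals <- c(low = low, mode = mode, high = high)
  if (!all(vapply(vals, function(v) is.numeric(v) && length(v) == 1L && is.finite(v), TRUE)))
    stop("`low`, `mode`, `high` must be single finite numbers", call. = FALSE)
  if (low <= 0 || mode < low || high < mode || high <= low)
    stop("triangular spec requires 0 < low <= mode <= high, low < high", call. = FALSE)
  structure(list(low = as.numeric(low), mode = as.numeric(mode),
                 high = as.numeric(high)),
            class = c("triangular_spec", "dist_spec"))
}

#' Lognormal spec by moment matching
#'
#' Returns the lognormal distribution whose analytic arithmetic mean and
#' standard deviation equal the supplied values:
#' `sigma^2 = log(1 + sd^2/mean^2)`, `mu = log(mean) - sigma^2/2`.
#' This is the constructor used when only summary statistics of the raw
#' concentrations (survey-table mean/SD) are available.
#'
#' @param mean Target arithmetic mean, `> 0`.
#' @param sd Target arithmetic standard deviation, `>= 0`. `sd = 0` yields a
#'   degenerate point mass at `mean`.
#' @return A [lognormal_spec()].
#' @export
#' @examples
#' spec <- lognormal_from_mean_sd(112, 74)   # nitrate, mg/L
#' dist_median(spec)                         # ~93.5 mg/L
lognormal_from_mean_sd <- function(mean, sd) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0)
    stop("`mean` must be a single positive number", call. = FALSE)
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stop("`sd` must be a single number >= 0", call. = FALSE)
  if (sd == 0) return(lognormal_spec(log(mean), 0))
  s2 <- log1p(sd^2 / mean^2)
  lognormal_spec(log(mean) - s2 / 2, sqrt(s2))
}

#' Lognormal spec from median and 95th percentile
#'
#' `mu = log(median)`, `sigma = log(p95/median) / z_0.95`, with `z_0.95` the
#' standard-normal 95th percentile. This is the parameterization used for
#' body weights reported as "median m kg with 95th percentile q kg".
#'
#' @param median Distribution median, `> 0`.
#' @param p95 95th percentile, `> median`.
#' @return A [lognormal_spec()].
#' @export
#' @examples
#' lognormal_from_median_p95(80, 100)   # adult male body weight, kg
lognormal_from_median_p95 <- function(median, p95) {
  if (!is.numeric(median) || length(median) != 1L || !is.finite(median) || median <= 0)
    stop("`median` must be a single positive number", call. = FALSE)
  if (!is.numeric(p95) || length(p95) != 1L || !is.finite(p95) || p95 <= median)
    stop("`p95` must exceed `median`", call. = FALSE)
  lognormal_spec(log(median), log(p95 / median) / Z95)
}

#' Fit a lognormal to observed values by log-moment matching
#'
#' Censored observations (reported only as below a detection limit, the value
#' holding the limit) are substituted according to `censor_policy` before the
#' fit. The returned spec reproduces the sample mean and sample standard
#' deviation (denominator n-1) of the log-transformed data.
#'
#' @param values Positive observations; censored entries hold the detection
#'   limit.
#' @param censored Logical vector parallel to `values`; default all detected.
#' @param censor_policy One of `"half"` (substitute limit/2, the default),
#'   `"full"` (the limit itself) or `"zero"` (drop censored values from the
#'   fit, since `log(0)` is undefined).
#' @return A [lognormal_spec()]; degenerate when all retained values are
#'   identical.
#' @export
fit_lognormal <- function(values, censored = rep(FALSE, length(values)),
                          censor_policy = c("half", "full", "zero")) {
  censor_policy <- match.arg(censor_policy)
  if (length(values) != length(censored))
    stop("`values` and `censored` must have equal length", call. = FALSE)
  if (sum(!censored) < 2L)
    stop("fewer than 2 detected values; build the spec from summary ",
         "statistics with lognormal_from_mean_sd() or ",
         "lognormal_from_median_p95() instead", call. = FALSE)
  v <- substitute_censored(values, censored, censor_policy)
  v <- v[v > 0]
  if (length(v) < 2L)
    stop("fewer than 2 positive values after censor substitution", call. = FALSE)
  lv <- log(v)
  s <- stats::sd(lv)
  lognormal_spec(mean(lv), if (isTRUE(all.equal(s, 0)) || s < .Machine$double.eps^0.5 * abs(mean(lv) + 1)) 0 else s)
}

# shared censored-value substitution rule
substitute_censored <- function(values, censored, policy) {
  if (!is.numeric(values) || any(!is.finite(values)) || any(values < 0))
    stop("values must be finite and non-negative", call. = FALSE)
  censored <- as.logical(censored)
  out <- values
  out[censored] <- switch(policy,
    half = values[censored] / 2,
    full = values[censored],
    zero = 0
  )
  out
}

#' @export
print.lognormal_spec <- function(x, ...) {
  cat(sprintf("<lognormal_spec> meanlog = %.6g, sdlog = %.6g%s\n",
              x$meanlog, x$sdlog,
              if (x$degenerate) sprintf(" (point mass at %.6g)", exp(x$meanlog)) else ""))
  invisible(x)
}

#' @export
print.uniform_spec <- function(x, ...) {
  cat(sprintf("<uniform_spec> [%.6g, %.6g]\n", x$low, x$high))
  invisible(x)
}

#' @export
print.triangular_spec <- function(x, ...) {
  cat(sprintf("<triangular_spec> [%.6g, %.6g, %.6g]\n", x$low, x$mode, x$high))
  invisible(x)
}

check_probs <- function(p) {
  if (!is.numeric(p) || length(p) < 1L || any(!is.finite(p)) ||
      any(p <= 0) || any(p >= 1))
    stop("probabilities must lie strictly inside (0, 1)", call. = FALSE)
  p
}

#' Analytic quantiles of a distribution spec
#'
#' Exact closed-form quantiles: `exp(mu + z_p * sigma)` for the lognormal,
#' `low + p * (high - low)` for the uniform, and the piecewise inverse CDF
#' for the triangular.
#'
#' @param x A distribution spec.
#' @param probs Probabilities strictly inside (0, 1).
#' @param ... Unused.
#' @return Numeric vector of quantiles.
#' @name quantile.dist_spec
NULL

#' @rdname quantile.dist_spec
#' @export
quantile.lognormal_spec <- function(x, probs, ...) {
  check_probs(probs)
  exp(x$meanlog + stats::qnorm(probs) * x$sdlog)
}

#' @rdname quantile.dist_spec
#' @export
quantile.uniform_spec <- function(x, probs, ...) {
  check_probs(probs)
  x$low + probs * (x$high - x$low)
}

#' @rdname quantile.dist_spec
#' @export
quantile.triangular_spec <- function(x, probs, ...) {
  check_probs(probs)
  fc <- (x$mode - x$low) / (x$high - x$low)
  ifelse(probs < fc,
         x$low + sqrt(probs * (x$high - x$low) * (x$mode - x$low)),
         x$high - sqrt((1 - probs) * (x$high - x$low) * (x$high - x$mode)))
}

#' Random draws from a distribution spec
#'
#' Draws are produced by the inverse-CDF transform of uniform variates, so
#' that matched-seed simulations across population scenarios share the same
#' underlying uniforms (common random numbers). Pass `u` to reuse an
#' externally generated uniform stream.
#'
#' @param spec A distribution spec.
#' @param n Number of draws.
#' @param u Optional vector of `n` uniforms in (0, 1); drawn from the current
#'   RNG stream when `NULL`.
#' @return Numeric vector of length `n`.
#' @export
draw <- function(spec, n, u = NULL) UseMethod("draw")

draw_u <- function(n, u) {
  if (is.null(u)) return(stats::runif(n))
  if (length(u) != n) stop("`u` must have length `n`", call. = FALSE)
  u
}

#' @export
draw.lognormal_spec <- function(spec, n, u = NULL) {
  u <- draw_u(n, u)
  if (spec$degenerate) return(rep(exp(spec$meanlog), n))
  exp(spec$meanlog + spec$sdlog * stats::qnorm(u))
}

#' @export
draw.uniform_spec <- function(spec, n, u = NULL) {
  u <- draw_u(n, u)
  spec$low + u * (spec$high - spec$low)
}

#' @export
draw.triangular_spec <- function(spec, n, u = NULL) {
  u <- draw_u(n, u)
  quantile.triangular_spec(spec, u)
}

#' Analytic moments and median of a distribution spec
#'
#' @param spec A distribution spec.
#' @return A single number.
#' @export
dist_mean <- function(spec) UseMethod("dist_mean")

#' @export
dist_mean.lognormal_spec <- function(spec) exp(spec$meanlog + spec$sdlog^2 / 2)

#' @export
dist_mean.uniform_spec <- function(spec) (spec$low + spec$high) / 2

#' @export
dist_mean.triangular_spec <- function(spec) (spec$low + spec$mode + spec$high) / 3

#' @rdname dist_mean
#' @export
dist_sd <- function(spec) UseMethod("dist_sd")

#' @export
dist_sd.lognormal_spec <- function(spec)
  dist_mean(spec) * sqrt(expm1(spec$sdlog^2))

#' @export
dist_sd.uniform_spec <- function(spec) (spec$high - spec$low) / sqrt(12)

#' @export
dist_sd.triangular_spec <- function(spec) {
  with(spec, sqrt((low^2 + mode^2 + high^2 - low * mode - low * high - mode * high) / 18))
}

#' @rdname dist_mean
#' @export
dist_median <- function(spec) UseMethod("dist_median")

#' @export
dist_median.lognormal_spec <- function(spec) exp(spec$meanlog)

#' @export
dist_median.uniform_spec <- function(spec) (spec$low + spec$high) / 2

#' @export
dist_median.triangular_spec <- function(spec) quantile.triangular_spec(spec, 0.5)

#' Serialize / deserialize a distribution spec
#'
#' Specs round-trip through plain tagged lists so that run configurations can
#' carry them in YAML.
#'
#' @param spec A distribution spec.
#' @return `spec_to_list()`: a named list with a `type` tag;
#'   `spec_from_list()`: the reconstructed spec.
#' @export
spec_to_list <- function(spec) {
  if (inherits(spec, "lognormal_spec"))
    return(list(type = "lognormal", meanlog = spec$meanlog, sdlog = spec$sdlog))
  if (inherits(spec, "uniform_spec"))
    return(list(type = "uniform", low = spec$low, high = spec$high))
  if (inherits(spec, "triangular_spec"))
    return(list(type = "triangular", low = spec$low, mode = spec$mode, high = spec$high))
  stop("not a distribution spec", call. = FALSE)
}

#' @rdname spec_to_list
#' @param x A tagged list as produced by `spec_to_list()`.
#' @export
spec_from_list <- function(x) {
  if (is.null(x$type)) stop("spec list lacks a `type` tag", call. = FALSE)
  switch(as.character(x$type),
    lognormal  = lognormal_spec(x$meanlog, x$sdlog),
    uniform    = uniform_spec(x$low, x$high),
    triangular = triangular_spec(x$low, x$mode, x$high),
    stop("unknown spec type: ", x$type, call. = FALSE)
  )
}
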