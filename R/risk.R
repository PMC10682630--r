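# Hazard-quotient distributions (HQ = exposure / RfD), exceedance
# probabilities against reference doses and alternate intake thresholds, and
# cross-population comparison.

#' Hazard quotient distribution for one exposure result
#'
#' Divides every exposure draw by the chronic oral reference dose. Because
#' the division is a positive monotone transform, each HQ percentile equals
#' the corresponding exposure percentile divided by the RfD exactly; this
#' identity is asserted internally. An HQ below 1 indicates non-risky
#' exposure for the chemical.
#'
#' @param exposure An [sample_exposure()] result.
#' @param rfd Oral reference dose in mg/kg/day, `> 0`. `NA` yields a
#'   `"not_assessable"` result (no HQ can be formed).
#' @param rfd_source Label for the reference-dose source.
#' @return An object of class `risk_result`: `parameter`, `scenario`, `rfd`,
#'   `rfd_source`, `status`, `draws` (HQ), `summary` (mean, sd, P25--P99) and
#'   `exceedance` = Pr(HQ > 1).
#' @export
hazard_quotient <- function(exposure, rfd, rfd_source = "USEPA") {
  stopifnot(inherits(exposure, "exposure_result"))
  if (length(rfd) != 1L) stop("`rfd` must be a single value", call. = FALSE)
  if (is.na(rfd)) {
    return(structure(list(parameter = exposure$parameter,
                          scenario = exposure$scenario,
                          rfd = NA_real_, rfd_source = rfd_source,
                          status = "not_assessable", draws = NULL,
                          summary = NULL, exceedance = NA_real_),
                     class = "risk_result"))
  }
  if (!is.numeric(rfd) || rfd <= 0)
    stop("`rfd` must be positive", call. = FALSE)
  hq <- exposure$draws / rfd
  summ <- summarize_draws(hq)
  # monotone-transform identity: HQ percentiles are exposure percentiles / rfd
  idx <- grep("^p", names(summ))
  stopifnot(max(abs(summ[idx] - exposure$summary[idx] / rfd)) <=
              1e-12 * max(1, max(summ[idx])))
  structure(list(parameter = exposure$parameter, scenario = exposure$scenario,
                 rfd = as.numeric(rfd), rfd_source = rfd_source,
                 status = "assessed", draws = hq, summary = summ,
                 exceedance = mean(hq > 1)),
            class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  if (identical(x$status, "not_assessable")) {
    cat(sprintf("<risk_result> %s, %s: not assessable (no reference dose)\n",
                x$parameter, x$scenario))
    return(invisible(x))
  }
  cat(sprintf("<risk_result> %s, %s, RfD %g mg/kg/day (%s)\n",
              x$parameter, x$scenario, x$rfd, x$rfd_source))
  print(signif(x$summary, 3))
  cat(sprintf("  Pr(HQ > 1) = %.3f\n", x$exceedance))
  invisible(x)
}

#' Probability that exposure exceeds a dose threshold
#'
#' Empirical fraction of Monte Carlo draws strictly above the threshold
#' (ties count as non-exceeding), with a binomial standard error.
#'
#' @param exposure An `exposure_result` (or `risk_result`, in which case the
#'   threshold is on the HQ scale).
#' @param threshold Positive dose in mg/kg/day (or HQ units).
#' @return List with `fraction`, `se`, `n` and `threshold`.
#' @export
#' @examples
#' no3 <- lognormal_from_mean_sd(112, 74)
#' ex <- sample_exposure(no3, default_scenarios()$adult_male,
#'                       n_iter = 10000, seed = 1)
#' exceedance_probability(ex, 1.6)$fraction  # ~0.4
exceedance_probability <- function(exposure, threshold) {
  stopifnot(inherits(exposure, c("exposure_result", "risk_result")))
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0)
    stop("`threshold` must be a single positive number", call. = FALSE)
  if (is.null(exposure$draws))
    stop("result carries no draws", call. = FALSE)
  n <- length(exposure$draws)
  f <- mean(exposure$draws > threshold)
  list(fraction = f, se = sqrt(f * (1 - f) / n), n = n, threshold = threshold)
}

#' Hazard-quotient table across scenarios and parameters
#'
#' One row per (scenario, parameter) with the P25--P99 hazard-quotient
#' percentiles, the exceedance fraction Pr(HQ > 1) and the reference dose
#' used. Parameters without a reference dose appear with status
#' `"not_assessable"` and NA percentiles.
#'
#' @param results List of [hazard_quotient()] results.
#' @param percentiles Percent points; default 25, 50, 75, 90, 95, 99.
#' @return Data frame with columns `scenario`, `parameter`, `pXX`...,
#'   `exceedance`, `rfd`, `rfd_source`, `status`.
#' @seealso [format_hq_table()] for the plain-text rendering in which HQ
#'   values below 0.01 print as `"<0.01"`.
#' @export
hq_table <- function(results, percentiles = c(25, 50, 75, 90, 95, 99)) {
  if (inherits(results, "risk_result")) results <- list(results)
  if (!length(results)) stop("`results` is empty", call. = FALSE)
  if (any(percentiles <= 0 | percentiles >= 100))
    stop("percentiles must lie strictly inside (0, 100)", call. = FALSE)
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "risk_result"))
    if (identical(r$status, "not_assessable")) {
      q <- rep(NA_real_, length(percentiles))
      exc <- NA_real_
    } else {
      q <- stats::quantile(r$draws, probs = percentiles / 100, names = FALSE,
                           type = 7)
      exc <- r$exceedance
    }
    qdf <- as.data.frame(as.list(q))
    names(qdf) <- sprintf("p%g", percentiles)
    cbind(data.frame(scenario = r$scenario, parameter = r$parameter,
                     stringsAsFactors = FALSE),
          qdf,
          data.frame(exceedance = exc, rfd = r$rfd,
                     rfd_source = r$rfd_source, status = r$status,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render an HQ table as plain text
#'
#' Follows the reporting convention for hazard-quotient tables: values below
#' 0.01 are printed as `"<0.01"`; the CSV written by the pipeline keeps full
#' precision.
#'
#' @param tab A [hq_table()] data frame.
#' @return Character vector of report lines (one header + one line per row).
#' @export
format_hq_table <- function(tab) {
  pcols <- grep("^p[0-9]", names(tab), value = TRUE)
  fmt <- function(v) {
    ifelse(is.na(v), "NA", ifelse(v < 0.01, "<0.01", sprintf("%.2f", v)))
  }
  header <- paste(c(sprintf("%-14s", "scenario"), sprintf("%-10s", "parameter"),
                    sprintf("%7s", pcols)), collapse = " ")
  lines <- vapply(seq_len(nrow(tab)), function(i) {
    paste(c(sprintf("%-14s", tab$scenario[i]), sprintf("%-10s", tab$parameter[i]),
            sprintf("%7s", fmt(unlist(tab[i, pcols])))), collapse = " ")
  }, character(1))
  c(header, lines)
}

#' Relative exposure between two population scenarios
#'
#' Signed percent difference, `100 * (stat_b - stat_a) / stat_a`, of a chosen
#' exposure statistic between two scenarios simulated with matched seeds on
#' the same concentration distribution, so the comparison isolates the
#' scenario parameters (intake, body weight) from sampling noise.
#'
#' @param scenario_a,scenario_b [exposure_scenario()] objects (reference and
#'   comparison group).
#' @param conc Concentration spec in mg/L.
#' @param statistic `"median"` (default), `"mean"`, or a percent point given
#'   as a number in (0, 100).
#' @param n_iter,seed Simulation size and seed (shared by both scenarios).
#' @return Signed percent difference.
#' @export
#' @examples
#' sc <- default_scenarios()
#' relative_exposure(sc$adult_male, sc$child_1_3,
#'                   lognormal_from_mean_sd(112, 74),
#'                   n_iter = 10000, seed = 1)  # ~ +220
relative_exposure <- function(scenario_a, scenario_b, conc,
                              statistic = "median", n_iter = 1e5, seed = 42L) {
  stat_of <- function(scenario) {
    ex <- sample_exposure(conc, scenario, n_iter = n_iter, seed = seed)
    if (identical(statistic, "median")) return(stats::median(ex$draws))
    if (identical(statistic, "mean")) return(mean(ex$draws))
    if (is.numeric(statistic) && length(statistic) == 1L &&
        statistic > 0 && statistic < 100)
      return(stats::quantile(ex$draws, statistic / 100, names = FALSE, type = 7))
    stop("`statistic` must be \"median\", \"mean\" or a percent in (0, 100)",
         call. = FALSE)
  }
  a <- stat_of(scenario_a)
  if (a == 0) stop("reference-scenario statistic is zero", call. = FALSE)
  b <- stat_of(scenario_b)
  100 * (b - a) / a
}
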