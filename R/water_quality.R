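# Data model and descriptive statistics for well measurements: survey-table
# summaries, WHO-guideline screening, censoring policy, between-campaign
# change.

#' Contaminant parameter profile
#'
#' Identity and reference values for one water-quality parameter: display
#' units, detection limit (same units), WHO drinking-water guideline value and
#' USEPA chronic oral reference dose (RfD, mg per kg body weight per day).
#'
#' @param id Parameter identifier, e.g. `"NO3"`.
#' @param units `"mg/L"` or `"ug/L"` for concentrations; the bulk indicators
#'   additionally use `"uS/cm"` (conductivity), `"mgCaCO3/L"` (hardness) and
#'   `"pH"`.
#' @param detection_limit Optional detection limit in `units`.
#' @param guideline Optional WHO guideline value in `units`; must be positive.
#' @param guideline_note Optional free-text note on the guideline (e.g. range
#'   guidelines, magnitude caveats).
#' @param rfd Optional oral reference dose in mg/kg/day; must be positive.
#' @param rfd_source Label for the reference-dose source (`"USEPA"`,
#'   `"WHO-EFSA"`, `"custom"`).
#' @return An object of class `parameter_profile`.
#' @export
parameter_profile <- function(id, units = c("mg/L", "ug/L"),
                              detection_limit = NA_real_,
                              guideline = NA_real_, guideline_note = NA_character_,
                              rfd = NA_real_, rfd_source = NA_character_) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("`id` must be a non-empty string", call. = FALSE)
  units <- match.arg(normalize_units(units),
                     c("mg/L", "ug/L", "uS/cm", "mgCaCO3/L", "pH"))
  for (nm in c("detection_limit", "guideline", "rfd")) {
    v <- get(nm)
    if (!is.na(v) && (!is.numeric(v) || v <= 0))
      stop("`", nm, "` must be positive when present", call. = FALSE)
  }
  structure(list(id = id, units = units,
                 detection_limit = as.numeric(detection_limit),
                 guideline = as.numeric(guideline),
                 guideline_note = guideline_note,
                 rfd = as.numeric(rfd), rfd_source = rfd_source),
            class = "parameter_profile")
}

#' @export
print.parameter_profile <- function(x, ...) {
  cat(sprintf("<parameter_profile> %s [%s]", x$id, x$units))
  if (!is.na(x$guideline)) cat(sprintf(", WHO guideline %g %s", x$guideline, x$units))
  if (!is.na(x$rfd)) cat(sprintf(", RfD %g mg/kg/day (%s)", x$rfd, x$rfd_source))
  cat("\n")
  invisible(x)
}

normalize_units <- function(u) {
  u <- trimws(as.character(u))
  u[u %in% c("µg/L", "μg/L", "ug/l")] <- "ug/L"
  u[u == "mg/l"] <- "mg/L"
  u[u %in% c("µS/cm", "μS/cm", "us/cm")] <- "uS/cm"
  u
}

#' Convert concentrations between mg/L and ug/L
#'
#' The package's canonical unit for exposure arithmetic is mg/L; microgram
#' inputs are converted on ingest (factor 1e-3).
#'
#' @param value Numeric concentrations.
#' @param from,to Unit strings (`"mg/L"` or `"ug/L"`).
#' @return Converted values.
#' @export
convert_units <- function(value, from, to = "mg/L") {
  from <- normalize_units(from)
  to <- normalize_units(to)
  ok <- c("mg/L", "ug/L")
  if (!all(from %in% ok) || !all(to %in% ok))
    stop("units must be mg/L or ug/L", call. = FALSE)
  factor <- ifelse(from == to, 1, ifelse(from == "ug/L", 1e-3, 1e3))
  value * factor
}

#' Summary statistics for one parameter's well measurements
#'
#' Computes a survey-table style row (n, max, min, mean, median, sd) after
#' applying a left-censoring substitution policy. Censored observations carry
#' the detection limit as their value. A parameter in which every well is
#' censored is flagged `all_censored`; such parameters are excluded from
#' exposure assessment.
#'
#' @param measurements Data frame with columns `value` and `censored`
#'   (logical), optionally `parameter` and `units` (must each be constant).
#' @param censor_policy `"half"` (detection limit / 2, the default common
#'   environmental practice), `"full"` or `"zero"`.
#' @return An object of class `summary_stats`: list with `n`, `max`, `min`,
#'   `mean`, `median`, `sd`, `fraction_censored`, `all_censored`, plus the
#'   parameter id and units when supplied.
#' @export
#' @examples
#' m <- data.frame(value = c(10, 4, 6), censored = c(FALSE, TRUE, FALSE))
#' summarize_measurements(m)$mean  # mean of {10, 2, 6} = 6
summarize_measurements <- function(measurements,
                                   censor_policy = c("half", "full", "zero")) {
  censor_policy <- match.arg(censor_policy)
  if (!is.data.frame(measurements) || nrow(measurements) == 0L)
    stop("`measurements` must be a non-empty data frame", call. = FALSE)
  if (!all(c("value", "censored") %in% names(measurements)))
    stop("`measurements` needs columns `value` and `censored`", call. = FALSE)
  par <- if ("parameter" %in% names(measurements)) unique(measurements$parameter) else NA_character_
  if (length(par) > 1L)
    stop("measurements mix parameters: ", paste(par, collapse = ", "), call. = FALSE)
  un <- if ("units" %in% names(measurements)) unique(normalize_units(measurements$units)) else NA_character_
  if (length(un) > 1L)
    stop("measurements mix units: ", paste(un, collapse = ", "), call. = FALSE)

  v <- substitute_censored(measurements$value, measurements$censored, censor_policy)
  frac <- mean(as.logical(measurements$censored))
  out <- structure(list(
    parameter = par, units = un, n = nrow(measurements),
    max = max(v), min = min(v), mean = mean(v),
    median = stats::median(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
    fraction_censored = frac, all_censored = frac == 1
  ), class = "summary_stats")
  validate_summary_stats(out)
}

validate_summary_stats <- function(s) {
  stopifnot(s$n >= 1, s$sd >= 0,
            s$min <= s$median, s$median <= s$max,
            s$min <= s$mean, s$mean <= s$max,
            s$fraction_censored >= 0, s$fraction_censored <= 1)
  s
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats>%s n=%d  mean=%.4g  median=%.4g  sd=%.4g  range=[%.4g, %.4g]  censored=%.0f%%%s\n",
              if (is.na(x$parameter)) "" else paste0(" ", x$parameter),
              x$n, x$mean, x$median, x$sd, x$min, x$max,
              100 * x$fraction_censored,
              if (x$all_censored) "  [all-censored]" else ""))
  invisible(x)
}

#' Screen a parameter against its WHO guideline
#'
#' Flags a parameter whose mean concentration is strictly above the profile's
#' guideline value; when well-level values are supplied, additionally reports
#' the fraction of wells strictly exceeding the guideline. Boundary equality
#' does not flag. A profile without a guideline yields an explicit
#' `"not_screenable"` status rather than a silent pass.
#'
#' @param x A [summarize_measurements()] result, or a numeric vector of
#'   well-level concentrations in the profile's units.
#' @param profile A [parameter_profile()].
#' @return A list with `parameter`, `status` (`"screened"` or
#'   `"not_screenable"`), `guideline`, `mean`, `above_guideline`, and
#'   `exceedance_fraction` (NA when only summary statistics are available).
#' @export
screen_guidelines <- function(x, profile) {
  stopifnot(inherits(profile, "parameter_profile"))
  if (is.na(profile$guideline)) {
    return(list(parameter = profile$id, status = "not_screenable",
                guideline = NA_real_, mean = NA_real_,
                above_guideline = NA, exceedance_fraction = NA_real_))
  }
  if (inherits(x, "summary_stats")) {
    m <- x$mean
    frac <- NA_real_
  } else if (is.numeric(x) && length(x) >= 1L) {
    m <- mean(x)
    frac <- mean(x > profile$guideline)
  } else stop("`x` must be summary_stats or a numeric vector", call. = FALSE)
  list(parameter = profile$id, status = "screened",
       guideline = profile$guideline, mean = m,
       above_guideline = m > profile$guideline,
       exceedance_fraction = frac)
}

#' Signed percent change between two campaign means
#'
#' `100 * (new - old) / old`, the arithmetic behind statements such as a 31 %
#' salinity increase or a 30 % nitrate decrease between monitoring campaigns.
#'
#' @param old_mean Baseline mean, `> 0`.
#' @param new_mean Later mean.
#' @return Signed percent change.
#' @export
#' @examples
#' percent_change(100, 131)  # +31
#' percent_change(100, 70)   # -30
percent_change <- function(old_mean, new_mean) {
  if (!is.numeric(old_mean) || any(old_mean <= 0))
    stop("`old_mean` must be positive", call. = FALSE)
  100 * (new_mean - old_mean) / old_mean
}

#' Read / write well-measurement tables
#'
#' The on-disk format is plain CSV with columns
#' `well_id,governorate,parameter,value,units,censored` as emitted by
#' [generate_wells()]. Lines starting with `#` are treated as comments.
#'
#' @param path File path.
#' @return `read_measurements()`: a data frame in the measurement format.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("well_id", "governorate", "parameter", "value", "units", "censored")
  if (!all(need %in% names(df)))
    stop("measurement file lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df$censored <- as.logical(df$censored)
  df$units <- normalize_units(df$units)
  df
}

#' @rdname read_measurements
#' @param measurements Measurement data frame.
#' @param header_lines Optional character vector written as `#`-prefixed
#'   comment lines before the CSV header (provenance).
#' @export
write_measurements <- function(measurements, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  utils::write.csv(measurements, con, row.names = FALSE)
  invisible(path)
}

#' Survey-style summary table over all parameters
#'
#' Applies [summarize_measurements()] per parameter and joins guideline
#' screening, yielding one row per parameter in the shape of a groundwater
#' survey quality table (parameter, units, max, min, mean, median, sd,
#' guideline, flag).
#'
#' @param measurements Measurement data frame (all parameters).
#' @param profiles Named list of [parameter_profile()] objects; defaults to
#'   profiles derived from the packaged Gaza survey table for matching ids.
#' @param censor_policy Passed to [summarize_measurements()].
#' @return Data frame, one row per parameter.
#' @export
summary_table <- function(measurements, profiles = NULL,
                          censor_policy = c("half", "full", "zero")) {
  censor_policy <- match.arg(censor_policy)
  pars <- unique(measurements$parameter)
  rows <- lapply(pars, function(p) {
    s <- summarize_measurements(measurements[measurements$parameter == p, , drop = FALSE],
                                censor_policy = censor_policy)
    prof <- profiles[[p]]
    scr <- if (!is.null(prof)) screen_guidelines(s, prof) else
      list(status = "not_screenable", guideline = NA_real_, above_guideline = NA)
    data.frame(parameter = p, units = s$units, n = s$n, max = s$max,
               min = s$min, mean = s$mean, median = s$median, sd = s$sd,
               fraction_censored = s$fraction_censored,
               all_censored = s$all_censored,
               guideline = scr$guideline,
               above_guideline = if (identical(scr$status, "screened")) scr$above_guideline else NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
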