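# Packaged reference data for the Gaza Strip groundwater survey: per-parameter
# summary statistics with WHO guideline values, USEPA chronic oral reference
# doses, alternate intake benchmarks and the default run configuration.

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "dwrisk")
  if (!nzchar(p)) stop("packaged file not found: ", file, call. = FALSE)
  p
}

#' Gaza groundwater survey summary table
#'
#' Per-parameter summary statistics (max, min, mean, median, SD) over 115
#' municipal wells, with WHO guideline values in the declared units,
#' detection limits and censoring modes. Six trace metals (Al, As, Cd, Co,
#' Ni, Pb) are censored in every well; PO4 and Cu were detected in a single
#' well each (point sources).
#'
#' @param quiet Suppress the data-caveat messages (the Mn guideline magnitude
#'   is stored as printed in the source survey despite being inconsistent
#'   with WHO practice).
#' @return Data frame, one row per parameter.
#' @export
gaza_summary <- function(quiet = FALSE) {
  df <- utils::read.csv(extdata_path("gaza_table1.csv"),
                        stringsAsFactors = FALSE, comment.char = "#")
  df$units <- normalize_units(df$units)
  if (!quiet) {
    noted <- df$parameter[!is.na(df$guideline_note) & df$guideline_note != "NA"]
    if ("Mn" %in% noted)
      message("Note: the Mn guideline value (0.8 on a ug/L row) is stored as ",
              "printed in the source survey; its magnitude is inconsistent ",
              "with WHO practice.")
  }
  df
}

#' USEPA chronic oral reference doses
#'
#' Reference doses (mg per kg body weight per day) for the parameters with a
#' hazard-quotient assessment. The Ag entry uses the standard USEPA IRIS
#' value of 5.0e-3 mg/kg/day.
#'
#' @param quiet Suppress the Ag provenance message.
#' @return Data frame with columns `parameter`, `rfd`, `source`.
#' @export
gaza_rfd <- function(quiet = FALSE) {
  df <- utils::read.csv(extdata_path("rfd_usepa.csv"),
                        stringsAsFactors = FALSE, comment.char = "#")
  if (!quiet)
    message("Ag RfD set to the standard USEPA IRIS value 5.0e-3 mg/kg/day; ",
            "override via the `rfd` argument if needed.")
  df
}

#' Alternate intake benchmarks
#'
#' WHO/EFSA acceptable daily intake for nitrate (3.7 mg/kg/day) and EFSA
#' adequate intake for fluoride (0.05 mg/kg/day, covering all exposure
#' sources). Reported alongside, never substituted for, the USEPA reference
#' doses.
#'
#' @return Data frame with columns `parameter`, `threshold`, `source`,
#'   `label`.
#' @export
alt_thresholds <- function() {
  utils::read.csv(extdata_path("alt_thresholds.csv"),
                  stringsAsFactors = FALSE, comment.char = "#")
}

#' Parameter profiles for the packaged survey
#'
#' Builds a named list of [parameter_profile()] objects joining the survey
#' table's units, detection limits and WHO guidelines with the USEPA
#' reference doses.
#'
#' @return Named list of `parameter_profile` objects.
#' @export
gaza_profiles <- function() {
  tab <- gaza_summary(quiet = TRUE)
  rfd <- gaza_rfd(quiet = TRUE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    j <- match(row$parameter, rfd$parameter)
    parameter_profile(
      id = row$parameter, units = row$units,
      detection_limit = row$detection_limit,
      guideline = row$who_guideline,
      guideline_note = row$guideline_note,
      rfd = if (is.na(j)) NA_real_ else rfd$rfd[j],
      rfd_source = if (is.na(j)) NA_character_ else rfd$source[j]
    )
  })
  stats::setNames(out, tab$parameter)
}

#' Concentration spec (mg/L) from a survey-table row
#'
#' Detected parameters get the lognormal moment-matched to the row's
#' mean/SD; single-well point sources get a point mass at the detected
#' value; all-censored parameters return `NULL` (excluded from exposure
#' assessment, which is only performed for detected chemicals). Microgram
#' rows are converted to mg/L; non-concentration rows (pH, EC, hardness)
#' return `NULL`.
#'
#' @param row One row of [gaza_summary()] (or any data frame with the same
#'   columns).
#' @return A [lognormal_spec()] in mg/L, or `NULL`.
#' @export
conc_spec_from_row <- function(row) {
  if (!row$units %in% c("mg/L", "ug/L")) return(NULL)
  if (identical(row$censoring, "all")) return(NULL)
  if (identical(row$censoring, "point")) {
    v <- convert_units(row$point_value, row$units)
    return(lognormal_spec(log(v), 0))
  }
  lognormal_from_mean_sd(convert_units(row$mean, row$units),
                         convert_units(row$sd, row$units))
}
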