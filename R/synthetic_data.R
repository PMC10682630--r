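# Synthetic well-measurement generator: emulates a stratified groundwater
# survey (115 municipal wells across five governorates) with per-parameter
# lognormal marginals matched to target summary statistics, fully censored
# trace metals, and single-well point-source detections.

GOVERNORATES <- c("Northern", "Gaza", "Deir al-Balah", "Khan Yunis", "Rafah")

default_governorate_counts <- function() {
  stats::setNames(c(30L, 34L, 18L, 22L, 11L), GOVERNORATES)
}

#' Configuration for the synthetic well generator
#'
#' @param parameters Data frame with one row per parameter and columns
#'   `parameter`, `units`, `mean`, `sd` (targets for the lognormal marginal),
#'   optional `min`/`max` (clipping range), `detection_limit`, `censoring`
#'   (`"none"`, `"all"`, or `"point"`) and `point_value` (single detected
#'   well's concentration for `"point"` parameters). Defaults to the packaged
#'   Gaza survey table, [gaza_summary()].
#' @param governorate_counts Named integer vector of wells per governorate;
#'   default 30/34/18/22/11 (115 wells in total). Must sum to `n_wells`.
#' @param n_wells Total well count; defaults to the sum of
#'   `governorate_counts`.
#' @param clip `"none"` (default; clipping shifts moments, so moment-matching
#'   checks run unclipped) or `"range"` (clip draws into the target
#'   `[min, max]`).
#' @param seed Integer RNG seed; a fixed seed makes the output byte-identical
#'   across runs.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(parameters = gaza_summary(quiet = TRUE),
                             governorate_counts = default_governorate_counts(),
                             n_wells = sum(governorate_counts),
                             clip = c("none", "range"),
                             seed = 1L) {
  clip <- match.arg(clip)
  if (!is.data.frame(parameters))
    stop("`parameters` must be a data frame", call. = FALSE)
  need <- c("parameter", "units", "mean", "sd")
  if (!all(need %in% names(parameters)))
    stop("`parameters` lacks columns: ",
         paste(setdiff(need, names(parameters)), collapse = ", "), call. = FALSE)
  np <- nrow(parameters)
  if (is.null(parameters$censoring)) parameters$censoring <- rep("none", np)
  if (is.null(parameters$detection_limit)) parameters$detection_limit <- rep(NA_real_, np)
  if (is.null(parameters$point_value)) parameters$point_value <- rep(NA_real_, np)
  if (is.null(parameters$min)) parameters$min <- rep(NA_real_, np)
  if (is.null(parameters$max)) parameters$max <- rep(NA_real_, np)
  bad <- !parameters$censoring %in% c("none", "all", "point")
  if (any(bad))
    stop("unknown censoring mode: ", paste(unique(parameters$censoring[bad]), collapse = ", "),
         call. = FALSE)
  open <- parameters$censoring == "none"
  if (any(open & (is.na(parameters$mean) | parameters$mean <= 0)))
    stop("every sampled parameter needs a positive target mean", call. = FALSE)
  if (any(open & (is.na(parameters$sd) | parameters$sd < 0)))
    stop("every sampled parameter needs a non-negative target sd", call. = FALSE)
  if (any(parameters$censoring == "all" & is.na(parameters$detection_limit)))
    stop("all-censored parameters need a detection limit", call. = FALSE)
  if (any(parameters$censoring == "point" &
          (is.na(parameters$point_value) | is.na(parameters$detection_limit))))
    stop("point-source parameters need `point_value` and `detection_limit`", call. = FALSE)
  governorate_counts <- round(governorate_counts)
  if (is.null(names(governorate_counts)) || any(!nzchar(names(governorate_counts))))
    stop("`governorate_counts` must be named", call. = FALSE)
  if (any(governorate_counts < 0))
    stop("governorate counts must be non-negative", call. = FALSE)
  if (sum(governorate_counts) != n_wells)
    stop("governorate counts sum to ", sum(governorate_counts),
         ", not the configured total of ", n_wells, call. = FALSE)
  structure(list(parameters = parameters,
                 governorate_counts = governorate_counts,
                 n_wells = as.integer(n_wells), clip = clip,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> %d wells x %d parameters, clip=%s, seed=%d\n",
              x$n_wells, nrow(x$parameters), x$clip, x$seed))
  invisible(x)
}

#' Generate a synthetic well-measurement table
#'
#' For each configured parameter, concentrations are drawn independently
#' across wells from the lognormal distribution moment-matched to the target
#' mean/SD (see [lognormal_from_mean_sd()]), optionally clipped into the
#' target range. All-censored parameters emit one censored row per well at the
#' detection limit; point-source parameters emit exactly one detected well
#' (chosen by the seeded RNG) and censored rows elsewhere. Wells are assigned
#' to governorates in contiguous blocks sized by the configured counts; no
#' spatial structure or inter-parameter correlation is modelled.
#'
#' @param config A [generator_config()].
#' @return Data frame with columns `well_id`, `governorate`, `parameter`,
#'   `value`, `units`, `censored`; `wells x parameters` rows.
#' @export
#' @examples
#' cfg <- generator_config(data.frame(parameter = "NO3", units = "mg/L",
#'                                    mean = 112, sd = 74), seed = 7)
#' wells <- generate_wells(cfg)
#' nrow(wells)  # 115
generate_wells <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_wells
  well_id <- sprintf("W%03d", seq_len(n))
  governorate <- rep(names(config$governorate_counts), times = config$governorate_counts)
  pars <- config$parameters
  if (nrow(pars) == 0L || n == 0L) {
    return(data.frame(well_id = character(), governorate = character(),
                      parameter = character(), value = numeric(),
                      units = character(), censored = logical(),
                      stringsAsFactors = FALSE))
  }
  blocks <- lapply(seq_len(nrow(pars)), function(i) {
    row <- pars[i, ]
    seed_i <- derive_seed(config$seed, i)
    if (row$censoring == "all") {
      value <- rep(row$detection_limit, n)
      censored <- rep(TRUE, n)
    } else if (row$censoring == "point") {
      hit <- with_seed(seed_i, sample.int(n, 1L))
      value <- rep(row$detection_limit, n)
      value[hit] <- row$point_value
      censored <- rep(TRUE, n)
      censored[hit] <- FALSE
    } else {
      spec <- lognormal_from_mean_sd(row$mean, row$sd)
      value <- with_seed(seed_i, draw(spec, n))
      if (config$clip == "range" && !is.na(row$min) && !is.na(row$max))
        value <- pmin(pmax(value, row$min), row$max)
      censored <- rep(FALSE, n)
    }
    data.frame(well_id = well_id, governorate = governorate,
               parameter = row$parameter, value = value,
               units = normalize_units(row$units), censored = censored,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
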