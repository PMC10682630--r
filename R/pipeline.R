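# End-to-end orchestration: validated run configuration, the
# summary -> exposure -> hazard-quotient pipeline, and provenance logging.

#' Validated run configuration for the full pipeline
#'
#' @param summary `"packaged"` (default: the bundled Gaza survey table) or a
#'   path to a summary CSV in the [gaza_summary()] column layout.
#' @param measurements Optional path to a well-measurement CSV (the
#'   [generate_wells()] format); when given, the summary table is computed
#'   from it instead of read from `summary`, and parameters censored in every
#'   well are excluded from exposure assessment.
#' @param scenarios Character vector of scenario names from
#'   [default_scenarios()], or a named list of [exposure_scenario()] objects.
#' @param n_iter Monte Carlo iterations per (parameter, scenario); `>= 1`.
#' @param seed Integer base seed. Each parameter gets a seed derived from it;
#'   the same parameter shares its seed across scenarios (matched seeds).
#' @param percentiles Percent points reported in the exposure and HQ tables.
#' @param censor_policy Censoring substitution policy for summaries.
#' @param rfd Data frame `parameter, rfd, source`; defaults to [gaza_rfd()].
#' @param thresholds Data frame of alternate intake benchmarks; defaults to
#'   [alt_thresholds()].
#' @param out_dir Output directory (created if absent).
#' @return An object of class `run_config`.
#' @export
run_config <- function(summary = "packaged", measurements = NULL,
                       scenarios = c("adult_male", "adult_female", "child_1_3"),
                       n_iter = 1e5, seed = 42L,
                       percentiles = c(25, 50, 75, 90, 95, 99),
                       censor_policy = c("half", "full", "zero"),
                       rfd = gaza_rfd(quiet = TRUE),
                       thresholds = alt_thresholds(),
                       out_dir = tempfile("dwrisk_run_")) {
  censor_policy <- match.arg(censor_policy)
  if (!is.numeric(n_iter) || length(n_iter) != 1L || n_iter < 1)
    stop("`n_iter` must be >= 1", call. = FALSE)
  if (any(percentiles <= 0 | percentiles >= 100))
    stop("percentiles must lie strictly inside (0, 100)", call. = FALSE)
  if (!identical(summary, "packaged") && !file.exists(summary))
    stop("summary file does not exist: ", summary, call. = FALSE)
  if (!is.null(measurements) && !file.exists(measurements))
    stop("measurements file does not exist: ", measurements, call. = FALSE)
  if (is.character(scenarios)) {
    known <- default_scenarios()
    bad <- setdiff(scenarios, names(known))
    if (length(bad))
      stop("unknown scenario(s): ", paste(bad, collapse = ", "),
           "; valid names: ", paste(names(known), collapse = ", "), call. = FALSE)
    scenarios <- known[scenarios]
  }
  if (!length(scenarios) || !all(vapply(scenarios, inherits, TRUE, "exposure_scenario")))
    stop("`scenarios` must name or contain exposure scenarios", call. = FALSE)
  if (!all(c("parameter", "rfd") %in% names(rfd)))
    stop("`rfd` needs columns parameter, rfd", call. = FALSE)
  structure(list(summary = summary, measurements = measurements,
                 scenarios = scenarios, n_iter = as.integer(n_iter),
                 seed = as.integer(seed), percentiles = percentiles,
                 censor_policy = censor_policy, rfd = rfd,
                 thresholds = thresholds, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Accepts the keys of [run_config()]; scenario entries may be names or
#' tagged distribution-spec lists (`intake`, `body_weight`) as produced by
#' [spec_to_list()].
#'
#' @param path YAML file path.
#' @param ... Overrides passed on to [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$scenarios) && is.list(raw$scenarios) &&
      is.null(names(raw$scenarios)) &&
      all(vapply(raw$scenarios, is.character, TRUE)))
    raw$scenarios <- unlist(raw$scenarios)
  if (!is.null(raw$scenarios) && is.list(raw$scenarios) &&
      !is.null(names(raw$scenarios))) {
    raw$scenarios <- lapply(stats::setNames(names(raw$scenarios), names(raw$scenarios)),
      function(nm) {
        sc <- raw$scenarios[[nm]]
        exposure_scenario(nm, spec_from_list(sc$intake),
                          spec_from_list(sc$body_weight))
      })
  }
  args <- utils::modifyList(raw, list(...))
  do.call(run_config, args)
}

config_hash <- function(config) {
  stable <- list(summary = config$summary, measurements = config$measurements,
                 scenarios = lapply(config$scenarios, function(s)
                   list(name = s$name, intake = spec_to_list(s$intake),
                        body_weight = spec_to_list(s$body_weight))),
                 n_iter = config$n_iter, seed = config$seed,
                 percentiles = config$percentiles,
                 censor_policy = config$censor_policy,
                 rfd = config$rfd, thresholds = config$thresholds)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(stable), f)
  unname(tools::md5sum(f))
}

write_table_csv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# summary table used for exposure: either the packaged/CSV survey layout or
# one computed from well-level measurements
pipeline_summary <- function(config) {
  if (!is.null(config$measurements)) {
    meas <- read_measurements(config$measurements)
    tab <- summary_table(meas, profiles = gaza_profiles(),
                         censor_policy = config$censor_policy)
    tab$censoring <- ifelse(tab$all_censored, "all", "none")
    tab$point_value <- NA_real_
    tab$who_guideline <- tab$guideline
    return(tab)
  }
  if (identical(config$summary, "packaged")) gaza_summary(quiet = TRUE)
  else {
    df <- utils::read.csv(config$summary, stringsAsFactors = FALSE,
                          comment.char = "#")
    df$units <- normalize_units(df$units)
    df
  }
}

#' Run the full screening / exposure / risk pipeline
#'
#' Emits, under `config$out_dir`: `summary.csv` (survey-shaped summary with
#' guideline flags), one `exposure_<scenario>.csv` and one
#' `hq_<scenario>.csv` per scenario, `hq_report.txt` (plain-text rendering
#' with the `<0.01` convention), `exceedance.csv` (reference doses and
#' alternate benchmarks) and `provenance.yaml` (seed, iterations, config
#' hash). Any stage failure aborts with the failing stage named and removes
#' partial outputs. Identical config and seed reproduce all outputs
#' byte-for-byte.
#'
#' @param config A [run_config()].
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with the output paths, the exposure and risk
#'   results, and the config hash.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  say <- function(...) if (verbose) message("[dwrisk] ", ...)
  stage <- "setup"
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline stage `", stage, "` failed: ", conmsg(e), call. = FALSE)
  }
  conmsg <- function(e) conditionMessage(e)
  header <- sprintf("dwrisk config_hash=%s seed=%d n_iter=%d", hash,
                    config$seed, config$n_iter)
  out <- tryCatch({
    stage <- "summary"
    say("summarizing / screening")
    tab <- pipeline_summary(config)
    profiles <- gaza_profiles()
    tab$above_guideline <- vapply(seq_len(nrow(tab)), function(i) {
      g <- tab$who_guideline[i]
      if (is.na(g)) NA else unname(tab$mean[i] > g)
    }, NA)
    p <- file.path(config$out_dir, "summary.csv")
    write_table_csv(tab, p, header); written <- c(written, p)

    stage <- "exposure"
    # detected concentration parameters only
    specs <- lapply(seq_len(nrow(tab)), function(i) conc_spec_from_row(tab[i, ]))
    names(specs) <- tab$parameter
    specs <- Filter(Negate(is.null), specs)
    say("simulating exposure for ", length(specs), " parameters x ",
        length(config$scenarios), " scenarios (n = ", config$n_iter, ")")
    exposures <- lapply(config$scenarios, function(sc) {
      res <- lapply(seq_along(specs), function(k)
        sample_exposure(specs[[k]], sc, n_iter = config$n_iter,
                        seed = derive_seed(config$seed, k),
                        parameter = names(specs)[k]))
      stats::setNames(res, names(specs))
    })
    # exposure tables follow the survey convention (P50 upward); the HQ
    # tables below additionally carry P25
    pct_exp <- config$percentiles[config$percentiles >= 50]
    if (!length(pct_exp)) pct_exp <- c(50, 75, 90, 95, 99)
    for (scn in names(exposures)) {
      et <- percentile_table(exposures[[scn]], percentiles = pct_exp)
      et$rfd <- config$rfd$rfd[match(et$parameter, config$rfd$parameter)]
      p <- file.path(config$out_dir, paste0("exposure_", scn, ".csv"))
      write_table_csv(et, p, header); written <- c(written, p)
    }

    stage <- "risk"
    risks <- lapply(exposures, function(res) {
      assessable <- intersect(names(res), config$rfd$parameter)
      lapply(stats::setNames(assessable, assessable), function(par) {
        j <- match(par, config$rfd$parameter)
        hazard_quotient(res[[par]], config$rfd$rfd[j],
                        rfd_source = if (!is.null(config$rfd$source)) config$rfd$source[j] else "custom")
      })
    })
    for (scn in names(risks)) {
      ht <- hq_table(risks[[scn]], percentiles = config$percentiles)
      p <- file.path(config$out_dir, paste0("hq_", scn, ".csv"))
      write_table_csv(ht, p, header); written <- c(written, p)
    }
    all_ht <- hq_table(unlist(risks, recursive = FALSE),
                       percentiles = config$percentiles)
    p <- file.path(config$out_dir, "hq_report.txt")
    writeLines(c(paste0("# ", header), format_hq_table(all_ht)), p)
    written <- c(written, p)

    stage <- "exceedance"
    exc_rows <- list()
    for (scn in names(exposures)) {
      for (par in names(exposures[[scn]])) {
        lims <- rbind(
          if (par %in% config$rfd$parameter)
            data.frame(threshold = config$rfd$rfd[match(par, config$rfd$parameter)],
                       source = "USEPA", label = "oral reference dose"),
          if (!is.null(config$thresholds) && par %in% config$thresholds$parameter)
            config$thresholds[config$thresholds$parameter == par,
                              c("threshold", "source", "label")]
        )
        if (is.null(lims) || !nrow(lims)) next
        for (i in seq_len(nrow(lims))) {
          e <- exceedance_probability(exposures[[scn]][[par]], lims$threshold[i])
          exc_rows[[length(exc_rows) + 1L]] <-
            data.frame(scenario = scn, parameter = par,
                       threshold = lims$threshold[i], source = lims$source[i],
                       label = lims$label[i], fraction = e$fraction, se = e$se,
                       stringsAsFactors = FALSE)
        }
      }
    }
    exc <- do.call(rbind, exc_rows)
    p <- file.path(config$out_dir, "exceedance.csv")
    write_table_csv(exc, p, header); written <- c(written, p)

    stage <- "provenance"
    p <- file.path(config$out_dir, "provenance.yaml")
    writeLines(yaml::as.yaml(list(config_hash = hash, seed = config$seed,
                                  n_iter = config$n_iter,
                                  scenarios = names(config$scenarios),
                                  censor_policy = config$censor_policy)), p)
    written <- c(written, p)

    list(paths = written, summary = tab, exposures = exposures, risks = risks,
         exceedance = exc, config_hash = hash)
  }, error = on_fail)
  say("done: ", length(out$paths), " files in ", config$out_dir)
  invisible(out)
}
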