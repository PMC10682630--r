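# shared fixtures, built in code

# minimal parameter table for the synthetic generator
tiny_param_table <- function() {
  data.frame(
    parameter = c("NO3", "F"),
    units = c("mg/L", "mg/L"),
    max = c(365, 2.6), min = c(16, 0.2),
    mean = c(112, 1.1), sd = c(74, 0.53),
    stringsAsFactors = FALSE
  )
}

# wrap a bare draw vector as an exposure result (for table/HQ plumbing tests)
fake_exposure <- function(draws, parameter = "X", scenario = "test") {
  structure(list(parameter = parameter, scenario = scenario,
                 n_iter = length(draws), seed = 0L, draws = draws,
                 summary = dwrisk:::summarize_draws(draws)),
            class = "exposure_result")
}

adult_male <- function() default_scenarios()$adult_male
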