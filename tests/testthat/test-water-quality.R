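# descriptive statistics, censoring policy, guideline screening

test_that("summarize_measurements applies the censoring substitution policy", {
  plain <- data.frame(value = 1:5, censored = FALSE)
  s <- summarize_measurements(plain)
  expect_equal(s$mean, 3); expect_equal(s$median, 3)
  expect_equal(s$min, 1); expect_equal(s$max, 5)
  expect_equal(s$fraction_censored, 0)

  mixed <- data.frame(value = c(10, 4, 6), censored = c(FALSE, TRUE, FALSE))
  expect_equal(summarize_measurements(mixed, "half")$mean, mean(c(10, 2, 6)))
  expect_equal(summarize_measurements(mixed, "full")$mean, mean(c(10, 4, 6)))
  expect_equal(summarize_measurements(mixed, "zero")$mean, mean(c(10, 0, 6)))
  expect_equal(summarize_measurements(mixed)$fraction_censored, 1 / 3)

  allc <- data.frame(value = rep(16, 115), censored = TRUE,
                     parameter = "As", units = "ug/L")
  s <- summarize_measurements(allc)
  expect_true(s$all_censored)
  expect_equal(s$fraction_censored, 1)

  expect_error(summarize_measurements(plain[0, ]), "non-empty")
  two_units <- data.frame(value = 1:2, censored = FALSE,
                          units = c("mg/L", "ug/L"))
  expect_error(summarize_measurements(two_units), "mix units")
  two_pars <- data.frame(value = 1:2, censored = FALSE,
                         parameter = c("A", "B"))
  expect_error(summarize_measurements(two_pars), "mix parameters")
})

test_that("guideline screening uses a strict inequality and explicit statuses", {
  no3 <- parameter_profile("NO3", "mg/L", guideline = 50)
  s <- summarize_measurements(data.frame(value = c(100, 124), censored = FALSE))
  scr <- screen_guidelines(s, no3)
  expect_identical(scr$status, "screened")
  expect_true(scr$above_guideline)

  at <- summarize_measurements(data.frame(value = c(50, 50), censored = FALSE))
  expect_false(screen_guidelines(at, no3)$above_guideline)  # boundary passes

  wells <- rep(25, 20)  # all at guideline/2
  scr <- screen_guidelines(wells, no3)
  expect_equal(scr$exceedance_fraction, 0)
  expect_false(scr$above_guideline)

  none <- parameter_profile("Sr", "ug/L")
  expect_identical(screen_guidelines(s, none)$status, "not_screenable")
})

test_that("raising the guideline never increases the exceedance fraction", {
  vals <- dwrisk:::with_seed(8, draw(lognormal_from_mean_sd(112, 74), 500))
  guidelines <- c(10, 25, 50, 100, 200, 400)
  fracs <- vapply(guidelines, function(g)
    screen_guidelines(vals, parameter_profile("NO3", "mg/L", guideline = g))$exceedance_fraction,
    numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("percent_change is signed arithmetic with the expected identities", {
  expect_equal(percent_change(100, 131), 31)
  expect_equal(percent_change(100, 70), -30)
  expect_equal(percent_change(7.3, 7.3), 0)
  # reversal identity: pc(a, b) = -pc(b, a) * b / a
  pairs <- dwrisk:::with_seed(4, matrix(runif(40, 0.1, 100), ncol = 2))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    expect_equal(percent_change(a, b), -percent_change(b, a) * b / a,
                 tolerance = 1e-10)
  }
  expect_error(percent_change(0, 10), "positive")
  expect_error(percent_change(-2, 10), "positive")
})

test_that("summaries over generator output recover the generator's targets", {
  cfg <- generator_config(tiny_param_table(),
                          governorate_counts = c(Northern = 200000L), seed = 21L)
  w <- generate_wells(cfg)
  s <- summarize_measurements(w[w$parameter == "NO3", ])
  expect_lt(abs(s$mean - 112) / 112, 0.01)
  expect_lt(abs(s$sd - 74) / 74, 0.01)
})

test_that("unit conversion and measurement round trips preserve values", {
  expect_equal(convert_units(2521, "ug/L"), 2.521)
  expect_equal(convert_units(1.6, "mg/L", "ug/L"), 1600)
  expect_equal(convert_units(c(1, 2), c("mg/L", "ug/L")), c(1, 0.002))
  expect_error(convert_units(1, "ppm"), "units")

  w <- generate_wells(generator_config(tiny_param_table(), seed = 6L))
  f <- tempfile(fileext = ".csv")
  write_measurements(w, f, header_lines = "round-trip fixture")
  back <- read_measurements(f)
  expect_equal(back$value, w$value)
  expect_identical(back$censored, w$censored)
  expect_identical(back$well_id, w$well_id)

  tab <- summary_table(w, profiles = gaza_profiles())
  expect_true(tab$above_guideline[tab$parameter == "NO3"])
  expect_equal(nrow(tab), 2)
})
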