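# hazard quotients, exceedance probabilities, population comparison

test_that("HQ percentiles equal exposure percentiles divided by the RfD, exactly", {
  ex <- sample_exposure(lognormal_from_mean_sd(112, 74), adult_male(),
                        n_iter = 5000, seed = 3L, parameter = "NO3")
  rr <- hazard_quotient(ex, 1.6)
  p <- c(1, 10, 25, 50, 75, 90, 95, 99) / 100
  expect_equal(quantile(rr$draws, p, names = FALSE),
               quantile(ex$draws, p, names = FALSE) / 1.6, tolerance = 1e-14)
  expect_equal(rr$draws, ex$draws / 1.6)
  # exceedance of the RfD equals the fraction of HQ draws above one, exactly
  expect_identical(exceedance_probability(ex, 1.6)$fraction,
                   mean(rr$draws > 1))
  expect_identical(rr$exceedance, mean(rr$draws > 1))
})

test_that("boundary and degenerate hazard quotients follow the strict inequality", {
  ex <- fake_exposure(rep(1.6, 100), parameter = "X")
  rr <- hazard_quotient(ex, 1.6)
  expect_true(all(rr$draws == 1))
  expect_equal(rr$exceedance, 0)  # ties count as non-exceeding

  na_rr <- hazard_quotient(ex, NA_real_)
  expect_identical(na_rr$status, "not_assessable")
  expect_error(hazard_quotient(ex, 0), "positive")
  expect_error(hazard_quotient(ex, -1), "positive")
})

test_that("exceedance is non-increasing in the threshold, with binomial SE", {
  ex <- sample_exposure(lognormal_from_mean_sd(112, 74), adult_male(),
                        n_iter = 20000, seed = 23L)
  thresholds <- c(0.1, 0.5, 1, 1.6, 2.5, 3.7, 6, 10)
  fr <- vapply(thresholds, function(t) exceedance_probability(ex, t)$fraction,
               numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_equal(exceedance_probability(ex, min(ex$draws) / 2)$fraction, 1)
  e <- exceedance_probability(ex, 1.6)
  expect_equal(e$se, sqrt(e$fraction * (1 - e$fraction) / e$n))
  expect_error(exceedance_probability(ex, 0), "positive")
})

test_that("hq_table renders sub-0.01 quotients as <0.01 in the text report", {
  tiny <- hazard_quotient(fake_exposure(rep(1e-4, 50), "Zn"), 0.3)
  big <- hazard_quotient(fake_exposure(seq(0.5, 5, length.out = 50), "NO3"), 1.6)
  tab <- hq_table(list(tiny, big))
  expect_equal(nrow(tab), 2)
  expect_true(all(tab[tab$parameter == "Zn", c("p25", "p99")] < 0.01))
  txt <- format_hq_table(tab)
  expect_match(txt[2], "<0.01")        # all-sub-threshold row
  expect_no_match(txt[3], "<0.01")     # NO3 row prints numbers
  # CSV-shape table keeps full precision
  expect_equal(tab$p50[tab$parameter == "Zn"], 1e-4 / 0.3, tolerance = 1e-12)

  na_row <- hq_table(hazard_quotient(fake_exposure(1:10, "PO4"), NA_real_))
  expect_identical(na_row$status, "not_assessable")
  expect_true(is.na(na_row$p50))
})

test_that("metal hazard quotients stay far below one except strontium", {
  # from the survey summaries: every metal with a reference dose except Sr
  # has HQ P95 < 0.05; Sr reaches ~0.19
  tab <- gaza_summary(quiet = TRUE)
  rfd <- gaza_rfd(quiet = TRUE)
  metals <- intersect(tab$parameter[tab$group == "metal"], rfd$parameter)
  p95 <- vapply(metals, function(par) {
    row <- tab[tab$parameter == par, ]
    ex <- sample_exposure(conc_spec_from_row(row), adult_male(),
                          n_iter = 20000, seed = 55L, parameter = par)
    hazard_quotient(ex, rfd$rfd[rfd$parameter == par])$summary[["p95"]]
  }, numeric(1))
  expect_true(all(p95[setdiff(metals, "Sr")] < 0.05))
  expect_gt(p95[["Sr"]], 0.1)
  expect_lt(p95[["Sr"]], 0.3)
})

test_that("relative exposure isolates scenario parameters via matched seeds", {
  sc <- default_scenarios()
  no3 <- lognormal_from_mean_sd(112, 74)
  expect_equal(relative_exposure(sc$adult_male, sc$adult_male, no3,
                                 n_iter = 2000, seed = 2L), 0)
  # female / male median intake ratio is governed by the body-weight ratio
  # 80/65, i.e. about +23 %
  fem <- relative_exposure(sc$adult_male, sc$adult_female, no3,
                           n_iter = 20000, seed = 2L)
  expect_gt(fem, 18); expect_lt(fem, 28)
  # statistic variants
  expect_type(relative_exposure(sc$adult_male, sc$child_1_3, no3,
                                statistic = "mean", n_iter = 2000, seed = 2L),
              "double")
  expect_error(relative_exposure(sc$adult_male, sc$adult_female, no3,
                                 statistic = "p500", n_iter = 100, seed = 1L),
               "statistic")
})

test_that("packaged reference doses load with their provenance messages", {
  expect_message(gaza_rfd(), "IRIS")
  rfd <- gaza_rfd(quiet = TRUE)
  expect_equal(rfd$rfd[rfd$parameter == "NO3"], 1.6)
  expect_equal(rfd$rfd[rfd$parameter == "Ag"], 0.005)
  alt <- alt_thresholds()
  expect_equal(alt$threshold[alt$parameter == "NO3"], 3.7)
  expect_equal(alt$threshold[alt$parameter == "F"], 0.05)
  expect_message(gaza_summary(), "Mn")
})
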