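# distribution specifications: parameterization, quantiles, fitting

test_that("moment matching reproduces target mean/sd and the implied median", {
  cases <- list(c(112, 74), c(1.1, 0.53), c(2.521, 2.049), c(5202, 5101),
                c(0.02, 0.001), c(180, 101))
  for (cs in cases) {
    spec <- lognormal_from_mean_sd(cs[1], cs[2])
    expect_equal(dist_mean(spec), cs[1], tolerance = 1e-10)
    expect_equal(dist_sd(spec), cs[2], tolerance = 1e-10)
    # closed-form median of the matched lognormal: mean^2 / sqrt(mean^2 + sd^2)
    expect_equal(dist_median(spec), cs[1]^2 / sqrt(cs[1]^2 + cs[2]^2),
                 tolerance = 1e-10)
  }
  # the nitrate survey row: implied median ~93.5, consistent with the
  # reported median of 93 mg/L
  no3 <- lognormal_from_mean_sd(112, 74)
  expect_equal(dist_median(no3), 93.44, tolerance = 1e-3)
})

test_that("median/P95 parameterization round-trips through its quantiles", {
  bw <- lognormal_from_median_p95(80, 100)
  expect_equal(bw$meanlog, 4.38203, tolerance = 1e-5)
  expect_equal(bw$sdlog, 0.135662, tolerance = 1e-5)
  child <- lognormal_from_median_p95(12.5, 20)
  expect_equal(child$meanlog, 2.52573, tolerance = 1e-5)
  expect_equal(child$sdlog, 0.285742, tolerance = 1e-5)
  for (spec in list(bw, child, lognormal_from_median_p95(65, 85))) {
    med <- exp(spec$meanlog)
    expect_equal(quantile(spec, 0.5), med, tolerance = 1e-10)
    expect_equal(quantile(spec, 0.95) / med,
                 quantile(spec, 0.95) / dist_median(spec), tolerance = 1e-10)
  }
  expect_equal(quantile(bw, 0.95), 100, tolerance = 1e-6)
  expect_equal(quantile(child, 0.95), 20, tolerance = 1e-6)
  expect_error(lognormal_from_median_p95(80, 80), "exceed")
  expect_error(lognormal_from_median_p95(80, 60), "exceed")
})

test_that("degenerate and invalid parameterizations are handled explicitly", {
  pm <- lognormal_from_mean_sd(5, 0)
  expect_true(pm$degenerate)
  expect_equal(dist_median(pm), 5)
  expect_equal(draw(pm, 4, u = c(0.1, 0.3, 0.7, 0.9)), rep(5, 4))
  zero <- lognormal_spec(-Inf, 0)
  expect_equal(draw(zero, 3, u = c(0.2, 0.5, 0.8)), rep(0, 3))
  expect_error(lognormal_from_mean_sd(0, 1), "positive")
  expect_error(lognormal_from_mean_sd(-3, 1), "positive")
  expect_error(lognormal_from_mean_sd(3, -1), ">= 0")
  expect_error(lognormal_spec(Inf, 1))
  expect_error(uniform_spec(0, 2), "0 < low < high")
  expect_error(uniform_spec(2, 0.5), "0 < low < high")
  expect_error(quantile(lognormal_spec(0, 1), 0), "inside")
  expect_error(quantile(uniform_spec(0.5, 2), 1), "inside")
  expect_error(quantile(lognormal_spec(0, 1), c(0.5, 1.2)), "inside")
})

test_that("analytic quantiles agree with reference distribution functions", {
  p <- c(0.01, 0.1, 0.25, 0.5, 0.75, 0.9, 0.99)
  ln <- lognormal_spec(1.3, 0.6)
  expect_equal(quantile(ln, p), qlnorm(p, 1.3, 0.6), tolerance = 1e-12)
  un <- uniform_spec(0.5, 2)
  expect_equal(quantile(un, p), qunif(p, 0.5, 2), tolerance = 1e-12)
  expect_equal(quantile(un, 0.5), 1.25)
  tri <- triangular_spec(0.25, 0.5, 1)
  # CDF(quantile(p)) = p, with the piecewise triangular CDF as oracle
  tri_cdf <- function(x) {
    ifelse(x < tri$mode,
           (x - tri$low)^2 / ((tri$high - tri$low) * (tri$mode - tri$low)),
           1 - (tri$high - x)^2 / ((tri$high - tri$low) * (tri$high - tri$mode)))
  }
  expect_equal(tri_cdf(quantile(tri, p)), p, tolerance = 1e-12)
})

test_that("fit_lognormal reproduces the sample log-moments", {
  # hand-computable three-point case
  spec <- fit_lognormal(c(1, exp(1), exp(2)))
  expect_equal(spec$meanlog, 1, tolerance = 1e-12)
  expect_equal(spec$sdlog, 1, tolerance = 1e-12)
  # parameter recovery on generated data
  x <- dwrisk:::with_seed(101, draw(lognormal_spec(1, 0.5), 10000))
  rec <- fit_lognormal(x)
  expect_equal(rec$meanlog, 1, tolerance = 0.02)
  expect_equal(rec$sdlog, 0.5, tolerance = 0.02)
  # degenerate and error cases
  expect_true(fit_lognormal(rep(3, 5))$degenerate)
  expect_error(fit_lognormal(c(2), censored = FALSE), "summary")
  expect_error(fit_lognormal(c(2, 4, 8), censored = c(TRUE, TRUE, FALSE)),
               "fewer than 2 detected")
  # censor substitution feeds the fit: <4 becomes 2 under the default policy
  spec <- fit_lognormal(c(10, 4, 6), censored = c(FALSE, TRUE, FALSE))
  expect_equal(spec$meanlog, mean(log(c(10, 2, 6))), tolerance = 1e-12)
})

test_that("fit_lognormal agrees with an independent maximum-likelihood fit", {
  x <- dwrisk:::with_seed(77, draw(lognormal_spec(0.5, 0.8), 2000))
  ours <- fit_lognormal(x)
  mle <- fitdistrplus::fitdist(x, "lnorm")
  expect_equal(ours$meanlog, unname(mle$estimate["meanlog"]), tolerance = 1e-3)
  expect_equal(ours$sdlog, unname(mle$estimate["sdlog"]), tolerance = 1e-3)
})

test_that("specs serialize to tagged lists and back", {
  specs <- list(lognormal_spec(1.2, 0.4), uniform_spec(0.25, 1),
                triangular_spec(0.5, 1, 2))
  for (s in specs) {
    s2 <- spec_from_list(spec_to_list(s))
    expect_equal(class(s2), class(s))
    expect_equal(quantile(s2, c(0.1, 0.5, 0.9)), quantile(s, c(0.1, 0.5, 0.9)))
  }
  expect_error(spec_from_list(list(type = "gamma")), "unknown spec type")
  expect_error(spec_from_list(list(low = 1)), "type")
})
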