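test_that("residual reports are self-consistent", {
  d <- tumor_data()
  start <- bp_params(1.62, 2.44, p = 5.02e-4, q = 5.55e-7, v0 = 318.5)
  fit <- polish_fit(c(1.62, 2.44), d, start)
  rep <- residual_report(fit, d)
  expect_equal(sum(rep$residuals^2), fit$sse, tolerance = 1e-6)
  expect_equal(rep$sd, sd(rep$residuals))
  expect_true(all(c(rep$sign_test_p, rep$anderson_darling_p,
                    rep$cramer_von_mises_p) >= 0))
  expect_true(all(c(rep$sign_test_p, rep$anderson_darling_p,
                    rep$cramer_von_mises_p) <= 1))
})

test_that("a perfectly interpolating curve has zero residuals", {
  truth <- bp_params(1, 2, p = 0.08, q = 4e-5, v0 = 120)
  syn <- generate_synthetic(truth, seq(0, 110, by = 10), noise_sd = 0)
  fit <- polish_fit(c(1, 2), syn, truth)
  rep <- residual_report(fit, syn)
  expect_equal(rep$sd, 0, tolerance = 1e-4)
  expect_equal(rep$sign_test_p, 1)
})

test_that("balanced residual signs give sign-test p = 1", {
  truth <- bp_params(1, 2, p = 0.08, q = 4e-5, v0 = 120)
  tt <- seq(0, 110, by = 10)
  v <- solve_curve(truth, tt)
  wiggle <- growth_dataset(tt, v + rep(c(1, -1), length.out = length(tt)))
  rep <- residual_report(truth, wiggle)
  expect_equal(rep$sign_test_p, 1)
})

test_that("splines are exact at knots and linear on collinear data", {
  d <- tumor_data()
  s <- spline_interpolate(d)
  expect_equal(s(d$times), d$volumes)
  lin <- growth_dataset(c(0, 10, 20, 30), c(100, 200, 300, 400))
  sl <- spline_interpolate(lin)
  expect_equal(sl(c(5, 15, 25)), c(150, 250, 350), tolerance = 1e-9)
})

test_that("spline midpoints match an independent natural-spline solver", {
  d <- tumor_data()
  s <- spline_interpolate(d)
  mid <- (head(d$times, -1) + tail(d$times, -1)) / 2
  expect_equal(s(mid), natural_spline_oracle(d$times, d$volumes, mid),
               tolerance = 1e-9)
})

test_that("spline growth rates recover known rates", {
  tt <- seq(0, 60, by = 2)
  expgrow <- growth_dataset(tt, exp(0.1 * tt))
  rates <- spline_rgr(expgrow, seq(10, 50, by = 5))
  expect_equal(rates, rep(0.1, 9), tolerance = 1e-3)
  flat <- growth_dataset(tt, rep(500, length(tt)))
  expect_equal(spline_rgr(flat, c(10, 30)), c(0, 0), tolerance = 1e-12)
  # central-difference cross-check on the tumor data at t = 50
  d <- tumor_data()
  s <- spline_interpolate(d)
  h <- 1e-4
  fd <- (s(50 + h) - s(50 - h)) / (2 * h) / s(50)
  r50 <- spline_rgr(d, 50)
  expect_gt(r50, 0)
  expect_equal(r50, fd, tolerance = 1e-6)
})

test_that("growth-rate envelopes collapse at threshold zero and nest", {
  d <- tumor_data()
  g <- grid_spec(spacing = 0.2, a_min = 1.0, a_max = 1.8, b_max = 2.8)
  ls <- sweep_grid(g, d, cfg_fast(seed = 23, f = 50L))
  tt <- seq(0, 114, by = 6)
  env0 <- rgr_envelope(ls, 0, tt)
  expect_equal(env0$lower, env0$best, tolerance = 1e-12)
  expect_equal(env0$upper, env0$best, tolerance = 1e-12)
  env1 <- rgr_envelope(ls, 0.01, tt)
  env5 <- rgr_envelope(ls, 0.05, tt)
  expect_true(all(env5$lower <= env5$best + 1e-12))
  expect_true(all(env5$best <= env5$upper + 1e-12))
  expect_true(all(env5$upper - env5$lower >= env1$upper - env1$lower - 1e-12))
})

test_that("prediction bands behave like t-based single-observation bands", {
  d <- tumor_data()
  start <- bp_params(1.62, 2.44, p = 5.02e-4, q = 5.55e-7, v0 = 318.5)
  fit <- polish_fit(c(1.62, 2.44), d, start)
  band95 <- prediction_band(fit, d, confidence = 0.95)
  expect_true(all(d$volumes >= band95$lower & d$volumes <= band95$upper))
  band99 <- prediction_band(fit, d, confidence = 0.99)
  expect_true(all(band99$lower <= band95$lower))
  expect_true(all(band99$upper >= band95$upper))
  # zero residual variance collapses the band onto the curve
  truth <- bp_params(1, 2, p = 0.08, q = 4e-5, v0 = 120)
  syn <- generate_synthetic(truth, seq(0, 110, by = 10), noise_sd = 0)
  pfit <- polish_fit(c(1, 2), syn, truth)
  pband <- prediction_band(pfit, syn)
  expect_lt(max(pband$upper - pband$lower), 1e-2)
})

test_that("band coverage is near nominal on seeded replicates", {
  d <- tumor_data()
  truth <- bp_params(1.62, 2.44, p = 5.02e-4, q = 5.55e-7, v0 = 318.5)
  covered <- 0L
  total <- 0L
  for (s in 1:200) {
    syn <- generate_synthetic(truth, d$times, noise_sd = 99, seed = 5000 + s)
    fit <- polish_fit(c(1.62, 2.44), syn, truth)
    band <- prediction_band(fit, syn, confidence = 0.95)
    covered <- covered + sum(syn$volumes >= band$lower &
                               syn$volumes <= band$upper)
    total <- total + length(syn)
  }
  expect_gte(covered / total, 0.90)
})

test_that("spline input validation", {
  short <- growth_dataset(c(0, 1), c(1, 2))
  expect_error(spline_interpolate(short), "at least 3")
})
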