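test_that("bp_rhs evaluates the growth law and its equilibrium", {
  pars <- bp_params(1.3, 2.7, p = 0.5, q = 0.2, v0 = 1)
  expect_equal(bp_rhs(1, pars), 0.3) # v^a = v^b = 1
  K <- (pars$p / pars$q)^(1 / (pars$b - pars$a))
  expect_equal(bp_rhs(K, pars), 0, tolerance = 1e-12)
  # direct single-expression arithmetic at the tumor best-fit parameters
  pars2 <- bp_params(1.62, 2.44, p = 5.02e-4, q = 5.55e-7, v0 = 318.5)
  expect_equal(bp_rhs(318.5, pars2), 4.9872264708852, tolerance = 1e-10)
  expect_error(bp_rhs(-1, pars), "positive")
  expect_error(bp_rhs(0, pars), "positive")
})

test_that("solve_curve matches the logistic closed form", {
  p <- 0.08
  q <- 4e-5
  v0 <- 120
  pars <- bp_params(1, 2, p = p, q = q, v0 = v0)
  tt <- seq(0, 200, by = 5)
  expect_equal(solve_curve(pars, tt), logistic_closed_form(p, q, v0, tt),
               tolerance = 1e-6)
  # anchoring at a nonzero first time
  tt2 <- seq(30, 200, by = 10)
  expect_equal(solve_curve(pars, tt2), logistic_closed_form(p, q, v0, tt2),
               tolerance = 1e-6)
})

test_that("solve_curve matches the bounded-exponential closed form", {
  p <- 30
  q <- 0.04
  v0 <- 100
  pars <- bp_params(0, 1, p = p, q = q, v0 = v0)
  tt <- seq(0, 200, by = 4)
  expect_equal(solve_curve(pars, tt), bounded_exp_closed_form(p, q, v0, tt),
               tolerance = 1e-6)
})

test_that("a curve started at the equilibrium stays constant", {
  pars <- bp_params(0.7, 1.9, p = 0.02, q = 0.02 / 800^1.2, v0 = 800)
  tt <- seq(0, 300, by = 10)
  expect_equal(solve_curve(pars, tt), rep(800, length(tt)), tolerance = 1e-9)
})

test_that("solve_curve agrees with an independent stiff ODE solver", {
  skip_if_not_installed("deSolve")
  cases <- list(
    bp_params(1.62, 2.44, p = 5.02e-4, q = 5.55e-7, v0 = 318.5),
    bp_params(1.34, 8.83, p = 2.27e-3, q = 2.28e-29, v0 = 323.5),
    bp_params(2 / 3, 1, p = 0.5, q = 0.05, v0 = 50)
  )
  tt <- seq(0, 114, by = 6)
  for (pars in cases) {
    ref <- deSolve::lsoda(
      y = c(u = log(pars$v0)), times = tt,
      func = function(t, y, parms) {
        list(pars$p * exp((pars$a - 1) * y) - pars$q * exp((pars$b - 1) * y))
      },
      rtol = 1e-10, atol = 1e-12
    )
    expect_equal(solve_curve(pars, tt), exp(ref[, "u"]),
                 tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("asymptotic and inflection volumes follow the ratio formulas", {
  # p = q logistic: asymptote 1
  expect_equal(asymptotic_volume(bp_params(1, 2, p = 0.3, q = 0.3, v0 = 0.5)),
               1)
  # logistic inflection at K/2
  pars <- bp_params(1, 2, p = 0.1, q = 1e-4, v0 = 50)
  expect_equal(inflection_volume(pars), asymptotic_volume(pars) / 2)
  # near-diagonal pair: huge but representable asymptote, direct arithmetic
  nd <- bp_params(0.68, 0.69, p = 0.185, q = 8.66e-3, v0 = 266.2)
  expect_equal(asymptotic_volume(nd), 9.23386750320133e132, tolerance = 1e-10)
  expect_error(inflection_volume(bp_params(0, 1, p = 1, q = 1, v0 = 1)),
               "a > 0")
})

test_that("inflection volume maximizes the growth rate (dense-scan oracle)", {
  for (pars in random_params(5, seed = 7)) {
    if (pars$a <= 0) next
    K <- asymptotic_volume(pars)
    grid <- seq(K * 1e-3, K * 0.999, length.out = 200000)
    scan <- grid[which.max(bp_rhs(grid, pars))]
    expect_equal(inflection_volume(pars), scan, tolerance = 1e-4)
  }
})

test_that("curves are positive, bounded and monotone", {
  tt <- seq(0, 250, length.out = 60)
  for (pars in random_params(12, seed = 11)) {
    v <- solve_curve(pars, tt)
    K <- asymptotic_volume(pars)
    expect_true(all(v > 0))
    expect_true(all(v <= max(pars$v0, K) * (1 + 1e-6)))
    if (pars$v0 < K) {
      # monotone ascent, up to roundoff once saturated at the asymptote
      expect_true(all(diff(v) >= -1e-6 * K))
      expect_gt(v[2], v[1])
    }
    # started above the asymptote the curve decays towards it
    pars_dn <- bp_params(pars$a, pars$b, p = pars$p, q = pars$q,
                         v0 = 1.5 * K)
    v_dn <- solve_curve(pars_dn, tt)
    expect_true(all(diff(v_dn) <= 1e-6 * K))
    expect_lt(v_dn[2], v_dn[1])
    expect_true(all(v_dn >= K * (1 - 1e-6)))
    # inflection below asymptote whenever defined
    if (pars$a > 0) {
      expect_lt(inflection_volume(pars), K)
    }
  }
})

test_that("relative growth rate matches numeric differentiation of log v", {
  pars <- bp_params(1.62, 2.44, p = 5.02e-4, q = 5.55e-7, v0 = 318.5)
  tt <- seq(5, 110, by = 5)
  h <- 1e-3
  num <- (log(solve_curve(pars, tt + h, t0 = 0)) -
            log(solve_curve(pars, tt - h, t0 = 0))) / (2 * h)
  expect_equal(relative_growth_rate(pars, tt, t0 = 0), num,
               tolerance = 1e-4)
  # zero at the asymptote
  K <- asymptotic_volume(pars)
  at_K <- bp_params(pars$a, pars$b, p = pars$p, q = pars$q, v0 = K)
  expect_equal(relative_growth_rate(at_K, c(0, 50)), c(0, 0),
               tolerance = 1e-10)
})

test_that("degenerate and invalid parameter sets are refused", {
  expect_error(exponent_pair(1, 1), "diagonal")
  expect_error(exponent_pair(2, 1), "diagonal")
  expect_error(exponent_pair(-0.5, 1), "finite")
  expect_error(bp_params(1, 2, p = -1, q = 1, v0 = 1), "positive")
  expect_error(bp_params(1, 2, p = 1, q = 0, v0 = 1), "positive")
  expect_error(solve_curve(bp_params(1, 2, p = 1, q = 1e-4, v0 = 10),
                           c(5, 1)), "sorted")
})

test_that("integration failure is flagged, not silent", {
  # absurd parameters: immediate overflow of the growth term
  bad <- bp_params(1.62, 2.44, p = 1e150, q = 1e-200, v0 = 300)
  expect_error(solve_curve(bad, c(0, 100)), "integration failed")
  v <- solve_curve(bad, c(0, 100), on_failure = "na")
  expect_true(all(is.na(v)))
  expect_true(attr(v, "failed"))
  expect_true(is.infinite(sse_of(bad, tumor_data())))
})
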