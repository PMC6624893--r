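# Shared fixtures and independent oracles for the test suite.

# small annealing budgets for tests; full budgets are exercised in the
# acceptance tests only
cfg_fast <- function(seed = 1L, f = 25L) {
  anneal_config(seed = seed, fast_factor = f)
}

tumor_data <- function() load_dataset("tumor")

# Verhulst (logistic) closed form: a = 1, b = 2, K = p/q,
# v(t) = K v0 e^{p t} / (K + v0 (e^{p t} - 1)), anchored at t = times[1]
logistic_closed_form <- function(p, q, v0, times) {
  K <- p / q
  tt <- times - times[1L]
  K * v0 * exp(p * tt) / (K + v0 * (exp(p * tt) - 1))
}

# bounded exponential closed form: a = 0, b = 1,
# v(t) = (p/q) (1 - d e^{-q t}) with d fixed by v(times[1]) = v0
bounded_exp_closed_form <- function(p, q, v0, times) {
  K <- p / q
  tt <- times - times[1L]
  d <- 1 - v0 / K
  K * (1 - d * exp(-q * tt))
}

# textbook natural cubic spline: second-derivative (M) formulation with
# M_1 = M_n = 0, solved as a dense linear system -- independent of
# stats::splinefun
natural_spline_oracle <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  A <- diag(n)
  rhs <- numeric(n)
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1] / 6
    A[i, i] <- (h[i - 1] + h[i]) / 3
    A[i, i + 1] <- h[i] / 6
    rhs[i] <- (y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]
  }
  M <- solve(A, rhs)
  vapply(xout, function(t) {
    j <- max(1L, min(n - 1L, findInterval(t, x)))
    dx1 <- x[j + 1] - t
    dx0 <- t - x[j]
    M[j] * dx1^3 / (6 * h[j]) + M[j + 1] * dx0^3 / (6 * h[j]) +
      (y[j] / h[j] - M[j] * h[j] / 6) * dx1 +
      (y[j + 1] / h[j] - M[j + 1] * h[j] / 6) * dx0
  }, numeric(1))
}

# random positive parameter sets with a finite, moderate asymptote
random_params <- function(n, seed) {
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- runif(1, 0.1, 1.6)
    b <- a + runif(1, 0.2, 1.4)
    K <- runif(1, 500, 5000)
    p <- 10^runif(1, -3, -1)
    q <- p / K^(b - a)
    v0 <- K * runif(1, 0.05, 0.9)
    out[[i]] <- bp_params(a, b, p = p, q = q, v0 = v0)
  }
  out
}
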