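test_that("grid enumeration stays above the diagonal and on the lattice", {
  g <- grid_spec(spacing = 0.1, a_min = 0, a_max = 0.5, b_max = 1)
  pairs <- grid_pairs(g)
  expect_true(all(pairs$b > pairs$a))
  expect_true(all(abs(pairs$a / 0.1 - round(pairs$a / 0.1)) < 1e-9))
  expect_true(all(abs(pairs$b / 0.1 - round(pairs$b / 0.1)) < 1e-9))
  # region mask carves the rectangle
  gm <- grid_spec(spacing = 0.1, a_max = 0.5, b_max = 1,
                  region_mask = function(a, b) b - a <= 0.3)
  expect_true(all(grid_pairs(gm)$b - grid_pairs(gm)$a <= 0.3 + 1e-9))
})

test_that("a single-pair sweep equals fit_pair", {
  d <- tumor_data()
  g <- grid_spec(spacing = 0.1, a_min = 1, a_max = 1, b_max = 1.1)
  ls <- sweep_grid(g, d, cfg_fast(seed = 17))
  expect_equal(nrow(ls$results), 1L)
  direct <- fit_pair(c(1, 1.1), d, cfg_fast(seed = 17))
  expect_equal(ls$results$sse, direct$sse)
  expect_equal(ls$results$p, direct$params$p)
})

test_that("near-optimal regions nest and contain the argmin", {
  d <- tumor_data()
  g <- grid_spec(spacing = 0.2, a_min = 0.6, a_max = 1.8, b_max = 2.8)
  ls <- sweep_grid(g, d, cfg_fast(seed = 4, f = 50L))
  bp <- best_pair(ls)
  r0 <- near_optimal_region(ls, 0)
  expect_equal(nrow(r0), 1L)
  expect_equal(c(r0$a, r0$b), c(bp$pair$a, bp$pair$b))
  r1 <- near_optimal_region(ls, 0.01)
  r5 <- near_optimal_region(ls, 0.05)
  r10 <- near_optimal_region(ls, 0.10)
  key <- function(r) paste(r$a, r$b)
  expect_true(all(key(r1) %in% key(r5)))
  expect_true(all(key(r5) %in% key(r10)))
  expect_true(key(r0) %in% key(r1))
  expect_gte(nrow(r10), nrow(r5))
  expect_gte(nrow(r5), nrow(r1))
})

test_that("best_pair breaks SSE ties lexicographically", {
  res <- data.frame(a = c(1.0, 0.5, 0.5), b = c(1.5, 2.0, 0.6),
                    v0 = 1, p = 1, q = 1, sse = c(10, 10, 10),
                    polished = TRUE, converged = TRUE)
  ls <- bpgrowth:::.new_landscape(res, grid_spec(spacing = 0.1), "tie")
  bp <- best_pair(ls)
  expect_equal(bp$pair$a, 0.5)
  expect_equal(bp$pair$b, 0.6)
})

test_that("landscape tables round-trip losslessly through CSV", {
  d <- tumor_data()
  g <- grid_spec(spacing = 0.2, a_min = 1.2, a_max = 1.6, b_max = 2.6)
  ls <- sweep_grid(g, d, cfg_fast(seed = 8, f = 50L))
  # inject an extreme q to exercise full-precision serialization
  ls$results$q[1] <- 2.28048131e-29
  path <- tempfile(fileext = ".csv")
  write_landscape(ls, path)
  back <- read_landscape(path, g)
  for (col in c("a", "b", "v0", "p", "q", "sse")) {
    expect_equal(back$results[[col]], ls$results[[col]], tolerance = 1e-15)
  }
  header <- readLines(path, n = 1L)
  expect_identical(header, "a,b,v0,p,q,sse")
})

test_that("region export tags pairs with their smallest threshold", {
  res <- data.frame(a = c(1, 1, 1), b = c(2, 3, 4), v0 = 1, p = 1, q = 1,
                    sse = c(100, 104, 109), polished = TRUE,
                    converged = TRUE)
  ls <- bpgrowth:::.new_landscape(res, grid_spec(), "toy")
  path <- tempfile(fileext = ".csv")
  out <- export_regions(ls, thresholds = c(0.01, 0.05, 0.10), path = path)
  expect_equal(out$threshold, c(0.01, 0.05, 0.10))
  expect_true(file.exists(path))
})

test_that("warm starts along b dominate short cold fits", {
  d <- tumor_data()
  g <- grid_spec(spacing = 0.1, a_min = 1.6, a_max = 1.6, b_max = 2.5)
  ls <- sweep_grid(g, d, cfg_fast(seed = 31, f = 10L))
  probe <- ls$results[ls$results$b >= 2.2, ]
  for (i in seq_len(nrow(probe))) {
    cold <- vapply(1:3, function(s) {
      anneal_fit(c(probe$a[i], probe$b[i]), d,
                 anneal_config(seed = 100 + s), steps = 1000L)$sse
    }, numeric(1))
    expect_lte(probe$sse[i], median(cold) * (1 + 1e-9))
  }
})

test_that("boundary extension recovers an optimum outside the initial grid", {
  truth <- bp_params(1, 2, p = 0.08, q = 4e-5, v0 = 120)
  syn <- generate_synthetic(truth, seq(0, 110, by = 10), noise_sd = 0)
  g <- grid_spec(spacing = 0.1, a_min = 0.9, a_max = 1.1, b_max = 1.6)
  ls <- sweep_grid(g, syn, cfg_fast(seed = 12, f = 50L))
  bp0 <- best_pair(ls)
  expect_gte(bp0$pair$b, 1.5) # pulled to the boundary
  ext <- extend_if_boundary(ls, syn, cfg_fast(seed = 13, f = 50L),
                            increment = 0.3, b_cap = 3)
  expect_gt(ext$grid$b_max, 1.6)
  bp1 <- best_pair(ext)
  expect_true(ext$secured)
  expect_equal(bp1$pair$b, 2, tolerance = 0.25)
  # an interior optimum leaves the landscape unchanged
  same <- extend_if_boundary(ext, syn, cfg_fast(seed = 14, f = 50L),
                             increment = 0.3, b_cap = 3)
  expect_identical(same$results, ext$results)
})

test_that("the smoothness screen flags an injected frayed entry", {
  d <- tumor_data()
  g <- grid_spec(spacing = 0.2, a_min = 1.0, a_max = 1.6, b_max = 2.6)
  ls <- sweep_grid(g, d, cfg_fast(seed = 19, f = 50L))
  sm <- landscape_smoothness(ls)
  expect_true(all(sm$ok))
  ls$results$sse[5] <- ls$results$sse[5] * 10
  sm2 <- landscape_smoothness(ls)
  expect_false(all(sm2$ok))
})
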