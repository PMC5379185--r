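kT300 <- 0.5962

test_that("unbiased Langevin sampling satisfies equipartition in a harmonic well", {
  # harmonic well as a degenerate double well? use a stiff quadratic via
  # mueller-free construction: reuse double_well_1d with tiny barrier is
  # messy, so build a bespoke harmonic swi_potential
  k_spring <- 3.0
  pot <- structure(list(kind = "double_well_1d", dim = 1L,
                        params = list(k = k_spring),
                        domain = list(c(-3, 3)), periodic = FALSE,
                        U = function(x) 0.5 * k_spring * x^2,
                        grad = function(x) k_spring * x),
                   class = "swi_potential")
  run <- langevin_sample(pot, kT = kT300, dt = 0.002, n_steps = 200000L,
                         friction = 1, x0 = 0, seed = 7, record_stride = 5L)
  v <- var(run$states[, 1])
  expected <- kT300 / k_spring
  # 3 standard errors with an effective sample size from autocorrelation
  rho <- acf(run$states[, 1], plot = FALSE, lag.max = 500)$acf
  tau <- 1 + 2 * sum(rho[rho > 0.05])
  n_eff <- nrow(run$states) / tau
  se <- expected * sqrt(2 / n_eff)
  expect_lt(abs(v - expected), 3 * se)
  # <U> = kT/2 per mode
  expect_equal(mean(0.5 * k_spring * run$states[, 1]^2), kT300 / 2,
               tolerance = 0.05)
})

test_that("zero-temperature dynamics stays at a minimum and seeds reproduce", {
  pot <- double_well_1d(barrier = 4, tilt = 2)
  xmin <- double_well_reference(pot, kT300)$x_min[1]
  frozen <- langevin_sample(pot, kT = 0, dt = 0.002, n_steps = 2000L,
                            x0 = xmin, seed = 1)
  # slack covers optimize()'s own x-tolerance on the oracle minimum
  expect_lt(max(abs(frozen$states[, 1] - xmin)), 1e-4)
  a <- langevin_sample(pot, kT = kT300, dt = 0.005, n_steps = 5000L,
                       seed = 42)
  b <- langevin_sample(pot, kT = kT300, dt = 0.005, n_steps = 5000L,
                       seed = 42)
  expect_identical(a$states, b$states)
  c2 <- langevin_sample(pot, kT = kT300, dt = 0.005, n_steps = 5000L,
                        seed = 43)
  expect_false(identical(a$states, c2$states))
})

test_that("the untempered limit deposits constant-height hills", {
  pot <- double_well_1d(barrier = 2, tilt = 1)
  run <- wt_metad(pot, cv_coordinate(1, range = c(-2.2, 2.2)), W = 0.1,
                  widths = 0.1, stride = 100L, bias_factor = Inf,
                  kT = kT300, dt = 0.005, n_steps = 20000L, x0 = -1,
                  seed = 3)
  expect_true(all(run$bias$hills$height == 0.1))
})

test_that("well-tempered hills shrink on revisits and decay like 1/t", {
  # single-well potential keeps the walker in one basin
  pot <- structure(list(kind = "double_well_1d", dim = 1L, params = list(),
                        domain = list(c(-3, 3)), periodic = FALSE,
                        U = function(x) 2 * x^2,
                        grad = function(x) 4 * x),
                   class = "swi_potential")
  run <- wt_metad(pot, cv_coordinate(1, range = c(-3, 3)), W = 0.1,
                  widths = 0.15, stride = 100L, bias_factor = 5,
                  kT = kT300, dt = 0.002, n_steps = 400000L, x0 = 0,
                  seed = 11)
  h <- run$bias$hills
  expect_true(all(h$height > 0 & h$height <= 0.1))
  # the tempered height at any fixed CV point is non-increasing in time,
  # because the accumulated bias there only grows
  v0 <- vapply(h$time, function(t) bias_value(run$bias, 0, t = t),
               numeric(1))
  implied <- 0.1 * exp(-v0 / ((5 - 1) * 0.5962))
  expect_true(all(diff(implied) <= 1e-12))
  central <- abs(h$center1) < 0.05
  hc <- h$height[central]
  # well-tempered asymptotics: hill height ~ t^(-1) at long times
  late <- h$time > quantile(h$time, 0.3)
  fit <- lm(log(height) ~ log(time), data = h[late & central, ])
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.15)
})

test_that("bias and reweighting estimators recover the double-well landscape", {
  pot <- double_well_calibrated(delta_g = 2.0, barrier = 4.0, kT = kT300)
  oracle <- pot$reference
  expect_equal(oracle$delta_g, 2.0, tolerance = 1e-6)
  expect_equal(oracle$barrier_left, 4.0, tolerance = 1e-6)
  run <- wt_metad(pot, cv_coordinate(1, range = c(-2.2, 2.2)), W = 0.1,
                  widths = 0.1, stride = 400L, bias_factor = 10,
                  kT = kT300, dt = 0.005, n_steps = 600000L,
                  x0 = oracle$x_min[1], seed = 12)
  fes_b <- find_basins_barriers(fes_from_bias(run$bias), min_depth = 1)
  fes_r <- find_basins_barriers(reweight(run), min_depth = 1)
  expect_equal(nrow(fes_b$basins) >= 2, TRUE)
  dg_b <- fes_b$delta_g["A", "B"]
  dg_r <- fes_r$delta_g["A", "B"]
  expect_equal(dg_b, oracle$delta_g, tolerance = 0.3 / oracle$delta_g)
  expect_equal(dg_r, oracle$delta_g, tolerance = 0.3 / oracle$delta_g)
  expect_lt(abs(dg_b - dg_r), 0.2)
  expect_lt(abs(fes_b$barriers["A", "B"] - oracle$barrier_left), 0.5)
  # grid argmin sits on the analytic minima
  expect_lt(abs(fes_b$basins$cv1[1] - oracle$x_min[1]), 0.1)
  expect_lt(abs(fes_b$basins$cv1[2] - oracle$x_min[2]), 0.1)
})

test_that("a null bias reduces reweighting to the unbiased histogram", {
  pot <- double_well_1d(barrier = 1.0, tilt = 0.3)
  run <- wt_metad(pot, cv_coordinate(1, range = c(-2.2, 2.2)), W = 1e-12,
                  widths = 0.1, stride = 200L, bias_factor = 10,
                  kT = kT300, dt = 0.005, n_steps = 100000L, x0 = -1,
                  seed = 5)
  w <- frame_weights(run)
  # all weights equal when the bias is negligible
  expect_lt(diff(range(w)) / mean(w), 1e-6)
  grid <- seq(-1.8, 1.8, length.out = 40)
  fes <- reweight(run, grid)
  hist_w <- table(factor(findInterval(run$cv_values[, 1],
                                      swiscape:::.centers_to_edges(grid),
                                      rightmost.closed = TRUE),
                         levels = seq_along(grid)))
  plain <- -kT300 * log(as.numeric(hist_w) / sum(hist_w))
  plain <- plain - min(plain[is.finite(plain)])
  expect_equal(fes$values[!fes$mask], plain[is.finite(plain)],
               tolerance = 1e-6)
})

test_that("reweighting onto a different observable matches unbiased sampling", {
  # bias |x| (symmetric CV), reweight onto x itself
  pot <- double_well_1d(barrier = 1.5, tilt = 0.5)
  cv_abs <- structure(list(name = "absx", value = function(x) abs(x[1]),
                           grad = function(x) sign(x[1]),
                           range = c(0, 2.2), periodic = FALSE),
                      class = "swi_cv")
  run <- wt_metad(pot, cv_abs, W = 0.05, widths = 0.1, stride = 200L,
                  bias_factor = 8, kT = kT300, dt = 0.005,
                  n_steps = 400000L, x0 = -1, seed = 6)
  unb <- langevin_sample(pot, kT = kT300, dt = 0.005, n_steps = 400000L,
                         x0 = -1, seed = 7)
  w <- frame_weights(run)
  xs <- run$states[, 1]
  # weighted empirical CDF vs unbiased empirical CDF on a grid
  grid <- seq(-2, 2, length.out = 81)
  cdf_w <- vapply(grid, function(g) sum(w[xs <= g]), numeric(1))
  cdf_u <- stats::ecdf(unb$states[, 1])(grid)
  expect_lt(max(abs(cdf_w - cdf_u)), 0.05)
})
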