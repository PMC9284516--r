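# Background correction, Tikhonov inversion, alpha selection, mode.

test_that("background fit recovers lambda and k from a clean trace", {
  p <- gaussian_distribution(2.25, 0.2)
  acq <- deer_acquisition(lambda = 0.3, k = 5e-4, noise_sd = 0)
  tr <- simulate_deer_trace(p, acq)
  bg <- fit_background(tr)
  expect_lt(abs(bg$lambda - 0.3), 0.02)
  expect_lt(abs(bg$k - 5e-4) / 5e-4, 0.05)
  expect_equal(bg$F[1], 1)
})

test_that("background fit degenerates informatively without modulation", {
  p <- gaussian_distribution(2.25, 0.2)
  tr <- simulate_deer_trace(p, deer_acquisition(lambda = 0, noise_sd = 1e-4,
                                                seed = 1))
  expect_error(fit_background(tr), "no dipolar modulation")
})

test_that("corrected form factor of a delta-distribution trace is the kernel", {
  r <- seq(1, 8, length.out = 201)
  delta <- distance_distribution(r, as.numeric(abs(r - 2.4) < 0.02))
  r0 <- r[abs(r - 2.4) < 0.02]
  tr <- simulate_deer_trace(delta, deer_acquisition(lambda = 0.5, k = 0,
                                                    noise_sd = 0.002, seed = 2))
  bg <- fit_background(tr)
  expect_lt(max(abs(bg$F - powder_kernel(bg$tau, r0))), 0.05)
})

test_that("Tikhonov solution equals brute-force QP enumeration on a coarse grid", {
  tau <- seq(0, 1000, by = 25)
  r <- seq(1.5, 4.5, length.out = 10)
  p0 <- gaussian_distribution(2.5, 0.4, r = r)
  set.seed(3)
  F <- form_factor(p0, tau) + rnorm(length(tau), 0, 0.02)
  for (alpha in c(0.01, 0.05, 0.5)) {
    oracle <- brute_force_tikhonov(F, tau, r, alpha)
    fit <- tikhonov_invert(F, tau, r, alpha)
    expect_lt(max(abs(attr(fit, "raw") - oracle)), 1e-6)
  }
})

test_that("inversion output is non-negative, normalized, mode on grid", {
  p <- gaussian_distribution(2.25, 0.2)
  tr <- simulate_deer_trace(p, deer_acquisition(seed = 5))
  bg <- fit_background(tr)
  sol <- tikhonov_invert(bg$F, bg$tau, alpha = 1)
  expect_true(all(sol$p >= 0))
  expect_equal(oligodeer:::trapz_(sol$r, sol$p), 1, tolerance = 1e-9)
  m <- distribution_mode(sol)
  expect_gte(as.numeric(m), min(sol$r))
  expect_lte(as.numeric(m), max(sol$r))
})

test_that("penalty norm is non-increasing in alpha", {
  p <- gaussian_distribution(2.25, 0.2)
  tr <- simulate_deer_trace(p, deer_acquisition(seed = 6))
  bg <- fit_background(tr)
  alphas <- 10^seq(-2, 2, length.out = 9)
  pen <- vapply(alphas, function(a)
    attr(tikhonov_invert(bg$F, bg$tau, alpha = a), "penalty_norm"), 0)
  expect_true(all(diff(pen) <= 1e-8))
})

test_that("a constant signal flags the no-signal case", {
  tau <- seq(0, 1990, by = 10)
  F <- rep(1, length(tau))
  sol <- tikhonov_invert(F, tau, alpha = 1)
  # all mass escapes to the long-distance edge where the kernel is flat
  expect_gt(as.numeric(distribution_mode(sol)), 7)
})

test_that("alpha selection is deterministic and favours small alpha without noise", {
  p <- gaussian_distribution(2.25, 0.2)
  tr <- simulate_deer_trace(p, deer_acquisition(seed = 7))
  bg <- fit_background(tr)
  a1 <- select_alpha(bg$F, bg$tau)
  a2 <- select_alpha(bg$F, bg$tau)
  expect_identical(as.numeric(a1), as.numeric(a2))
  tr0 <- simulate_deer_trace(p, deer_acquisition(noise_sd = 0))
  bg0 <- fit_background(tr0)
  a0 <- as.numeric(select_alpha(bg0$F, bg0$tau))
  grid <- 10^seq(-3, 2, length.out = 24)
  # corner sits in the small-alpha limb, far below the grid median
  expect_lte(a0, 0.05)
  expect_lte(a0, median(grid))
})

test_that("full fit recovers a Gaussian truth within the grid resolution", {
  truth <- gaussian_distribution(2.25, 0.2)
  tr <- simulate_deer_trace(truth, deer_acquisition(seed = 11))
  fit <- deer_fit(tr)
  expect_s3_class(fit, "deer_fit")
  expect_lt(abs(fit$mode_r - 2.25), 0.1)
  expect_lt(abs(fit$lambda - 0.3), 0.05)
  # methods are consistent
  expect_equal(unname(coef(fit)["mode_r"]), fit$mode_r)
  expect_equal(fitted(fit) + residuals(fit), fit$F)
  expect_length(predict(fit, "trace"), length(tr$t))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "deer_trace")
})

test_that("distribution mode handles analytic, tied and flat cases", {
  r <- seq(1, 8, length.out = 201)
  delta <- distance_distribution(r, as.numeric(abs(r - 2.2) < 0.02))
  expect_equal(as.numeric(distribution_mode(delta)), r[abs(r - 2.2) < 0.02])
  g <- gaussian_distribution(3.0, 0.4, r = seq(1, 8, by = 0.035))
  expect_lt(abs(as.numeric(distribution_mode(g)) - 3.0), 0.035 + 1e-9)
  bim <- distance_distribution(r, dnorm(r, 1.0, 0.1) + 1.5 * dnorm(r, 1.6, 0.1))
  expect_lt(abs(as.numeric(distribution_mode(bim)) - 1.6), 0.05)
  # ties break toward the smaller distance
  twopk <- distance_distribution(r, as.numeric(abs(r - 2) < 0.02) +
                                   as.numeric(abs(r - 5) < 0.02))
  expect_lt(as.numeric(distribution_mode(twopk)), 3)
  flat <- distance_distribution(r, rep(1, length(r)))
  expect_error(distribution_mode(flat), "flat")
})

test_that("trace file round trip preserves data and metadata", {
  p <- gaussian_distribution(2.25, 0.2)
  tr <- simulate_deer_trace(p, deer_acquisition(seed = 3))
  f <- tempfile()
  write_deer_trace(tr, f)
  back <- read_deer_trace(f)
  expect_equal(back$t, tr$t)
  expect_equal(back$v, tr$v, tolerance = 1e-9)
  meta <- attr(back, "metadata")
  expect_equal(meta$lambda, 0.3)
  expect_equal(meta$seed, 3)
})
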