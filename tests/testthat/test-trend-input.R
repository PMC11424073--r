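test_that("random walk generator is seeded, scaled, and degenerate-safe", {
  cfg <- trend_input_config(n_samples = 100, seed = 11)
  w1 <- simulate_random_walk(cfg)
  w2 <- simulate_random_walk(cfg)
  expect_identical(w1, w2)
  expect_equal(nrow(w1), 100)
  expect_equal(diff(w1$time), rep(cfg$sample_step, 99))

  flat <- simulate_random_walk(
    trend_input_config(diffusion = 0, n_samples = 10, initial_value = 3,
                       seed = 5))
  expect_equal(flat$value, rep(3, 10))

  # increment variance matches diffusion^2 * step analytically
  big <- simulate_random_walk(trend_input_config(n_samples = 1e5, seed = 2))
  expect_equal(var(diff(big$value)), 0.2^2 * 0.1, tolerance = 0.03)

  expect_error(trend_input_config(sample_step = 0), "sample_step")
  expect_error(trend_input_config(n_samples = 1), "n_samples")
})

test_that("affine normalization maps the range onto the band and keeps signs", {
  expect_equal(normalize_affine(as_series(c(0, 1)), 0.25, 0.75)$value,
               c(0.25, 0.75))
  expect_equal(normalize_affine(as_series(c(-2, -1, 0)), 0.25, 0.75)$value,
               c(0.25, 0.5, 0.75))
  expect_error(normalize_affine(as_series(c(2, 2, 2))), "constant")
  expect_error(normalize_affine(as_series(c(0, 1)), 0.75, 0.25), "strictly")

  w <- simulate_random_walk(trend_input_config(n_samples = 500, seed = 9))
  nw <- normalize_affine(w, 0.25, 0.75)
  expect_equal(sign(diff(nw$value)), sign(diff(w$value)))
  expect_equal(range(nw$value), c(0.25, 0.75))
})

test_that("EMA matches the hand recursion and its boundary behaviour", {
  s <- as_series(c(0, 1, 1))
  expect_equal(ema_smooth(s, 0.5)$value, c(0, 0.5, 0.75))
  expect_equal(ema_smooth(s, 0)$value, s$value)
  expect_equal(ema_smooth(s, 0.5, init = 2)$value, c(1, 1, 1))
  expect_error(ema_smooth(s, 1), "memory")
  expect_error(ema_smooth(s, -0.1), "memory")

  v <- rnorm(200)
  expect_equal(ema_smooth(as_series(v), 0.73)$value, ema_loop(v, 0.73))

  const <- as_series(rep(4, 50))
  expect_equal(ema_smooth(const, 0.9)$value, rep(4, 50))
})

test_that("EMA increments of a random walk form AR(1) with the memory weight", {
  for (m in c(0.3, 0.8)) {
    cfg <- trend_input_config(n_samples = 1e5, memory = m, seed = 21)
    u <- ema_smooth(simulate_random_walk(cfg), m)
    du <- diff(u$value)
    rho <- cor(du[-length(du)], du[-1])
    expect_equal(rho, m, tolerance = 0.01)
  }
})

test_that("full input pipeline stays in the band and is reproducible", {
  cfg <- trend_input_config(seed = 7)
  u <- make_trend_input(cfg)
  expect_true(all(u$value >= 0.25 & u$value <= 0.75))
  expect_identical(u, make_trend_input(cfg))
})

test_that("sign persistence counts matching consecutive increment signs", {
  expect_equal(sign_persistence(as_series(1:10)), 1)
  expect_equal(sign_persistence(as_series(c(0, 1, 0, 1, 0, 1))), 0)
  expect_error(sign_persistence(as_series(c(1, 2))), "3 samples")
  # pairs containing an exact-zero increment are dropped
  expect_equal(sign_persistence(as_series(c(0, 1, 1, 2, 3))), 1)
})

test_that("pipeline sign persistence approaches the orthant probability", {
  cfg <- trend_input_config(n_samples = 1e5, memory = 0.8, seed = 31)
  p <- sign_persistence(make_trend_input(cfg))
  expect_equal(p, theoretical_sign_match(0.8), tolerance = 0.01)
})

test_that("orthant probability formula is exact and matches Monte Carlo", {
  expect_identical(theoretical_sign_match(0), 0.5)
  expect_identical(theoretical_sign_match(1), 1)
  expect_equal(theoretical_sign_match(0.8), 0.79517, tolerance = 1e-5)
  expect_error(theoretical_sign_match(1.1), "rho")

  rho <- 0.8
  sims <- withr::with_seed(42, {
    z1 <- rnorm(1e6)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(1e6)
    mean(sign(z1) == sign(z2))
  })
  expect_equal(sims, theoretical_sign_match(rho), tolerance = 0.002)
})

test_that("linear interpolation honours samples, midpoints, and range", {
  s <- tibble::tibble(time = c(0, 1, 3), value = c(0, 2, -2))
  expect_equal(interpolate_series(s, c(0, 1, 3)), c(0, 2, -2))
  expect_equal(interpolate_series(s, 0.5), 1)
  expect_equal(interpolate_series(s, 2), 0)
  expect_error(interpolate_series(s, 3.5), "range")
  expect_error(interpolate_series(s, -0.1), "range")
})

test_that("delta-convention helper exposes both readings", {
  expect_equal(memory_from_delta(0.2), 0.8)
  expect_equal(memory_from_delta(0.2, "literal"), 0.2)
})
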