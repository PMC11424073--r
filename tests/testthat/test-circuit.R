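test_that("segment solution matches hand results and quadrature", {
  expect_equal(segment_solution(2.5, 1, 1, 1, 1, 0), 2.5)
  expect_equal(segment_solution(0, a = 1, b = 0, gain = 1, decay = 1,
                                dt = log(2)), 0.5)
  # ramp input: z(t) = t - 1 + e^{-t} at gain = decay = 1
  expect_equal(segment_solution(0, a = 0, b = 1, gain = 1, decay = 1, dt = 1),
               exp(-1), tolerance = 1e-12)
  expect_error(segment_solution(0, 1, 0, 1, 0, 1), "decay")

  cases <- withr::with_seed(13, replicate(20, list(
    x0 = rnorm(1), a = rnorm(1), b = rnorm(1),
    gain = runif(1, 0.1, 3), decay = runif(1, 0.1, 3),
    dt = runif(1, 0, 2)), simplify = FALSE))
  for (cs in cases) {
    expect_equal(
      segment_solution(cs$x0, cs$a, cs$b, cs$gain, cs$decay, cs$dt),
      quadrature_oracle(cs$x0, cs$a, cs$b, cs$gain, cs$decay, cs$dt),
      tolerance = 1e-9)
  }
})

test_that("constant input drives both states to alpha * c / beta", {
  p <- circuit_params(0.4, 0.05, 0.3)
  for (c_in in c(1, 2.5)) {
    u <- as_series(rep(c_in, 60))
    # start far from equilibrium; horizon 20/(gamma*beta) model time
    horizon <- 20 / (p$gamma * p$beta)
    traj <- integrate_circuit(u, p, init = c(10, -5),
                              time_per_sample = horizon / 59)
    expect_equal(traj$x[60], p$alpha * c_in / p$beta, tolerance = 1e-6)
    expect_equal(traj$y[60], p$alpha * c_in / p$beta, tolerance = 1e-6)
  }
})

test_that("gamma = 1 with equal starts collapses the two states", {
  u <- make_trend_input(trend_input_config(n_samples = 80, seed = 3))
  traj <- integrate_circuit(u, circuit_params(0.3, 0.1, 1))
  expect_equal(traj$x, traj$y, tolerance = 1e-12)
  expect_equal(traj$d, rep(0, 80), tolerance = 1e-12)
})

test_that("exact segment integrator agrees with fine-step Euler", {
  expect_lt(max_euler_discrepancy(100, seed_base = 500), 1e-6)
})

test_that("integrate_circuit chains segment_solution exactly", {
  u <- make_trend_input(trend_input_config(n_samples = 40, seed = 8))
  p <- preset_params("accuracy")
  dt <- 100
  traj <- integrate_circuit(u, p, time_per_sample = dt)
  x <- p$alpha * u$value[1] / p$beta
  y <- x
  for (k in 1:39) {
    a <- u$value[k]
    b <- (u$value[k + 1] - u$value[k]) / dt
    x <- segment_solution(x, a, b, p$alpha, p$beta, dt)
    y <- segment_solution(y, a, b, p$gamma * p$alpha, p$gamma * p$beta, dt)
    expect_equal(traj$x[k + 1], x, tolerance = 1e-12)
    expect_equal(traj$y[k + 1], y, tolerance = 1e-12)
  }
})

test_that("the circuit is linear in its input", {
  u <- make_trend_input(trend_input_config(n_samples = 100, seed = 17))
  p <- preset_params("accuracy")
  k <- 3.7
  u_scaled <- dplyr::mutate(u, value = k * value)
  t1 <- integrate_circuit(u, p)
  t2 <- integrate_circuit(u_scaled, p)
  expect_equal(t2$x, k * t1$x, tolerance = 1e-10)
  expect_equal(t2$y, k * t1$y, tolerance = 1e-10)
  expect_equal(t2$d, k * t1$d, tolerance = 1e-10)
})

test_that("monotone rising input keeps the fast average above the slow one", {
  u <- as_series(seq(0, 1, length.out = 200))
  traj <- integrate_circuit(u, circuit_params(0.2, 0.1, 0.3),
                            time_per_sample = 1)
  expect_true(all(traj$d[51:200] > 0))
})

test_that("momentum signal is odd, bounded, strictly increasing, exact at 0", {
  expect_identical(momentum_signal(0), 0)
  d <- withr::with_seed(4, rnorm(200, sd = 5))
  expect_equal(momentum_signal(-d), -momentum_signal(d), tolerance = 1e-12)
  expect_true(all(abs(momentum_signal(d)) < 500))
  expect_equal(momentum_signal(c(-1e6, 1e6)), c(-500, 500))
  grid <- sort(d)
  expect_true(all(diff(momentum_signal(grid)) > 0))
  # frozen high-precision logistic evaluation at d = 0.01
  expect_equal(momentum_signal(0.01), 2.4999792, tolerance = 1e-6)
})

test_that("direction prediction follows sign(d) with carry-forward ties", {
  traj <- tibble::tibble(d = c(0, 2, -1, 0, 0, 3))
  expect_identical(predict_direction(traj), c(1L, 1L, -1L, -1L, -1L, 1L))
  expect_identical(predict_direction(tibble::tibble(d = c(2, -1)), 2), -1L)
  expect_error(predict_direction(tibble::tibble(d = 1), 2), "range")
})

test_that("trajectory TSV round-trips at full precision", {
  u <- make_trend_input(trend_input_config(n_samples = 30, seed = 5))
  traj <- integrate_circuit(u, preset_params("accuracy"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_tsv(traj, path)
  back <- read_trajectory_tsv(path)
  for (col in c("time", "u", "x", "y", "d", "s")) {
    expect_equal(back[[col]], traj[[col]], tolerance = 1e-12)
  }
})
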