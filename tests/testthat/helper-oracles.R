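# Independent oracles used to cross-check the package's closed-form
# integrators and statistics. Deliberately naive implementations.

# Fine-step forward-Euler integration of z' = gain * u(t) - decay * z
# against a piecewise-linear input: each of the n-1 segments spans `dt`
# time units subdivided into steps of length <= step. The Euler update
# z_{j+1} = (1 - decay h) z_j + h gain u_j is a first-order linear
# recurrence, so it is evaluated at C speed with stats::filter; the
# scheme itself stays plain explicit Euler. Being first order, its
# global error scales like step * |z''|, hence the tiny default step.
euler_oracle <- function(u, gain, decay, dt, z0, step = 5e-7) {
  n <- length(u)
  z <- numeric(n)
  z[1] <- z0
  for (k in seq_len(n - 1)) {
    m <- ceiling(dt / step)
    h <- dt / m
    tau <- (seq_len(m) - 1) * h
    uu <- u[k] + (u[k + 1] - u[k]) * tau / dt
    zs <- stats::filter(h * gain * uu, 1 - decay * h,
                        method = "recursive", init = z[k])
    z[k + 1] <- zs[m]
  }
  z
}

# One randomized small integration case for the Euler agreement check:
# parameters kept in ranges where the first-order Euler error bound
# (step/2 * max|z''| * min(T, 1/decay)) stays well below 1e-6.
random_euler_case <- function(seed) {
  withr::with_seed(seed, {
    gain <- runif(1, 0.1, 1)
    decay <- runif(1, 0.5, 2)
    dt <- runif(1, 0.1, 0.2)
    b <- runif(3, -1, 1)                  # per-segment input slopes
    u0 <- runif(1, -1, 1)
    u <- u0 + c(0, cumsum(b * dt))
    z0 <- gain * u0 / decay + runif(1, -0.5, 0.5)
    list(u = u, gain = gain, decay = decay, dt = dt, z0 = z0)
  })
}

max_euler_discrepancy <- function(n_cases, seed_base) {
  worst <- 0
  for (i in seq_len(n_cases)) {
    cs <- random_euler_case(seed_base + i)
    exact <- trendcircuit:::segment_chain(cs$u, cs$gain, cs$decay, cs$dt,
                                          cs$z0)
    euler <- euler_oracle(cs$u, cs$gain, cs$decay, cs$dt, cs$z0)
    worst <- max(worst, max(abs(exact - euler)))
  }
  worst
}

# Quadrature evaluation of the driven-decay solution
# z(dt) = z0 e^{-k dt} + \int_0^dt e^{-k(dt - tau)} g (a + b tau) dtau
quadrature_oracle <- function(x0, a, b, gain, decay, dt) {
  integrand <- function(tau) exp(-decay * (dt - tau)) * gain * (a + b * tau)
  x0 * exp(-decay * dt) +
    stats::integrate(integrand, 0, dt, rel.tol = 1e-12)$value
}

# Hand-rolled EMA recursion (loop form), init at the first sample.
ema_loop <- function(v, memory) {
  out <- numeric(length(v))
  out[1] <- v[1]
  for (t in seq_along(v)[-1]) {
    out[t] <- (1 - memory) * v[t] + memory * out[t - 1]
  }
  out
}

as_series <- function(value, time = seq_along(value)) {
  tibble::tibble(time = time, value = value)
}
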