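#' Configuration for the stochastic trend generator
#'
#' Bundles every knob of the input pipeline: a Wiener random walk sampled at
#' discrete steps, affine normalization of each realized sequence to a fixed
#' band, and exponential smoothing that turns the memoryless walk into a
#' trending signal. The defaults are the reproduction preset used throughout
#' the package: diffusion 0.2 sampled at step 0.1, sequences of 1,000 samples
#' normalized to \[0.25, 0.75\], smoothing memory 0.8.
#'
#' `memory` is the weight on the *previous* smoothed value, so it equals the
#' persistence (lag-1 autocorrelation) of the smoothed increments when the raw
#' input is a random walk. See [memory_from_delta()] for converting a
#' smoothing constant quoted under the opposite convention.
#'
#' @param diffusion Wiener scale (standard deviation per unit square-root
#'   time), `>= 0`.
#' @param sample_step Time between consecutive samples, `> 0`.
#' @param n_samples Number of samples per sequence, `>= 2`.
#' @param norm_lo,norm_hi Normalization band; `norm_lo < norm_hi`.
#' @param memory Exponential-smoothing weight on the previous smoothed value,
#'   in `[0, 1)`.
#' @param initial_value Starting level of the raw walk.
#' @param seed Integer seed; the generator is a pure function of the config,
#'   seed included.
#' @return A list of class `trend_input_config`.
#' @examples
#' cfg <- trend_input_config(seed = 1)
#' u <- make_trend_input(cfg)
#' range(u$value)
#' @export
trend_input_config <- function(diffusion = 0.2,
                               sample_step = 0.1,
                               n_samples = 1000,
                               norm_lo = 0.25,
                               norm_hi = 0.75,
                               memory = 0.8,
                               initial_value = 0,
                               seed = 1L) {
  check_number(diffusion, "diffusion", lo = 0)
  check_number(sample_step, "sample_step", lo = 0, strict = TRUE)
  check_count(n_samples, "n_samples", min = 2)
  check_number(norm_lo, "norm_lo")
  check_number(norm_hi, "norm_hi")
  if (!(norm_lo < norm_hi)) {
    abort("`norm_lo` must be strictly less than `norm_hi`.")
  }
  check_number(memory, "memory", lo = 0)
  if (memory >= 1) {
    abort("`memory` must lie in [0, 1): memory = 1 would never update.")
  }
  check_number(initial_value, "initial_value")
  check_count(seed, "seed", min = -.Machine$integer.max)
  structure(
    list(
      diffusion = diffusion, sample_step = sample_step,
      n_samples = as.integer(n_samples),
      norm_lo = norm_lo, norm_hi = norm_hi,
      memory = memory, initial_value = initial_value,
      seed = as.integer(seed)
    ),
    class = "trend_input_config"
  )
}

#' @export
print.trend_input_config <- function(x, ...) {
  cat("<trend_input_config>\n")
  cat(sprintf("  walk: diffusion %g, step %g, %d samples, start %g, seed %d\n",
              x$diffusion, x$sample_step, x$n_samples, x$initial_value,
              x$seed))
  cat(sprintf("  normalize to [%g, %g]; smoothing memory %g\n",
              x$norm_lo, x$norm_hi, x$memory))
  invisible(x)
}

#' Convert a smoothing constant between the two EMA conventions
#'
#' Exponential moving averages are written both as
#' `o_t = (1 - m) input_t + m o_{t-1}` (weight `m` on the previous value,
#' this package's `memory`) and with the roles of the two weights swapped.
#' Given a quoted constant `delta`, returns the `memory` under either reading.
#'
#' @param delta Quoted smoothing constant in `[0, 1]`.
#' @param convention `"weight-on-new"` (the quoted value multiplies the new
#'   observation, so `memory = 1 - delta`; the reproduction preset treats the
#'   quoted 0.2 this way) or `"literal"` (`memory = delta`).
#' @return The memory weight on the previous smoothed value.
#' @examples
#' memory_from_delta(0.2)            # 0.8
#' memory_from_delta(0.2, "literal") # 0.2
#' @export
memory_from_delta <- function(delta,
                              convention = c("weight-on-new", "literal")) {
  check_number(delta, "delta", lo = 0, hi = 1)
  convention <- match.arg(convention)
  if (convention == "weight-on-new") 1 - delta else delta
}

validate_series <- function(series, arg = "series", min_len = 2L) {
  if (!is.data.frame(series) || !all(c("time", "value") %in% names(series))) {
    abort(sprintf("`%s` must be a data frame with columns `time` and `value`.",
                  arg))
  }
  if (nrow(series) < min_len) {
    abort(sprintf("`%s` needs at least %d samples, got %d.",
                  arg, min_len, nrow(series)))
  }
  if (!all(is.finite(series$time)) || !all(is.finite(series$value))) {
    abort(sprintf("`%s` contains non-finite times or values.", arg))
  }
  if (any(diff(series$time) <= 0)) {
    abort(sprintf("`%s` times must be strictly increasing.", arg))
  }
  invisible(series)
}

#' Simulate a sampled Wiener random walk
#'
#' Generates `n_samples` points at spacing `sample_step`; increments are
#' independent Gaussian with mean 0 and variance `diffusion^2 * sample_step`.
#' Identical configs (seed included) give bit-identical output.
#'
#' @param config A [trend_input_config()].
#' @return A tibble with columns `time`, `value`.
#' @examples
#' w <- simulate_random_walk(trend_input_config(n_samples = 5, seed = 7))
#' w
#' @export
simulate_random_walk <- function(config) {
  stopifnot(inherits(config, "trend_input_config"))
  n <- config$n_samples
  incr_sd <- config$diffusion * sqrt(config$sample_step)
  steps <- withr::with_seed(config$seed, rnorm(n - 1L, mean = 0, sd = incr_sd))
  tibble(
    time = (seq_len(n) - 1L) * config$sample_step,
    value = config$initial_value + cumsum(c(0, steps))
  )
}

#' Affinely rescale a series to a fixed band
#'
#' Maps the minimum value to `lo` and the maximum to `hi` through a single
#' positive-slope affine map, so the sign of every increment is preserved.
#' A constant series has no usable range and is an error rather than a silent
#' midpoint fill, which would corrupt downstream accuracy statistics.
#'
#' @param series A time-series data frame (`time`, `value`).
#' @param lo,hi Target band, `lo < hi`.
#' @return A tibble with the same times and rescaled values.
#' @examples
#' normalize_affine(tibble::tibble(time = 0:2, value = c(-2, -1, 0)), 0.25, 0.75)
#' @export
normalize_affine <- function(series, lo = 0.25, hi = 0.75) {
  validate_series(series)
  check_number(lo, "lo"); check_number(hi, "hi")
  if (!(lo < hi)) abort("`lo` must be strictly less than `hi`.")
  r <- range(series$value)
  if (r[1] == r[2]) {
    abort("Cannot normalize a constant series: value range is zero.")
  }
  tibble(
    time = series$time,
    value = lo + (series$value - r[1]) * (hi - lo) / (r[2] - r[1])
  )
}

#' Exponential moving average of a series
#'
#' Applies the recursion `o_t = (1 - memory) * value_t + memory * o_{t-1}`.
#' By default the recursion starts at the first sample (`o_0` = first value),
#' which avoids a startup transient; pass a number to start elsewhere. Output
#' values stay within the convex hull of the initial value and the inputs.
#'
#' @param series A time-series data frame (`time`, `value`).
#' @param memory Weight on the previous smoothed value, in `[0, 1)`.
#' @param init `"first-sample"` (default) or a finite number.
#' @return A tibble with the same times and smoothed values.
#' @examples
#' ema_smooth(tibble::tibble(time = 0:2, value = c(0, 1, 1)), memory = 0.5)
#' @export
ema_smooth <- function(series, memory, init = "first-sample") {
  validate_series(series)
  check_number(memory, "memory", lo = 0)
  if (memory >= 1) abort("`memory` must lie in [0, 1).")
  v <- series$value
  o0 <- if (identical(init, "first-sample")) v[1] else {
    check_number(init, "init")
    init
  }
  if (memory == 0) {
    out <- v
  } else {
    # o_t = (1-m) v_t + m o_{t-1}: a first-order recursive filter
    out <- as.numeric(stats::filter((1 - memory) * v, memory,
                                    method = "recursive", init = o0))
  }
  tibble(time = series$time, value = out)
}

#' Generate one smoothed, normalized trend sequence
#'
#' The full input pipeline: simulate the Wiener walk, normalize it to
#' `[norm_lo, norm_hi]`, then exponentially smooth with weight `memory`.
#' All values lie within the normalization band.
#'
#' @param config A [trend_input_config()].
#' @return A tibble with columns `time`, `value`.
#' @examples
#' u <- make_trend_input(trend_input_config(seed = 42))
#' all(u$value >= 0.25 & u$value <= 0.75)
#' @export
make_trend_input <- function(config) {
  stopifnot(inherits(config, "trend_input_config"))
  simulate_random_walk(config) |>
    normalize_affine(config$norm_lo, config$norm_hi) |>
    ema_smooth(config$memory)
}

#' Sign persistence of a series' increments
#'
#' The fraction of consecutive increment pairs that share sign — the frequency
#' with which the most recent direction of change predicts the next one. For
#' the smoothed random-walk input this is the best hit rate any predictor can
#' achieve, i.e. the maximum potential accuracy. Pairs containing an
#' exact-zero increment are excluded from numerator and denominator (a
#' measure-zero event under continuous noise).
#'
#' @param series A time-series data frame with at least 3 samples.
#' @return A frequency in `[0, 1]` (`NaN` if every pair contains a zero
#'   increment).
#' @seealso [theoretical_sign_match()] for the analytic ceiling.
#' @examples
#' sign_persistence(tibble::tibble(time = 1:5, value = c(1, 2, 3, 4, 5)))
#' @export
sign_persistence <- function(series) {
  validate_series(series, min_len = 3L)
  d <- diff(series$value)
  s_prev <- sign(d[-length(d)])
  s_next <- sign(d[-1])
  keep <- s_prev != 0 & s_next != 0
  mean(s_prev[keep] == s_next[keep])
}

#' Probability that correlated Gaussian variates share sign
#'
#' For two standard bivariate-normal variates with correlation `rho`, the
#' probability both are positive or both negative is
#' `1/2 + asin(rho) / pi` (the orthant probability). Smoothed random-walk
#' increments form an AR(1) process whose lag-1 autocorrelation equals the
#' smoothing memory, so this gives the analytic maximum potential accuracy of
#' the trend input: `theoretical_sign_match(0.8)` is about 0.795.
#'
#' @param rho Correlation in `[-1, 1]` (vectorized).
#' @return Probability in `[0, 1]`.
#' @examples
#' theoretical_sign_match(c(0, 0.8, 1))
#' @export
theoretical_sign_match <- function(rho) {
  if (!is.numeric(rho) || any(!is.finite(rho)) || any(abs(rho) > 1)) {
    abort("`rho` must be numeric with |rho| <= 1.")
  }
  0.5 + asin(rho) / pi
}

#' Linearly interpolate a series
#'
#' Values between samples are obtained by linear interpolation between the
#' bracketing points; at a sample time the sample's value is returned exactly.
#' Times outside the series' range are an error (no extrapolation).
#'
#' @param series A time-series data frame (`time`, `value`).
#' @param t Time point(s) within `[min(time), max(time)]`.
#' @return Interpolated value(s).
#' @examples
#' interpolate_series(tibble::tibble(time = c(0, 1), value = c(0, 2)), 0.5)
#' @export
interpolate_series <- function(series, t) {
  validate_series(series)
  if (!is.numeric(t) || any(!is.finite(t))) abort("`t` must be finite.")
  tr <- range(series$time)
  if (any(t < tr[1]) || any(t > tr[2])) {
    abort(sprintf("`t` outside the series' time range [%g, %g].",
                  tr[1], tr[2]))
  }
  approx(series$time, series$value, xout = t, method = "linear")$y
}

check_number <- function(x, name, lo = -Inf, hi = Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict) x > lo else x >= lo) && x <= hi
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number%s.", name,
                  if (is.finite(lo) || is.finite(hi)) {
                    sprintf(" in %s%g, %g]", if (strict) "(" else "[", lo, hi)
                  } else ""))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    x == round(x) && x >= min
  if (!ok) {
    abort(sprintf("`%s` must be an integer >= %g.", name, min))
  }
  invisible(x)
}
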