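#' Configuration for circuit parameter optimization
#'
#' Fixes everything the optimizer needs: the objective (`"accuracy"` — mean
#' prediction accuracy — or `"robust"` — accuracy plus
#' `robustness_weight * mean |x - y|`), the seeded training ensemble, the
#' starting point, and Nelder-Mead controls. The training sequences are fixed
#' once from the seed (common random numbers), so the objective is a
#' deterministic function of the parameters and the simplex search is
#' well-posed.
#'
#' @param objective `"accuracy"` or `"robust"`.
#' @param robustness_weight Weight on the mean signal width, `>= 0`; used by
#'   the `"robust"` objective (0 reduces it to the accuracy objective).
#' @param n_training_sequences Sequences in the training ensemble.
#' @param sequence_length Samples per sequence (overrides the input config).
#' @param input_config A [trend_input_config()].
#' @param initial_params Starting [circuit_params()].
#' @param n_restarts Nelder-Mead restarts from jittered starts, `>= 1`.
#' @param seed Master seed for training sequences and restart jitter.
#' @param max_iterations Nelder-Mead iteration cap per restart.
#' @param tolerance Relative convergence tolerance.
#' @param burn_in Leading samples excluded from scoring.
#' @param time_per_sample Model time per inter-sample interval.
#' @param n_heldout Sequences in the held-out evaluation ensemble.
#' @return A list of class `optimization_config`.
#' @export
optimization_config <- function(objective = c("accuracy", "robust"),
                                robustness_weight = 0,
                                n_training_sequences = 30L,
                                sequence_length = 1000L,
                                input_config = trend_input_config(),
                                initial_params = circuit_params(0.1, 0.1, 0.5),
                                n_restarts = 5L,
                                seed = 1L,
                                max_iterations = 300L,
                                tolerance = 1e-8,
                                burn_in = 20L,
                                time_per_sample = 100,
                                n_heldout = 100L) {
  objective <- match.arg(objective)
  check_number(robustness_weight, "robustness_weight", lo = 0)
  check_count(n_training_sequences, "n_training_sequences", min = 1)
  check_count(sequence_length, "sequence_length", min = 25)
  stopifnot(inherits(input_config, "trend_input_config"),
            inherits(initial_params, "circuit_params"))
  check_count(n_restarts, "n_restarts", min = 1)
  check_count(seed, "seed", min = -.Machine$integer.max)
  check_count(max_iterations, "max_iterations", min = 1)
  check_number(tolerance, "tolerance", lo = 0, strict = TRUE)
  check_count(burn_in, "burn_in", min = 1)
  check_number(time_per_sample, "time_per_sample", lo = 0, strict = TRUE)
  check_count(n_heldout, "n_heldout", min = 1)
  input_config$n_samples <- as.integer(sequence_length)
  structure(
    list(objective = objective, robustness_weight = robustness_weight,
         n_training_sequences = as.integer(n_training_sequences),
         sequence_length = as.integer(sequence_length),
         input_config = input_config, initial_params = initial_params,
         n_restarts = as.integer(n_restarts), seed = as.integer(seed),
         max_iterations = as.integer(max_iterations), tolerance = tolerance,
         burn_in = as.integer(burn_in), time_per_sample = time_per_sample,
         n_heldout = as.integer(n_heldout)),
    class = "optimization_config"
  )
}

training_inputs <- function(config) {
  purrr::map(seq_len(config$n_training_sequences), function(i) {
    cfg <- config$input_config
    cfg$seed <- as.integer(config$seed + i)
    make_trend_input(cfg)
  })
}

# mean accuracy (+ optional width bonus) over prebuilt inputs; -Inf-safe
evaluate_objective <- function(params, config, inputs, weight) {
  scores <- purrr::map_dbl(inputs, function(u) {
    traj <- integrate_circuit(u, params,
                              time_per_sample = config$time_per_sample)
    if (!all(is.finite(traj$d))) return(NA_real_)
    acc <- circuit_accuracy(traj, burn_in = config$burn_in)$circuit_accuracy
    if (weight > 0) acc + weight * signal_width(traj, config$burn_in) else acc
  })
  if (any(is.na(scores))) -Inf else mean(scores)
}

#' Mean prediction accuracy over the training ensemble
#'
#' The objective maximized in the accuracy regime: the circuit's mean
#' direction-prediction accuracy over the config's fixed, seeded training
#' sequences. Identical `(params, config)` always give the identical value
#' (common random numbers). Invalid parameters score `-Inf` rather than
#' raising, so a wandering simplex can recover.
#'
#' @param params A [circuit_params()] object (or a plain list with fields
#'   `alpha`, `beta`, `gamma`).
#' @param config An [optimization_config()].
#' @return Mean accuracy in `[0, 1]`, or `-Inf` for invalid parameters.
#' @export
accuracy_objective <- function(params, config) {
  stopifnot(inherits(config, "optimization_config"))
  params <- as_params_safe(params)
  if (is.null(params)) return(-Inf)
  evaluate_objective(params, config, training_inputs(config), weight = 0)
}

#' Robustness-weighted objective
#'
#' Mean accuracy plus `robustness_weight` times the mean signal width
#' (`|x - y|`) over the training ensemble. With weight 0 this equals
#' [accuracy_objective()] exactly; larger weights favour circuits whose fast
#' and slow averages run further apart — stronger, noise-resistant momentum
#' signals that lag trend reversals.
#'
#' @inheritParams accuracy_objective
#' @return Objective value, or `-Inf` for invalid parameters.
#' @export
robust_objective <- function(params, config) {
  stopifnot(inherits(config, "optimization_config"))
  params <- as_params_safe(params)
  if (is.null(params)) return(-Inf)
  evaluate_objective(params, config, training_inputs(config),
                     weight = config$robustness_weight)
}

as_params_safe <- function(p) {
  if (inherits(p, "circuit_params")) return(p)
  ok <- is.list(p) && all(c("alpha", "beta", "gamma") %in% names(p)) &&
    all(vapply(p[c("alpha", "beta", "gamma")],
               function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
               logical(1))) &&
    p$alpha >= 0 && p$beta > 0 && p$gamma > 0
  if (!ok) return(NULL)
  circuit_params(p$alpha, p$beta, p$gamma)
}

# Nelder-Mead maximization over log-parameters; fn takes a positive
# length-p vector. Returns list(par, value, evals, trace).
nelder_log_optim <- function(fn, start, max_iterations, tolerance) {
  stopifnot(all(start > 0))
  evals <- 0L
  trace_obj <- numeric(0)
  wrapped <- function(lp) {
    v <- fn(exp(lp))
    evals <<- evals + 1L
    trace_obj[evals] <<- v
    if (!is.finite(v)) return(1e10)  # worst value keeps the simplex moving
    -v
  }
  fit <- optim(log(start), wrapped, method = "Nelder-Mead",
               control = list(maxit = max_iterations, reltol = tolerance))
  list(par = exp(fit$par), value = -fit$value, evals = evals,
       trace = trace_obj, convergence = fit$convergence)
}

#' Optimize circuit parameters by Nelder-Mead
#'
#' Maximizes the configured objective over `(alpha, beta, gamma)` in
#' log-space (positivity by construction), taking the best of `n_restarts`
#' simplex runs started from the initial parameters and seeded log-normal
#' jitters of them. The returned object records the best parameters, the
#' objective re-evaluated at them on the training seeds (exact, same
#' sequences), the evaluation trace, and a held-out median deviation measured
#' on fresh seeds.
#'
#' @param config An [optimization_config()].
#' @return A `trend_opt` object; see [tidy.trend_opt()] and
#'   [glance.trend_opt()].
#' @examples
#' \donttest{
#' cfg <- optimization_config(n_training_sequences = 5, sequence_length = 300,
#'                            n_restarts = 2, max_iterations = 80, seed = 1)
#' fit <- run_optimization(cfg)
#' glance(fit)
#' }
#' @export
run_optimization <- function(config) {
  stopifnot(inherits(config, "optimization_config"))
  inputs <- training_inputs(config)
  weight <- if (config$objective == "robust") config$robustness_weight else 0
  fn <- function(p) {
    evaluate_objective(circuit_params(p[1], p[2], p[3]), config, inputs,
                       weight)
  }
  p0 <- with(config$initial_params, c(alpha, beta, gamma))
  starts <- c(list(p0), purrr::map(seq_len(config$n_restarts - 1L), function(r) {
    withr::with_seed(config$seed + 1000L + r,
                     p0 * exp(rnorm(3, sd = 0.75)))
  }))
  runs <- purrr::imap(starts, function(st, r) {
    fit <- nelder_log_optim(fn, st, config$max_iterations, config$tolerance)
    fit$restart <- r
    fit
  })
  best <- runs[[which.max(purrr::map_dbl(runs, "value"))]]
  params <- circuit_params(best$par[1], best$par[2], best$par[3])
  trace <- purrr::map_dfr(runs, function(r) {
    tibble(restart = r$restart, eval = seq_along(r$trace),
           objective = r$trace)
  })
  heldout <- ensemble_evaluate(
    params, config$input_config, n_sequences = config$n_heldout,
    seed = config$seed + config$n_training_sequences + 1000L,
    burn_in = config$burn_in, time_per_sample = config$time_per_sample)
  structure(
    list(
      params = params,
      objective_value = fn(best$par),  # exact re-evaluation, same seeds
      median_deviation = heldout$median_deviation,
      heldout = heldout,
      trace = trace,
      convergence = best$convergence,
      config = config
    ),
    class = "trend_opt"
  )
}

#' @export
print.trend_opt <- function(x, ...) {
  cat(sprintf("<trend_opt> objective \"%s\"", x$config$objective))
  if (x$config$objective == "robust") {
    cat(sprintf(" (weight %g)", x$config$robustness_weight))
  }
  cat("\n")
  cat(sprintf("  params: alpha %.4g, beta %.4g, gamma %.4g\n",
              x$params$alpha, x$params$beta, x$params$gamma))
  cat(sprintf("  training objective: %.4g\n", x$objective_value))
  cat(sprintf("  held-out median deviation: %.4g (%d sequences)\n",
              x$median_deviation, x$config$n_heldout))
  invisible(x)
}

#' Tidy an optimization result
#'
#' @param x A `trend_opt` from [run_optimization()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.trend_opt <- function(x, ...) {
  tibble(term = c("alpha", "beta", "gamma"),
         estimate = c(x$params$alpha, x$params$beta, x$params$gamma))
}

#' One-row summary of an optimization result
#'
#' @param x A `trend_opt` from [run_optimization()].
#' @param ... Unused.
#' @return A one-row tibble: objective, training value, held-out median
#'   deviation, restarts, evaluation count, convergence code.
#' @export
glance.trend_opt <- function(x, ...) {
  tibble(
    objective = x$config$objective,
    objective_value = x$objective_value,
    median_deviation = x$median_deviation,
    n_restarts = x$config$n_restarts,
    n_evaluations = nrow(x$trace),
    convergence = x$convergence
  )
}
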