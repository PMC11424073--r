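#' Score a trajectory's direction predictions
#'
#' At every sample `t` in the scored window the circuit's prediction
#' ([predict_direction()]) is compared with the realized next increment
#' `u[t+1] - u[t]`; the final sample yields no prediction. The maximum
#' potential accuracy — the hit rate of predicting that the previous
#' increment's sign continues — is computed over the same window, so the
#' deviation is a paired difference. Steps whose realized (or, for the
#' ceiling, prior) increment is exactly zero are excluded, matching
#' [sign_persistence()].
#'
#' The first `burn_in` samples are excluded from scoring; with equilibrium
#' initialization the default of 20 comfortably covers any residual
#' transient.
#'
#' @param trajectory A `circuit_trajectory` from [integrate_circuit()].
#' @param burn_in Number of leading samples excluded from scoring, `>= 1`.
#' @return A one-row tibble: `circuit_accuracy`, `max_potential_accuracy`,
#'   `deviation` (= max potential - circuit), `n_predictions`.
#' @examples
#' u <- make_trend_input(trend_input_config(seed = 3))
#' traj <- integrate_circuit(u, preset_params("accuracy"))
#' circuit_accuracy(traj)
#' @export
circuit_accuracy <- function(trajectory, burn_in = 20L) {
  if (!is.data.frame(trajectory) ||
      !all(c("u", "d") %in% names(trajectory))) {
    abort("`trajectory` must contain columns `u` and `d`.")
  }
  check_count(burn_in, "burn_in", min = 1)
  n <- nrow(trajectory)
  if (n <= burn_in + 2) {
    abort(sprintf(
      "Trajectory too short: %d samples with burn_in %d (need > burn_in + 2).",
      n, burn_in))
  }
  du <- diff(trajectory$u)
  t_idx <- (burn_in + 1L):(n - 1L)   # predictions target u[t+1] - u[t]
  realized <- sign(du[t_idx])
  prior <- sign(du[t_idx - 1L])
  pred <- predict_direction(trajectory, t_idx)

  keep_c <- realized != 0
  circ <- mean(pred[keep_c] == realized[keep_c])
  keep_m <- realized != 0 & prior != 0
  maxp <- mean(prior[keep_m] == realized[keep_m])

  tibble(
    circuit_accuracy = circ,
    max_potential_accuracy = maxp,
    deviation = maxp - circ,
    n_predictions = sum(keep_c)
  )
}

#' Mean absolute momentum of a trajectory
#'
#' The average magnitude of the fast-minus-slow difference `|x - y|` over the
#' post-burn-in window: how widely separated the two moving averages run. A
#' wider separation gives a stronger, noise-resistant signal but lags trend
#' reversals.
#'
#' @inheritParams circuit_accuracy
#' @return Non-negative mean of `|d|`.
#' @export
signal_width <- function(trajectory, burn_in = 20L) {
  if (!is.data.frame(trajectory) || !"d" %in% names(trajectory)) {
    abort("`trajectory` must contain a momentum column `d`.")
  }
  check_count(burn_in, "burn_in", min = 0)
  n <- nrow(trajectory)
  if (n <= burn_in) abort("Trajectory shorter than burn_in.")
  mean(abs(trajectory$d[(burn_in + 1L):n]))
}

#' Evaluate a circuit over an ensemble of independent input sequences
#'
#' Simulates `n_sequences` independent trend inputs (sequence `i` uses seed
#' `seed + i`, so the whole ensemble is a pure function of the master seed),
#' integrates the circuit on each, and collects per-sequence accuracy
#' reports. The headline statistic is the median per-sequence deviation from
#' the maximum potential accuracy.
#'
#' @param params A [circuit_params()] object.
#' @param input_config A [trend_input_config()]; its `seed` field is ignored
#'   in favour of the derived per-sequence seeds.
#' @param n_sequences Number of independent sequences, `>= 1`.
#' @param seed Master seed (default: the input config's seed).
#' @param burn_in Leading samples excluded from scoring.
#' @param time_per_sample Model time per inter-sample interval.
#' @return A `trend_ensemble` object; see [tidy.trend_ensemble()] for the
#'   per-sequence table and [glance.trend_ensemble()] for the summary row.
#' @examples
#' ens <- ensemble_evaluate(preset_params("accuracy"),
#'                          trend_input_config(), n_sequences = 10, seed = 1)
#' glance(ens)
#' @export
ensemble_evaluate <- function(params, input_config,
                              n_sequences = 200L,
                              seed = input_config$seed,
                              burn_in = 20L,
                              time_per_sample = 100) {
  stopifnot(inherits(params, "circuit_params"),
            inherits(input_config, "trend_input_config"))
  check_count(n_sequences, "n_sequences", min = 1)
  check_count(seed, "seed", min = -.Machine$integer.max)
  if (seed + n_sequences >= .Machine$integer.max) {
    abort("`seed` too large: derived per-sequence seeds must stay below 2^31.")
  }
  per_seq <- purrr::map_dfr(seq_len(n_sequences), function(i) {
    cfg <- input_config
    cfg$seed <- as.integer(seed + i)
    traj <- integrate_circuit(make_trend_input(cfg), params,
                              time_per_sample = time_per_sample)
    rep <- circuit_accuracy(traj, burn_in = burn_in)
    dplyr::mutate(rep, sequence_id = i, signal_width = signal_width(traj, burn_in),
                  .before = 1)
  })
  structure(
    list(
      per_sequence = per_seq,
      median_deviation = median(per_seq$deviation),
      n_sequences = as.integer(n_sequences),
      seed = as.integer(seed),
      params = params,
      input_config = input_config,
      burn_in = as.integer(burn_in),
      time_per_sample = time_per_sample
    ),
    class = "trend_ensemble"
  )
}

#' @export
print.trend_ensemble <- function(x, ...) {
  cat(sprintf(
    "<trend_ensemble> %d sequences (seed %d)\n", x$n_sequences, x$seed))
  cat(sprintf("  params: alpha %g, beta %g, gamma %g\n",
              x$params$alpha, x$params$beta, x$params$gamma))
  cat(sprintf(
    "  median deviation from max potential accuracy: %.4g\n",
    x$median_deviation))
  cat(sprintf("  median circuit accuracy: %.4g; median ceiling: %.4g\n",
              median(x$per_sequence$circuit_accuracy),
              median(x$per_sequence$max_potential_accuracy)))
  invisible(x)
}

#' Tidy an ensemble evaluation
#'
#' @param x A `trend_ensemble` from [ensemble_evaluate()].
#' @param ... Unused.
#' @return The per-sequence tibble: `sequence_id`, `signal_width`,
#'   `circuit_accuracy`, `max_potential_accuracy`, `deviation`,
#'   `n_predictions`.
#' @export
tidy.trend_ensemble <- function(x, ...) {
  x$per_sequence
}

#' One-row summary of an ensemble evaluation
#'
#' @param x A `trend_ensemble` from [ensemble_evaluate()].
#' @param ... Unused.
#' @return A one-row tibble with the ensemble medians and bookkeeping.
#' @export
glance.trend_ensemble <- function(x, ...) {
  tibble(
    median_deviation = x$median_deviation,
    median_circuit_accuracy = median(x$per_sequence$circuit_accuracy),
    median_max_potential_accuracy =
      median(x$per_sequence$max_potential_accuracy),
    mean_signal_width = mean(x$per_sequence$signal_width),
    n_sequences = x$n_sequences,
    seed = x$seed
  )
}

#' Write an ensemble's per-sequence table as TSV
#'
#' @param ensemble A `trend_ensemble`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ensemble_tsv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "trend_ensemble"))
  df <- ensemble$per_sequence[
    c("sequence_id", "circuit_accuracy", "max_potential_accuracy", "deviation")]
  utils::write.table(format(df, digits = 15), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
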