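#' Read and write time series as TSV
#'
#' Two columns `time` and `value` with a header row; the reader tolerates
#' comment lines starting with `#`. Values are written with 15 significant
#' digits so round trips preserve full printed precision.
#'
#' @param series A time-series data frame (`time`, `value`).
#' @param path File path.
#' @return `write_series_tsv()` returns `path` invisibly;
#'   `read_series_tsv()` returns a tibble with columns `time`, `value`.
#' @export
write_series_tsv <- function(series, path) {
  validate_series(series)
  df <- data.frame(time = sprintf("%.15g", series$time),
                   value = sprintf("%.15g", series$value))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_tsv
#' @export
read_series_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", colClasses = "numeric")
  if (!all(c("time", "value") %in% names(df))) {
    abort("Series file must have columns `time` and `value`.")
  }
  out <- as_tibble(df[c("time", "value")])
  validate_series(out)
  out
}

#' Read and write circuit parameters as JSON
#'
#' The on-disk form is a flat object `{"alpha": ..., "beta": ..., "gamma": ...}`.
#'
#' @param params A [circuit_params()] object.
#' @param path File path.
#' @return `write_circuit_params()` returns `path` invisibly;
#'   `read_circuit_params()` returns a [circuit_params()] object (invalid
#'   values raise the usual validation errors).
#' @export
write_circuit_params <- function(params, path) {
  stopifnot(inherits(params, "circuit_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_circuit_params
#' @export
read_circuit_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("alpha", "beta", "gamma")) {
    if (is.null(p[[f]])) abort(sprintf("Params file missing field `%s`.", f))
  }
  circuit_params(p$alpha, p$beta, p$gamma)
}

#' Read an input-generator config from JSON or YAML
#'
#' The file is a flat mapping whose keys mirror [trend_input_config()]
#' argument names exactly (`diffusion`, `sample_step`, `n_samples`,
#' `norm_lo`, `norm_hi`, `memory`, `initial_value`, `seed`). Missing required
#' fields and unknown fields are reported by name. The format is chosen by
#' extension (`.json` vs `.yml`/`.yaml`).
#'
#' @param path File path.
#' @return A [trend_input_config()] object.
#' @export
read_input_config <- function(path) {
  raw <- read_config_file(path)
  known <- names(formals(trend_input_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config field(s): %s.",
                  paste0("`", unknown, "`", collapse = ", ")))
  }
  required <- c("seed")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Config missing required field(s): %s.",
                  paste0("`", missing, "`", collapse = ", ")))
  }
  do.call(trend_input_config, raw)
}

read_config_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yml = ,
    yaml = yaml::read_yaml(path),
    abort(sprintf("Unsupported config extension `.%s` (use .json/.yaml).", ext))
  )
  if (!is.list(raw)) abort("Config file must contain a mapping.")
  raw
}

#' Write a run manifest
#'
#' Every command drops a `manifest.json` beside its outputs recording the
#' command name, the fully resolved configuration, the package version, the
#' master seed, the output paths and a timestamp — enough to reproduce the
#' run bit-for-bit (the timestamp is informational only).
#'
#' @param dir Output directory (created if needed).
#' @param command Command name.
#' @param config Fully resolved configuration (list).
#' @param seed Master seed.
#' @param outputs Character vector of output file paths.
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, command, config, seed, outputs) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    command = command,
    config = strip_classes(config),
    package_version = as.character(utils::packageVersion("trendcircuit")),
    seed = seed,
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else {
    x
  }
}
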