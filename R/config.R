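#' Load a run configuration
#'
#' Reads a YAML configuration with sections `model` (any field of
#' [msinrf_params()]), `stimulus` (recipe name and parameters),
#' `experiment` (name and grid overrides), `seeds`, `output_dir` and
#' `log_level`.  Every omitted field falls back to the package defaults,
#' so an empty file yields the canonical model (k = 0.4, n = 5,
#' lambda = -30, p = 0.4, q = 0.1, ...).  Unknown keys are rejected with
#' a message naming each offending key.
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @return An object of class `msinrf_config`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file '", path, "' not found",
                                 call. = FALSE)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  allowed_top <- c("model", "stimulus", "experiment", "seeds",
                   "output_dir", "log_level")
  model_fields <- names(formals(msinrf_params))
  stim_fields <- c("name", "contrast", "sf_cpd", "tf_hz", "phase",
                   "direction", "speed_deg_s", "width_deg", "polarity",
                   "element_px", "noise_sf_cpd", "noise_contrast",
                   "jitter_hz", "reverse_phi", "missing_fundamental",
                   "smooth", "jump_ms", "env_sf_cpd", "env_tf_hz",
                   "env_contrast", "carrier_sf_cpd", "depth", "seed",
                   "size_px", "n_frames", "fps", "deg_per_px",
                   "sf1", "tf1", "sf2", "tf2", "c_each", "phase1",
                   "phase2", "signal_contrast", "signal_sf_cpd",
                   "signal_tf_hz", "signal_phase")
  exp_fields <- c("name", "n_contrasts", "n_phases", "n_noise_sf",
                  "n_seeds", "n_control_seeds", "n_sf", "n_tf", "lgn",
                  "smooth", "seed", "size_px", "n_frames", "scale")
  bad <- character()
  bad <- c(bad, setdiff(names(raw), allowed_top))
  if (!is.null(raw$model)) bad <- c(bad, setdiff(names(raw$model),
                                                 model_fields))
  if (!is.null(raw$stimulus)) bad <- c(bad, setdiff(names(raw$stimulus),
                                                    stim_fields))
  if (!is.null(raw$experiment)) bad <- c(bad, setdiff(names(raw$experiment),
                                                      exp_fields))
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(sort(unique(bad)), collapse = ", "),
         call. = FALSE)
  }
  model <- do.call(msinrf_params, raw$model %||% list())
  structure(list(model = model,
                 stimulus = raw$stimulus %||% list(),
                 experiment = raw$experiment %||% list(),
                 seeds = as.integer(raw$seeds %||% 1L),
                 output_dir = raw$output_dir %||% ".",
                 log_level = raw$log_level %||% "info"),
            class = "msinrf_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration as YAML
#'
#' Inverse of [load_config()]: `load_config(save_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config An `msinrf_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "msinrf_config"))
  out <- list(model = unclass(config$model),
              stimulus = config$stimulus,
              experiment = config$experiment,
              seeds = config$seeds,
              output_dir = config$output_dir,
              log_level = config$log_level)
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' @export
print.msinrf_config <- function(x, ...) {
  cat("MS-INRF run configuration\n")
  cat(sprintf("  experiment: %s; seeds: %s; output: %s\n",
              x$experiment$name %||% "(none)",
              paste(x$seeds, collapse = ","), x$output_dir))
  print(x$model)
  invisible(x)
}
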