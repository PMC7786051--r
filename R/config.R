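# Run configuration: defaults, YAML loading, strict key validation.

#' Default run configuration
#'
#' Returns the full configuration tree consumed by the `cmd_*` pipeline
#' commands and the command-line tool. Unknown keys in a user file are
#' rejected; every run writes the resolved configuration next to its
#' outputs.
#'
#' @return Nested named list with sections `paths`, `fluid`, `physics`,
#'   `tracking`, `qc`, `simulation`, plus `seed` and `log_level`.
#' @export
default_run_config <- function() {
  list(
    paths = list(tracks = NULL, frames = NULL, results = NULL,
                 outdir = "."),
    fluid = list(density_fg_um3 = 1005, viscosity_pa_s = 0.89e-3,
                 temperature_c = 25),
    physics = list(g = GRAVITY, wall_correction = 1,
                   reynolds_threshold = 0.1),
    tracking = list(min_frames = 5, min_area_px = 500, min_contrast = 0.1,
                    discard_first = 0, pixel_size_um = NULL,
                    frame_interval_s = NULL),
    qc = list(alpha = 0.05, force_screen = FALSE),
    simulation = list(preset = NULL, condition = NULL, n_spheroids = 10,
                      repetitions = 10, radius_mean_um = 55,
                      radius_sd_um = 10, density_mean = 1050,
                      density_sd = 10, n_frames = 30,
                      frame_interval = 1 / 30, pixel_size = 2,
                      frame_rows = 512, frame_cols = 512,
                      loc_noise_px = 0.5, radius_noise_px = 0.1,
                      weight_factor = 1, diameter_factor = 1,
                      write_frames = FALSE),
    seed = NULL,
    log_level = "info"
  )
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) {
      stop_invalid(sprintf("unknown configuration key: %s", full))
    }
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]])) {
        stop_invalid(sprintf("configuration key %s must be a section", full))
      }
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      base[key] <- user[key] # [<- keeps explicit NULLs
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, overlays it on [default_run_config()], and rejects
#' unknown keys. Programmatic overrides (e.g. from command-line flags) are
#' applied last.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Optional nested list applied after the file.
#' @return Validated configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = NULL) {
  config <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop_invalid(sprintf("config file not found: %s", path))
    }
    user <- yaml::read_yaml(path)
    if (!is.null(user)) config <- merge_config(config, user)
  }
  if (!is.null(overrides)) config <- merge_config(config, overrides)
  config
}

config_fluid <- function(config) {
  fluid_properties(density = config$fluid$density_fg_um3,
                   viscosity = config$fluid$viscosity_pa_s,
                   temperature = config$fluid$temperature_c)
}

write_resolved_config <- function(config, outdir) {
  drop_null <- function(x) {
    if (!is.list(x)) return(x)
    x <- lapply(x, drop_null)
    x[!vapply(x, is.null, logical(1))]
  }
  yaml::write_yaml(drop_null(config), file.path(outdir, "run_config.yaml"))
}

sf_log <- function(config, level, fmt, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  lvl <- config$log_level %||% "info"
  threshold <- if (lvl %in% names(levels)) levels[[lvl]] else 2
  if (levels[[level]] >= threshold && threshold < 4) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
}
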