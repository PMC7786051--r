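# Synthetic falling-spheroid generator. Emulates a single dark quasi-circular
# spheroid (60-200 um diameter) sinking at constant terminal velocity through
# a bright quiescent channel, observed over repeated free-fall runs
# ("repetitions"). Ground truth is drawn from configurable distributions and
# always satisfies the forward Stokes model exactly, so every pipeline stage
# can be validated against it.
#
# Stochastic terms: centroid localization noise and per-frame radius jitter
# (both in px), and additive intensity noise in rendered frames. Brownian
# motion and pre-terminal transients are omitted -- negligible at the 100 um
# scale -- but a constant drift hook emulates residual flow if wanted.

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the measurement regime of the real assay: cohorts of 10
#' spheroids, 10 repetitions each, radii drawn from a truncated normal
#' within 30-100 um (diameters 60-200 um), water-like buffer, 2 um/px
#' optics at 30 frames/s on 512 x 512 rasters.
#'
#' @param n_spheroids Number of spheroids in the cohort (default 10).
#' @param repetitions Free-fall repetitions per spheroid (default 10).
#' @param radius_mean_um,radius_sd_um Truncated-normal radius distribution
#'   (um).
#' @param radius_bounds_um Truncation bounds, um (default 30-100).
#' @param density_mean,density_sd Normal mass-density distribution
#'   (fg/um^3); draws are kept above the fluid density (a non-sinking
#'   spheroid never transits the channel, so it cannot be measured).
#' @param fluid A [fluid_properties()] object.
#' @param n_frames Frames per repetition (default 30).
#' @param frame_interval s between frames (default 1/30).
#' @param pixel_size um/px (default 2).
#' @param frame_shape Raster rows x cols in px (default 512 x 512).
#' @param loc_noise_px SD of centroid localization noise per coordinate, px
#'   (default 0.5).
#' @param radius_noise_px SD of per-frame radius jitter, px (default 0.1;
#'   the circle fit is far more stable than the centroid).
#' @param background_intensity,object_intensity Rendered intensities in
#'   0-1 (bright field: background > object).
#' @param intensity_noise_sd Additive Gaussian intensity noise for renders.
#' @param blur_sigma_px Gaussian optical blur applied to renders, px.
#' @param treatment_effect List with multiplicative `weight` and `diameter`
#'   factors applied to the ground truth (default both 1 = untreated).
#' @param drift_um_s Constant residual-flow drift added to the fall
#'   velocity (default 0).
#' @param g,wall_correction Passed to the forward model.
#' @param seed Optional integer seed fixing every draw.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_spheroids = 10, repetitions = 10,
                              radius_mean_um = 55, radius_sd_um = 10,
                              radius_bounds_um = c(30, 100),
                              density_mean = 1050, density_sd = 10,
                              fluid = fluid_properties(),
                              n_frames = 30, frame_interval = 1 / 30,
                              pixel_size = 2, frame_shape = c(512L, 512L),
                              loc_noise_px = 0.5, radius_noise_px = 0.1,
                              background_intensity = 0.85,
                              object_intensity = 0.3,
                              intensity_noise_sd = 0.02, blur_sigma_px = 1,
                              treatment_effect = list(weight = 1,
                                                      diameter = 1),
                              drift_um_s = 0, g = GRAVITY,
                              wall_correction = 1, seed = NULL) {
  fluid <- as_fluid(fluid)
  num_pos <- c(n_spheroids = n_spheroids, repetitions = repetitions,
               radius_mean_um = radius_mean_um, radius_sd_um = radius_sd_um,
               density_mean = density_mean, density_sd = density_sd,
               n_frames = n_frames, frame_interval = frame_interval,
               pixel_size = pixel_size)
  if (any(!is.finite(num_pos)) || any(num_pos <= 0)) {
    stop_invalid(paste0(
      "simulation parameters must be positive: ",
      paste(names(num_pos)[!is.finite(num_pos) | num_pos <= 0],
            collapse = ", ")
    ))
  }
  if (length(radius_bounds_um) != 2L || radius_bounds_um[1] <= 0 ||
      diff(radius_bounds_um) <= 0) {
    stop_invalid("radius_bounds_um must be increasing positive bounds (um)")
  }
  if (loc_noise_px < 0 || radius_noise_px < 0 || intensity_noise_sd < 0) {
    stop_invalid("noise standard deviations must be non-negative")
  }
  if (!is.list(treatment_effect) ||
      is.null(treatment_effect$weight) || is.null(treatment_effect$diameter) ||
      treatment_effect$weight <= 0 || treatment_effect$diameter <= 0) {
    stop_invalid("treatment_effect must list positive weight and diameter factors")
  }
  structure(
    list(n_spheroids = as.integer(n_spheroids),
         repetitions = as.integer(repetitions),
         radius_mean_um = radius_mean_um, radius_sd_um = radius_sd_um,
         radius_bounds_um = radius_bounds_um,
         density_mean = density_mean, density_sd = density_sd,
         fluid = fluid, n_frames = as.integer(n_frames),
         frame_interval = frame_interval, pixel_size = pixel_size,
         frame_shape = as.integer(frame_shape),
         loc_noise_px = loc_noise_px, radius_noise_px = radius_noise_px,
         background_intensity = background_intensity,
         object_intensity = object_intensity,
         intensity_noise_sd = intensity_noise_sd,
         blur_sigma_px = blur_sigma_px,
         treatment_effect = treatment_effect, drift_um_s = drift_um_s,
         g = g, wall_correction = wall_correction, seed = seed),
    class = "simulation_config"
  )
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Draw the ground-truth table of a synthetic cohort
#'
#' Radii come from the configured truncated normal, mass densities from a
#' normal kept above the fluid density; treatment factors rescale diameter
#' by d and weight by w (hence density by w/d^3). The true terminal
#' velocity of every row satisfies the forward Stokes model exactly.
#'
#' @param config A [simulation_config()].
#' @param condition Condition label stored on each row.
#' @return Data frame: `spheroid_id`, `condition`, `r_um_true`,
#'   `rho_fg_um3_true`, `weight_ng_true`, `v_um_s_true`.
#' @export
simulate_truth <- function(config, condition = "untreated") {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_spheroids
  r <- rtruncnorm1(n, config$radius_mean_um, config$radius_sd_um,
                   config$radius_bounds_um[1], config$radius_bounds_um[2])
  rho <- rtruncnorm1(n, config$density_mean, config$density_sd,
                     config$fluid$density + 1, Inf)
  wf <- config$treatment_effect$weight
  df <- config$treatment_effect$diameter
  r <- r * df
  rho <- rho * wf / df^3
  v <- terminal_velocity(r, rho, config$fluid, config$g,
                         config$wall_correction)
  w <- weight_and_volume(rho, r)$weight_ng
  data.frame(
    spheroid_id = sprintf("S%03d", seq_len(n)), condition = condition,
    r_um_true = r, rho_fg_um3_true = rho, weight_ng_true = w,
    v_um_s_true = v, stringsAsFactors = FALSE
  )
}

track_geometry <- function(truth_row, config) {
  r_px <- truth_row$r_um_true / config$pixel_size
  nrow_px <- config$frame_shape[1]
  # start near the top of the raster, clear of the border
  z0_px <- r_px + 2 + stats::runif(1, 0, 10)
  col_px <- config$frame_shape[2] / 2 + stats::runif(1, -10, 10)
  list(r_px = r_px, z0_px = z0_px, col_px = col_px, nrow_px = nrow_px)
}

#' Simulate one free-fall repetition as a position track
#'
#' Vertical position z(t) = z0 + v t with i.i.d. Gaussian localization
#' noise on both coordinates and a per-frame radius jitter term; columns
#' follow the shared tracks.csv schema. Deterministic given the RNG state
#' (seed once per cohort, or `set.seed()` before calling).
#'
#' @param truth_row One row of a [simulate_truth()] table.
#' @param config A [simulation_config()].
#' @param repetition Repetition index stored on the rows.
#' @return Data frame: `spheroid_id`, `repetition`, `frame`, `time_s`,
#'   `row_px`, `col_px`, `radius_px`, `quality`.
#' @export
simulate_track <- function(truth_row, config, repetition = 1L) {
  geom <- track_geometry(truth_row, config)
  t <- (seq_len(config$n_frames) - 1) * config$frame_interval
  v <- truth_row$v_um_s_true + config$drift_um_s
  row_px <- geom$z0_px + v * t / config$pixel_size +
    stats::rnorm(config$n_frames, 0, config$loc_noise_px)
  col_px <- geom$col_px + stats::rnorm(config$n_frames, 0, config$loc_noise_px)
  radius_px <- geom$r_px + stats::rnorm(config$n_frames, 0,
                                        config$radius_noise_px)
  data.frame(
    spheroid_id = truth_row$spheroid_id, repetition = as.integer(repetition),
    frame = seq_len(config$n_frames), time_s = t, row_px = row_px,
    col_px = col_px, radius_px = radius_px, quality = "ok",
    stringsAsFactors = FALSE
  )
}

render_one_frame <- function(center_row, center_col, r_px, config) {
  shape <- config$frame_shape
  bg <- config$background_intensity
  obj <- config$object_intensity
  dr <- outer(seq_len(shape[1]) - center_row, rep(1, shape[2]))
  dc <- outer(rep(1, shape[1]), seq_len(shape[2]) - center_col)
  dist <- sqrt(dr^2 + dc^2)
  coverage <- matrix(pmin(1, pmax(0, r_px - dist + 0.5)), # 1 px soft edge
                     shape[1], shape[2])
  img <- bg - (bg - obj) * coverage
  if (config$blur_sigma_px > 0) {
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                             sigma = config$blur_sigma_px))
  }
  if (config$intensity_noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, config$intensity_noise_sd)
  }
  matrix(pmin(1, pmax(0, img)), shape[1], shape[2])
}

#' Render one free-fall repetition as bright-field frames
#'
#' Draws a dark anti-aliased disc of the true radius on a bright uniform
#' background at the noiseless track position of each frame, applies
#' Gaussian optical blur and additive intensity noise.
#'
#' @inheritParams simulate_track
#' @return A [frame_sequence()].
#' @export
render_frames <- function(truth_row, config, repetition = 1L) {
  geom <- track_geometry(truth_row, config)
  if (geom$z0_px + geom$r_px >= geom$nrow_px ||
      geom$r_px * 2 >= config$frame_shape[2]) {
    stop_invalid("disc does not fit the frame at its initial position")
  }
  t <- (seq_len(config$n_frames) - 1) * config$frame_interval
  v <- truth_row$v_um_s_true + config$drift_um_s
  rows <- geom$z0_px + v * t / config$pixel_size
  frames <- lapply(seq_len(config$n_frames), function(i) {
    render_one_frame(rows[i], geom$col_px, geom$r_px, config)
  })
  frame_sequence(frames, config$pixel_size, config$frame_interval)
}

#' Cell-line and treatment presets for the synthetic generator
#'
#' Loose caricatures reproducing the qualitative orderings of four
#' colorectal-carcinoma lines -- they are validation fixtures, not estimates
#' of the real cell lines. `ht29`: smaller, lighter aggregates with low and
#' dispersed mass density; `sw620` / `dld1`: heavier and denser; `hct15`:
#' size-dispersed with low density. NK co-culture presets (`*_nk_6h`,
#' `*_nk_24h`) apply weight/diameter reduction factors of the magnitude the
#' assay is meant to resolve (e.g. `sw620_nk_6h`: weight x 0.53 = -47%).
#'
#' @param preset Preset label; call with no argument to list them.
#' @param ... Overrides forwarded to [simulation_config()].
#' @return A [simulation_config()] (invisible label list when no preset
#'   given).
#' @export
cohort_preset <- function(preset, ...) {
  presets <- list(
    ht29  = list(radius_mean_um = 40, radius_sd_um = 7,
                 density_mean = 1030, density_sd = 15),
    sw620 = list(radius_mean_um = 55, radius_sd_um = 8,
                 density_mean = 1060, density_sd = 8),
    dld1  = list(radius_mean_um = 55, radius_sd_um = 8,
                 density_mean = 1065, density_sd = 8),
    hct15 = list(radius_mean_um = 55, radius_sd_um = 15,
                 density_mean = 1035, density_sd = 8)
  )
  effects <- list(
    sw620_nk_6h  = list(base = "sw620", weight = 0.53, diameter = 0.82),
    sw620_nk_24h = list(base = "sw620", weight = 0.77, diameter = 0.87),
    dld1_nk_24h  = list(base = "dld1",  weight = 0.66, diameter = 0.87),
    hct15_nk_24h = list(base = "hct15", weight = 0.77, diameter = 0.93)
  )
  labels <- c(names(presets), names(effects))
  if (missing(preset)) return(invisible(labels))
  if (!preset %in% labels) {
    stop_invalid(sprintf("unknown preset '%s'; available: %s", preset,
                         paste(labels, collapse = ", ")))
  }
  if (preset %in% names(effects)) {
    eff <- effects[[preset]]
    base <- presets[[eff$base]]
    args <- c(base, list(treatment_effect = list(weight = eff$weight,
                                                 diameter = eff$diameter)))
  } else {
    args <- presets[[preset]]
  }
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

#' Simulate a full cohort with known ground truth
#'
#' Draws the ground-truth table and generates, per spheroid and repetition,
#' position tracks (always) and optionally rendered frame sequences.
#' Identical config + seed gives bit-identical output.
#'
#' @param config A [simulation_config()], or a preset label understood by
#'   [cohort_preset()].
#' @param condition Condition label stored on the truth/track rows
#'   (defaults to the preset label when one is given).
#' @param render If `TRUE`, also return rendered [frame_sequence()] objects
#'   (list indexed `[[spheroid]][[repetition]]`); memory-heavy, default
#'   `FALSE`.
#' @param ... Overrides forwarded to [cohort_preset()] when `config` is a
#'   label.
#' @return List with `truth` (data frame), `tracks` (data frame, shared
#'   tracks.csv schema), `frames` (list or NULL) and `config`.
#' @export
simulate_cohort <- function(config, condition = NULL, render = FALSE, ...) {
  if (is.character(config)) {
    if (is.null(condition)) condition <- config
    config <- cohort_preset(config, ...)
  }
  if (!inherits(config, "simulation_config")) {
    stop_invalid("config must be a simulation_config or a preset label")
  }
  if (is.null(condition)) condition <- "untreated"
  truth <- simulate_truth(config, condition = condition)
  tracks <- vector("list", nrow(truth) * config$repetitions)
  frames <- if (render) vector("list", nrow(truth)) else NULL
  k <- 0L
  for (i in seq_len(nrow(truth))) {
    if (render) frames[[i]] <- vector("list", config$repetitions)
    for (rep_j in seq_len(config$repetitions)) {
      k <- k + 1L
      tracks[[k]] <- simulate_track(truth[i, ], config, rep_j)
      if (render) frames[[i]][[rep_j]] <- render_frames(truth[i, ], config,
                                                        rep_j)
    }
  }
  list(truth = truth, tracks = do.call(rbind, tracks), frames = frames,
       config = config)
}
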