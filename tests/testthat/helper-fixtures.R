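# Shared fixtures: synthetic frames and cohorts built in code at test time.

# Render a single bright-field frame with a dark anti-aliased disc, the
# same intensity model as the package renderer but assembled independently
# here so detection tests do not lean on the renderer they validate.
make_disc_frame <- function(center_row, center_col, radius_px,
                            shape = c(128L, 128L), bg = 0.85, obj = 0.3) {
  dr <- outer(seq_len(shape[1]) - center_row, rep(1, shape[2]))
  dc <- outer(rep(1, shape[1]), seq_len(shape[2]) - center_col)
  dist <- sqrt(dr^2 + dc^2)
  coverage <- matrix(pmin(1, pmax(0, radius_px - dist + 0.5)),
                     shape[1], shape[2])
  bg - (bg - obj) * coverage
}

# A noiseless linear track in the tracks.csv schema.
make_linear_track <- function(v_um_s, n_frames = 20, fps = 30,
                              pixel_size = 2, z0_px = 10, radius_px = 30,
                              spheroid_id = "S001", repetition = 1L) {
  t <- (seq_len(n_frames) - 1) / fps
  data.frame(
    spheroid_id = spheroid_id, repetition = repetition,
    frame = seq_len(n_frames), time_s = t,
    row_px = z0_px + v_um_s * t / pixel_size,
    col_px = 64, radius_px = radius_px, quality = "ok",
    stringsAsFactors = FALSE
  )
}

# Simulate a cohort at track level and measure it through the pipeline.
# The Reynolds guard is disabled: the default study conditions sit at
# Re ~ 0.1, exactly on the guard, and the warning is exercised separately.
sim_and_measure <- function(config, condition = "untreated") {
  cohort <- simulate_cohort(config, condition = condition)
  results <- measure_tracks(cohort$tracks, config$pixel_size,
                            config$frame_interval, config$fluid,
                            condition = condition, reynolds_threshold = NA)
  list(truth = cohort$truth, results = results)
}

# Results-level clean cohort: per-spheroid metrics drawn from normal radius
# and velocity, density/weight derived through the physics, so the four
# metric columns carry realistic correlations.
make_normal_results <- function(n = 10, r_mean = 75, r_sd = 3,
                                v_mean = 600, v_sd = 30,
                                fluid = fluid_properties()) {
  r <- stats::rnorm(n, r_mean, r_sd)
  v <- stats::rnorm(n, v_mean, v_sd)
  rho <- mass_density_from_motion(v, r, fluid)
  w <- weight_and_volume(rho, r)$weight_ng
  data.frame(
    spheroid_id = sprintf("S%03d", seq_len(n)), condition = "untreated",
    n_reps = 10L, diameter_um = 2 * r, diameter_sd = 0,
    velocity_um_s = v, velocity_sd = 0, mass_density_fg_um3 = rho,
    density_sd = 0, weight_ng = w, weight_sd = 0, qc_flag = "kept",
    flagged_metrics = "", stringsAsFactors = FALSE
  )
}
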