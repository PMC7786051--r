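# Repetition aggregation, normality screening, Tukey fences, the any-metric
# removal rule and cohort comparison.

fitted_track <- function(v_um_s, radius_um, repetition = 1L,
                         pixel_size = 2) {
  trk <- make_linear_track(v_um_s, radius_px = radius_um / pixel_size,
                           pixel_size = pixel_size, repetition = repetition)
  fit_terminal_velocity(track_from_positions(trk, pixel_size, 1 / 30,
                                             repetition))
}

test_that("aggregation applies the final-radius rule and recomputes physics", {
  fl <- fluid_properties(1005, 1.0e-3)
  tracks <- list(fitted_track(551.6, 50.1, 1L), fitted_track(551.6, 49.9, 2L),
                 fitted_track(551.6, 50.0, 3L))
  res <- aggregate_repetitions(tracks, fl, reynolds_threshold = NA)
  expect_equal(res$radius_um, 50.0)
  expect_equal(res$diameter_um, 2 * res$radius_um) # exact by construction
  # density/weight recomputable from (v, r) through the physics
  expect_equal(res$mass_density_fg_um3,
               mass_density_from_motion(551.6, 50.0, fl))
  expect_equal(res$weight_ng,
               weight_and_volume(res$mass_density_fg_um3, 50.0)$weight_ng)
})

test_that("identical repetitions give zero dispersion", {
  fl <- fluid_properties(1005, 1.0e-3)
  tracks <- lapply(1:10, function(i) fitted_track(400, 60, i))
  res <- aggregate_repetitions(tracks, fl, reynolds_threshold = NA)
  expect_equal(res$n_repetitions, 10L)
  expect_equal(res$velocity_sd, 0)
  expect_equal(res$diameter_sd, 0)
  expect_equal(res$density_sd, 0, tolerance = 1e-12)
  single <- aggregate_repetitions(tracks[1:3], fl, reynolds_threshold = NA)
  expect_equal(res$mass_density_fg_um3, single$mass_density_fg_um3)
  expect_equal(res$weight_ng, single$weight_ng)
})

test_that("aggregation rejects too few or unfitted repetitions", {
  fl <- fluid_properties()
  expect_error(aggregate_repetitions(list(fitted_track(400, 60)), fl),
               class = "spherofall_insufficient_repetitions")
  unfitted <- track_from_positions(make_linear_track(400), 2, 1 / 30)
  expect_error(
    aggregate_repetitions(list(unfitted, unfitted, unfitted), fl),
    class = "spherofall_invalid_track"
  )
})

test_that("pipeline recovers simulated ground truth per spheroid", {
  cfg <- simulation_config(n_spheroids = 10, repetitions = 10,
                           radius_mean_um = 75, radius_sd_um = 4,
                           density_mean = 1050, density_sd = 6, seed = 71)
  out <- sim_and_measure(cfg)
  ord <- match(out$results$spheroid_id, out$truth$spheroid_id)
  rel_rho <- abs(out$results$mass_density_fg_um3 -
                   out$truth$rho_fg_um3_true[ord]) /
    out$truth$rho_fg_um3_true[ord]
  expect_lt(max(rel_rho), 0.01) # each spheroid's density within 1%
})

test_that("Shapiro-Wilk screen flags non-normal samples and is affine-invariant", {
  set.seed(41)
  bimodal <- c(rnorm(10, 0, 0.5), rnorm(10, 100, 0.5))
  expect_false(shapiro_screen(bimodal)$normal)
  x <- rnorm(20)
  expect_equal(shapiro_screen(x)$statistic,
               shapiro_screen(5 - 3 * x)$statistic, tolerance = 1e-9)
  expect_error(shapiro_screen(c(1, 2)),
               class = "spherofall_insufficient_data")
  expect_error(shapiro_screen(rep(1, 10)),
               class = "spherofall_degenerate_input")
})

test_that("Tukey fences match hand-computed quartiles", {
  # sorted {1,2,3,4,100}: Q1 = 2, Q3 = 4 (type-7 interpolation),
  # fences (-1, 7) -> only 100 flagged
  tk <- tukey_outlier_flags(c(1, 2, 3, 4, 100))
  expect_equal(unname(tk$fences), c(-1, 7))
  expect_identical(tk$flagged, 5L)
  # constant sample: fences collapse, nothing flagged
  expect_length(tukey_outlier_flags(rep(3.3, 6))$flagged, 0)
  # flags invariant under shifting all values
  set.seed(42)
  v <- rnorm(30)
  expect_identical(tukey_outlier_flags(v)$flagged,
                   tukey_outlier_flags(v + 57)$flagged)
  # values exactly on a fence are not flagged: {-4,-1,0,1,4} has
  # Q1 = -1, Q3 = 1, fences (-4, 4), so the extremes sit on the fences
  tk2 <- tukey_outlier_flags(c(-4, -1, 0, 1, 4))
  expect_equal(unname(tk2$fences), c(-4, 4))
  expect_length(tk2$flagged, 0)
  expect_error(tukey_outlier_flags(c(1, 2, 3)),
               class = "spherofall_insufficient_data")
})

test_that("one aberrant metric suffices to remove a spheroid", {
  set.seed(43)
  res <- make_normal_results(n = 11)
  res$velocity_um_s[11] <- res$velocity_um_s[11] * 10 # velocity only
  qc <- apply_removal_rule(res)
  expect_true("S011" %in% qc$removed)
  expect_true(any(qc$ledger$spheroid_id == "S011" &
                    qc$ledger$metric == "velocity"))
  expect_identical(qc$results$qc_flag[11], "removed")
  # removed set equals the union of per-metric flag sets
  expect_setequal(qc$removed, unique(qc$ledger$spheroid_id))
  # survivors re-checked for normality
  expect_true(all(vapply(qc$shapiro_after, function(s)
    is.na(s$normal) || is.logical(s$normal), logical(1))))
})

test_that("degenerate cohorts are signaled, not screened", {
  res <- make_normal_results(n = 6)
  res$diameter_um <- 100
  res$velocity_um_s <- 500
  res$mass_density_fg_um3 <- 1050
  res$weight_ng <- 550
  qc <- apply_removal_rule(res)
  expect_length(qc$removed, 0)
  expect_true(all(vapply(qc$shapiro_before, function(s)
    isTRUE(s$degenerate), logical(1))))
  expect_error(apply_removal_rule(make_normal_results(n = 3)),
               class = "spherofall_insufficient_data")
})

test_that("cohort comparison reports percent change and the pooled t-test", {
  set.seed(44)
  ctrl <- make_normal_results(n = 10)
  treat <- ctrl
  treat$weight_ng <- treat$weight_ng * 0.53 +
    rnorm(10, 0, 0.02 * mean(treat$weight_ng))
  cmp <- compare_cohorts(ctrl, treat, "weight")
  expect_equal(cmp$percent_change,
               100 * (mean(treat$weight_ng) / mean(ctrl$weight_ng) - 1))
  expect_lt(cmp$p, 0.001)
  # identical cohorts: 0 percent change, p = 1
  same <- compare_cohorts(ctrl, ctrl, "weight")
  expect_equal(same$percent_change, 0)
  expect_equal(same$p, 1)
  expect_equal(same$t, 0)
})

test_that("pooled t-test agrees with the closed-form statistic", {
  ctrl <- make_normal_results(n = 5)
  treat <- make_normal_results(n = 5)
  x <- c(12.1, 10.8, 11.5, 12.9, 11.1)
  y <- c(9.6, 10.2, 8.8, 9.9, 10.4)
  ctrl$weight_ng <- x
  treat$weight_ng <- y
  cmp <- compare_cohorts(ctrl, treat, "weight")
  # independent closed-form pooled-variance oracle
  sp2 <- (4 * var(x) + 4 * var(y)) / 8
  t_hand <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  p_hand <- 2 * pt(-abs(t_hand), df = 8)
  expect_equal(cmp$t, t_hand, tolerance = 1e-12)
  expect_equal(cmp$p, p_hand, tolerance = 1e-12)
})

test_that("comparison errors on degenerate inputs", {
  ctrl <- make_normal_results(n = 5)
  expect_error(compare_cohorts(ctrl[1:2, ], ctrl, "weight"),
               class = "spherofall_insufficient_data")
  zero <- ctrl
  zero$weight_ng <- c(-2, -1, 0, 1, 2) # mean exactly zero
  expect_error(compare_cohorts(zero, ctrl, "weight"),
               class = "spherofall_undefined_percent_change")
  const <- ctrl
  const$weight_ng <- 5
  expect_error(compare_cohorts(const, const, "weight"),
               class = "spherofall_degenerate_variance")
})
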