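# Circular-reference geometry, per-frame detection, track assembly and the
# terminal-velocity regression.

test_that("minimal enclosing circle is exact on constructed point sets", {
  th <- seq(0, 2 * pi, length.out = 61)[-61]
  circ <- min_enclosing_circle(cbind(3 + 2 * cos(th), -1 + 2 * sin(th)))
  expect_equal(circ$center, c(3, -1), tolerance = 1e-9)
  expect_equal(circ$radius, 2, tolerance = 1e-9)
  # interior points do not change the circle
  circ2 <- min_enclosing_circle(rbind(cbind(3 + 2 * cos(th), -1 + 2 * sin(th)),
                                      cbind(runif(40, 2, 4), runif(40, -2, 0))))
  expect_equal(circ2$radius, 2, tolerance = 1e-9)
  # degenerate sets: single point and collinear points
  expect_equal(min_enclosing_circle(cbind(5, 7))$radius, 0)
  col3 <- min_enclosing_circle(cbind(c(0, 1, 4), c(0, 0, 0)))
  expect_equal(col3$radius, 2)
  expect_equal(col3$center, c(2, 0))
})

test_that("detection localizes noiseless rendered discs to sub-pixel accuracy", {
  cases <- expand.grid(r = c(20, 35, 55), row = c(64.0, 80.5),
                       col = c(60.0, 70.25))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    frame <- make_disc_frame(cs$row, cs$col, cs$r, shape = c(160L, 160L))
    det <- detect_spheroid(frame)
    expect_identical(det$quality, "ok")
    expect_lt(max(abs(det$centroid - c(cs$row, cs$col))), 0.5)
    expect_lt(abs(det$radius_px - cs$r), 1.0)
  }
})

test_that("detection is equivariant under integer-pixel translation", {
  f0 <- detect_spheroid(make_disc_frame(50, 60, 25, shape = c(160L, 160L)))
  f1 <- detect_spheroid(make_disc_frame(53, 65, 25, shape = c(160L, 160L)))
  expect_equal(f1$centroid - f0$centroid, c(3, 5), tolerance = 1e-6)
  # radius is invariant to vertical position within the frame
  f2 <- detect_spheroid(make_disc_frame(110, 60, 25, shape = c(160L, 160L)))
  expect_equal(f2$radius_px, f0$radius_px, tolerance = 1e-6)
})

test_that("detection filters candidates and flags quality states", {
  expect_error(detect_spheroid(matrix(0.8, 64, 64)),
               class = "spherofall_no_detection")
  # second component below the minimum area is discarded silently
  two <- make_disc_frame(60, 55, 40, shape = c(160L, 160L))
  two <- pmin(two, make_disc_frame(130, 130, 9, shape = c(160L, 160L)))
  det <- detect_spheroid(two, min_area = 500)
  expect_identical(det$quality, "ok")
  expect_equal(det$centroid, c(60, 55), tolerance = 0.5)
  # both components large: flagged, prior breaks the tie
  both <- make_disc_frame(50, 40, 25, shape = c(160L, 160L))
  both <- pmin(both, make_disc_frame(120, 120, 25, shape = c(160L, 160L)))
  det2 <- detect_spheroid(both, min_area = 500)
  expect_identical(det2$quality, "multiple_candidates")
  prior <- list(centroid = c(118, 118))
  det3 <- detect_spheroid(both, prior = prior, min_area = 500)
  expect_equal(det3$centroid, c(120, 120), tolerance = 0.5)
  # object on the frame border is flagged but still measured
  border <- make_disc_frame(4, 80, 20, shape = c(160L, 160L))
  expect_identical(detect_spheroid(border)$quality, "touching_border")
})

test_that("track assembly records gaps and survives partial loss", {
  cfg <- simulation_config(n_spheroids = 1, frame_shape = c(256L, 256L),
                           n_frames = 30, intensity_noise_sd = 0,
                           loc_noise_px = 0, radius_noise_px = 0, seed = 3)
  truth <- data.frame(spheroid_id = "S001", condition = "x", r_um_true = 50,
                      rho_fg_um3_true = 1030, weight_ng_true = NA,
                      v_um_s_true = 150)
  set.seed(3)
  seq30 <- render_frames(truth, cfg)
  tr <- extract_track(seq30)
  expect_identical(tr$n_ok, 30L)
  expect_identical(tr$n_gaps, 0L)
  # two blanked frames become gaps; regression still runs
  seq_gap <- seq30
  seq_gap$frames[[10]] <- matrix(0.85, 256, 256)
  seq_gap$frames[[20]] <- matrix(0.85, 256, 256)
  tr_gap <- fit_terminal_velocity(extract_track(seq_gap))
  expect_identical(tr_gap$n_ok, 28L)
  expect_identical(tr_gap$n_gaps, 2L)
  expect_equal(tr_gap$slope_um_s, 150, tolerance = 1e-3)
  # too few frames at all
  expect_error(extract_track(frame_sequence(seq30$frames[1:3], 2, 1 / 30)),
               class = "spherofall_track_too_short")
})

test_that("object leaving the field of view flags trailing frames", {
  cfg <- simulation_config(n_spheroids = 1, frame_shape = c(150L, 150L),
                           n_frames = 30, intensity_noise_sd = 0,
                           pixel_size = 2, seed = 5)
  truth <- data.frame(spheroid_id = "S001", condition = "x", r_um_true = 40,
                      rho_fg_um3_true = 1060, weight_ng_true = NA,
                      v_um_s_true = 400) # 400 um/s exits a 300 um frame
  set.seed(5)
  seqx <- render_frames(truth, cfg)
  tr <- extract_track(seqx)
  q <- tr$detections$quality
  expect_true(all(q[1:10] == "ok"))
  expect_true(all(q[q != "ok"] %in% c("touching_border", "gap")))
  expect_gt(sum(q != "ok"), 0)
  # ok detections stop once the disc reaches the border
  last_ok <- max(which(q == "ok"))
  expect_true(all(q[seq(last_ok + 1, 30)] != "ok"))
})

test_that("terminal-velocity regression matches closed-form least squares", {
  # exact linear data
  tr <- track_from_positions(make_linear_track(551.6), pixel_size = 2,
                             frame_interval = 1 / 30)
  fit <- fit_terminal_velocity(tr)
  expect_equal(fit$slope_um_s, 551.6, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # hand-computed OLS on five listed points:
  # (t, z) = (0,0), (0.1,55), (0.2,110), (0.3,166), (0.4,220)
  # Sxx = 0.1, Sxy = 55.10 -> slope 551.0, intercept 0
  pts <- data.frame(spheroid_id = "S001", repetition = 1L, frame = 1:5,
                    time_s = c(0, 0.1, 0.2, 0.3, 0.4),
                    row_px = c(0, 55, 110, 166, 220) / 2,
                    col_px = 0, radius_px = 25, quality = "ok")
  fit2 <- fit_terminal_velocity(track_from_positions(pts, 2, 0.1))
  expect_equal(fit2$slope_um_s, 551.0, tolerance = 1e-9)
  expect_equal(fit2$intercept_um, 0, tolerance = 1e-9)
  # discard_first drops leading points
  fit3 <- fit_terminal_velocity(track_from_positions(pts, 2, 0.1),
                                discard_first = 2)
  expect_equal(fit3$slope_um_s, 550, tolerance = 1e-9)
  expect_error(fit_terminal_velocity(track_from_positions(pts, 2, 0.1),
                                     discard_first = 3),
               class = "spherofall_insufficient_data")
})

test_that("OLS slope is unbiased under localization noise", {
  set.seed(21)
  slopes <- replicate(100, {
    trk <- make_linear_track(551.6, n_frames = 20)
    trk$row_px <- trk$row_px + rnorm(20, 0, 0.5) # sigma = 1 um at 2 um/px
    fit_terminal_velocity(track_from_positions(trk, 2, 1 / 30))$slope_um_s
  })
  se_mean <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 551.6), 2 * se_mean)
})

test_that("r-squared decreases with localization noise on average", {
  set.seed(31)
  mean_r2 <- vapply(c(0.25, 1, 4), function(sig_px) {
    mean(replicate(40, {
      trk <- make_linear_track(300, n_frames = 20)
      trk$row_px <- trk$row_px + rnorm(20, 0, sig_px)
      fit_terminal_velocity(track_from_positions(trk, 2, 1 / 30))$r_squared
    }))
  }, numeric(1))
  expect_true(all(diff(mean_r2) < 0))
})
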