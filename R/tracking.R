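# Bright-field tracking of a single falling spheroid: per-frame segmentation
# and circular-reference assignment, track assembly across frames, and the
# per-repetition terminal-velocity regression.
#
# Raster convention: frames are numeric matrices; the ROW index increases
# along the fall direction (gravity), so the regression slope of vertical
# position against time is positive for a sinking object. Pixel centers sit
# at integer coordinates.

#' Frame sequence of one free-fall repetition
#'
#' @param frames List of single-channel numeric matrices, all the same
#'   dimension.
#' @param pixel_size Pixel size, um/px (> 0).
#' @param frame_interval Time between consecutive frames, s (> 0).
#' @return Object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, pixel_size, frame_interval) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop_invalid("frames must be a non-empty list of matrices")
  }
  dims <- vapply(frames, function(f) {
    if (!is.matrix(f) || !is.numeric(f)) {
      stop_invalid("every frame must be a numeric matrix (single channel)")
    }
    dim(f)
  }, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_invalid("all frames must share the same dimensions")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop_invalid("pixel_size must be a single positive number (um/px)")
  }
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      frame_interval <= 0) {
    stop_invalid("frame_interval must be a single positive number (s)")
  }
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "frame_sequence")
}

component_boundary <- function(mask) {
  # pixels of the component with a 4-neighbour outside it (or on the edge)
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(FALSE, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- padded[2:(nr + 1L), 2:(nc + 1L)]
  nb <- padded[1:nr, 2:(nc + 1L)] & padded[3:(nr + 2L), 2:(nc + 1L)] &
    padded[2:(nr + 1L), 1:nc] & padded[2:(nr + 1L), 3:(nc + 2L)]
  which(core & !nb, arr.ind = TRUE)
}

#' Detect the falling spheroid in one bright-field frame
#'
#' Segments the dark object against the bright background with an Otsu
#' histogram-split threshold, fills holes, labels connected components,
#' drops components below `min_area`, and fits the circular reference (the
#' minimal enclosing circle of the component) to the surviving candidate.
#' Ties among candidates are broken by proximity to the previous detection,
#' else by area. The sub-pixel centroid is the intensity-weighted first
#' moment of the component (weight = background level minus intensity).
#'
#' @param frame Numeric matrix, single channel; rows run along the fall
#'   direction.
#' @param prior Optional previous detection (used to pick among multiple
#'   candidates).
#' @param min_area Minimum component area in px^2 (default 500).
#' @param min_contrast Minimum relative contrast (background mean minus
#'   object mean, over background mean) below which the detection is flagged
#'   `low_contrast`.
#' @return Object of class `spheroid_detection`: list with `centroid`
#'   (row, col in px, continuous), `radius_px`, `area_px2`, `quality`
#'   (one of ok, low_contrast, touching_border, multiple_candidates).
#' @export
detect_spheroid <- function(frame, prior = NULL, min_area = 500,
                            min_contrast = 0.1) {
  if (!is.matrix(frame) || !is.numeric(frame) || length(frame) == 0L) {
    stop_invalid("frame must be a non-empty numeric matrix")
  }
  rng <- range(frame)
  if (diff(rng) <= 0) {
    stop_data("no object detected: frame has uniform intensity",
              class = "spherofall_no_detection")
  }
  norm <- (frame - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm))
  mask <- norm < thr # dark object on bright background
  mask <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0.5
  labels <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labels <- EBImage::imageData(labels)
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= min_area)
  if (length(keep) == 0L) {
    stop_data(sprintf(
      "no object detected: no component reaches the minimum area of %d px^2",
      as.integer(min_area)
    ), class = "spherofall_no_detection")
  }

  cents <- t(vapply(keep, function(k) {
    idx <- which(labels == k, arr.ind = TRUE)
    colMeans(idx)
  }, numeric(2)))
  pick <- if (!is.null(prior) && length(keep) > 1L) {
    d2 <- (cents[, 1] - prior$centroid[1])^2 + (cents[, 2] - prior$centroid[2])^2
    which.min(d2)
  } else {
    which.max(areas[keep])
  }
  lab <- keep[pick]
  comp <- labels == lab
  idx <- which(comp, arr.ind = TRUE)

  touching <- any(idx[, 1] == 1L) || any(idx[, 1] == nrow(frame)) ||
    any(idx[, 2] == 1L) || any(idx[, 2] == ncol(frame))

  bg_mean <- mean(frame[!mask])
  obj_mean <- mean(frame[comp])
  contrast <- (bg_mean - obj_mean) / bg_mean

  # sub-pixel centroid: intensity-weighted moments (darker = heavier)
  w <- pmax(bg_mean - frame[comp], 0)
  centroid <- if (sum(w) > 0) {
    c(sum(idx[, 1] * w), sum(idx[, 2] * w)) / sum(w)
  } else {
    colMeans(idx)
  }

  circ <- min_enclosing_circle(component_boundary(comp))

  quality <- if (touching) "touching_border"
  else if (length(keep) > 1L) "multiple_candidates"
  else if (contrast < min_contrast) "low_contrast"
  else "ok"

  structure(
    list(centroid = centroid, radius_px = circ$radius,
         circle_center = circ$center, area_px2 = length(w),
         quality = quality),
    class = "spheroid_detection"
  )
}

empty_detections <- function() {
  data.frame(frame = integer(), time_s = numeric(), row_px = numeric(),
             col_px = numeric(), radius_px = numeric(), area_px2 = numeric(),
             quality = character(), stringsAsFactors = FALSE)
}

#' Assemble the position track of one repetition
#'
#' Runs [detect_spheroid()] on every frame, chaining each detection as the
#' prior for the next. Frames where nothing is detected are recorded as gaps
#' (no interpolation; the regression simply skips them). The per-repetition
#' maximum radius -- the quantity entering the final-radius rule -- is the
#' maximum over detections with quality `ok`.
#'
#' @param sequence A [frame_sequence()].
#' @param min_frames Minimum number of frames required (default 5).
#' @param min_area,min_contrast Passed to [detect_spheroid()].
#' @param repetition_id Identifier stored on the track.
#' @return Object of class `repetition_track` with the per-frame detection
#'   table, regression fields unset (see [fit_terminal_velocity()]).
#' @export
extract_track <- function(sequence, min_frames = 5, min_area = 500,
                          min_contrast = 0.1, repetition_id = 1L) {
  if (!inherits(sequence, "frame_sequence")) {
    stop_invalid("sequence must be a frame_sequence object")
  }
  n <- length(sequence$frames)
  if (n < min_frames) {
    stop_data(sprintf("sequence has %d frames; at least %d required",
                      n, as.integer(min_frames)),
              class = "spherofall_track_too_short")
  }
  prior <- NULL
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    det <- tryCatch(
      detect_spheroid(sequence$frames[[i]], prior = prior,
                      min_area = min_area, min_contrast = min_contrast),
      spherofall_no_detection = function(e) NULL
    )
    t_i <- (i - 1) * sequence$frame_interval
    if (is.null(det)) {
      rows[[i]] <- data.frame(frame = i, time_s = t_i, row_px = NA_real_,
                              col_px = NA_real_, radius_px = NA_real_,
                              area_px2 = NA_real_, quality = "gap",
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(frame = i, time_s = t_i,
                              row_px = det$centroid[1],
                              col_px = det$centroid[2],
                              radius_px = det$radius_px,
                              area_px2 = det$area_px2,
                              quality = det$quality,
                              stringsAsFactors = FALSE)
      if (det$quality %in% c("ok", "multiple_candidates")) prior <- det
    }
  }
  detections <- do.call(rbind, rows)
  new_repetition_track(detections, sequence$pixel_size,
                       sequence$frame_interval, repetition_id)
}

new_repetition_track <- function(detections, pixel_size, frame_interval,
                                 repetition_id = 1L) {
  ok <- detections$quality == "ok"
  if (sum(ok) < 3L) {
    stop_data(sprintf(
      "track has %d usable detections; at least 3 required", sum(ok)
    ), class = "spherofall_track_too_short")
  }
  max_radius_px <- max(detections$radius_px[ok])
  structure(
    list(repetition_id = repetition_id, detections = detections,
         pixel_size = pixel_size, frame_interval = frame_interval,
         n_ok = sum(ok), n_gaps = sum(detections$quality == "gap"),
         max_radius_px = max_radius_px,
         max_radius_um = max_radius_px * pixel_size,
         slope_um_s = NA_real_, intercept_um = NA_real_,
         r_squared = NA_real_, slope_stderr_um_s = NA_real_),
    class = "repetition_track"
  )
}

#' Build a repetition track from pre-extracted positions
#'
#' Accepts a table in the tracks.csv schema (`frame`, `time_s`, `row_px`,
#' `col_px`, `radius_px`, `quality`; `quality` defaults to ok) so that the
#' downstream regression and aggregation can run without image data.
#'
#' @param positions Data frame of per-frame positions.
#' @param pixel_size um/px.
#' @param frame_interval s; used to fill `time_s` when absent.
#' @param repetition_id Identifier stored on the track.
#' @return A `repetition_track` (regression unfitted).
#' @export
track_from_positions <- function(positions, pixel_size, frame_interval,
                                 repetition_id = 1L) {
  req <- c("frame", "row_px", "radius_px")
  missing_cols <- setdiff(req, names(positions))
  if (length(missing_cols) > 0) {
    stop_invalid(paste0("positions table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  positions <- positions[order(positions$frame), , drop = FALSE]
  if (anyDuplicated(positions$frame)) {
    stop_invalid("positions table has duplicated frame indices")
  }
  if (is.null(positions$time_s)) {
    positions$time_s <- (positions$frame - min(positions$frame)) *
      frame_interval
  }
  if (is.null(positions$col_px)) positions$col_px <- NA_real_
  if (is.null(positions$quality)) positions$quality <- "ok"
  if (is.null(positions$area_px2)) positions$area_px2 <- NA_real_
  detections <- positions[, c("frame", "time_s", "row_px", "col_px",
                              "radius_px", "area_px2", "quality")]
  new_repetition_track(detections, pixel_size, frame_interval, repetition_id)
}

#' Fit the terminal velocity of one repetition
#'
#' Ordinary least-squares regression of vertical position (um, increasing
#' along the fall) against time (s); the slope is the repetition's terminal
#' velocity. Only detections with quality `ok` enter the fit; gaps are
#' skipped (OLS tolerates irregular sampling). Optionally the first
#' `discard_first` usable points are dropped (the Stokes velocity-relaxation
#' time of a 100 um spheroid is milliseconds, far below one frame interval,
#' so the default discards nothing).
#'
#' @param track A `repetition_track`.
#' @param discard_first Number of initial usable detections to drop
#'   (default 0).
#' @return The track with `slope_um_s`, `intercept_um`, `r_squared` and
#'   `slope_stderr_um_s` populated.
#' @export
fit_terminal_velocity <- function(track, discard_first = 0) {
  if (!inherits(track, "repetition_track")) {
    stop_invalid("track must be a repetition_track")
  }
  d <- track$detections
  use <- which(d$quality == "ok")
  if (discard_first > 0) use <- use[-seq_len(min(discard_first, length(use)))]
  if (length(use) < 3L) {
    stop_data("fewer than 3 usable detections after discarding",
              class = "spherofall_insufficient_data")
  }
  t <- d$time_s[use]
  z <- d$row_px[use] * track$pixel_size
  if (diff(range(t)) <= 0) {
    stop_invalid("zero time span: all usable detections share one timestamp")
  }
  fit <- stats::lm(z ~ t)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope)) {
    stop_data("terminal-velocity fit produced a non-finite slope",
              class = "spherofall_invalid_track")
  }
  # r^2 and slope SE computed directly (summary.lm warns on zero-residual
  # fits, which are routine on noiseless synthetic tracks)
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  tss <- sum((z - mean(z))^2)
  n <- length(use)
  track$slope_um_s <- slope
  track$intercept_um <- unname(stats::coef(fit)[1])
  track$r_squared <- if (tss > 0) 1 - rss / tss else as.numeric(rss == 0)
  track$slope_stderr_um_s <- sqrt(rss / (n - 2) / sum((t - mean(t))^2))
  track
}

#' @export
print.repetition_track <- function(x, ...) {
  cat(sprintf(
    "Repetition %s: %d detections (%d ok, %d gaps), max radius %.2f um\n",
    format(x$repetition_id), nrow(x$detections), x$n_ok, x$n_gaps,
    x$max_radius_um
  ))
  if (is.finite(x$slope_um_s)) {
    cat(sprintf("  terminal velocity %.2f um/s (r^2 = %.4f, se %.3f)\n",
                x$slope_um_s, x$r_squared, x$slope_stderr_um_s))
  } else {
    cat("  regression not yet fitted\n")
  }
  invisible(x)
}
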