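# Per-spheroid aggregation and the cohort-level statistics chain:
# Shapiro-Wilk normality screening over the four reported metrics (terminal
# velocity, mass density, diameter, weight), Tukey box-plot fences for
# outlier identification where normality fails, any-metric removal, a
# normality re-check on the survivors, and pooled two-sample t-tests with
# percent change for treatment comparisons.

QC_METRICS <- c(velocity = "velocity_um_s", density = "mass_density_fg_um3",
                diameter = "diameter_um", weight = "weight_ng")

#' Aggregate the repetitions of one spheroid into its physical result
#'
#' Final-radius rule: the spheroid radius is the mean over repetitions of
#' each repetition's maximum detected radius. The terminal velocity is the
#' mean of the per-repetition regression slopes. Mass density and weight
#' are computed from the aggregated (velocity, radius) pair through the
#' inverse Stokes model; per-metric dispersions come from the
#' per-repetition values.
#'
#' @param tracks List of fitted `repetition_track` objects (>= 3).
#' @param fluid A [fluid_properties()] object.
#' @param spheroid_id Identifier stored on the result.
#' @param condition Condition label stored on the result.
#' @param g,wall_correction Passed to the physics.
#' @param reynolds_threshold Stokes-regime guard (see [reynolds_number()]).
#' @return Object of class `spheroid_result`; see
#'   [results_table()] for the tabular form.
#' @export
aggregate_repetitions <- function(tracks, fluid = fluid_properties(),
                                  spheroid_id = "S001",
                                  condition = "untreated", g = GRAVITY,
                                  wall_correction = 1,
                                  reynolds_threshold = 0.1) {
  if (!is.list(tracks) || length(tracks) < 3L) {
    stop_data("at least 3 fitted repetitions are required per spheroid",
              class = "spherofall_insufficient_repetitions")
  }
  fluid <- as_fluid(fluid)
  slopes <- vapply(tracks, function(tr) {
    if (!inherits(tr, "repetition_track")) {
      stop_invalid("tracks must be repetition_track objects")
    }
    tr$slope_um_s
  }, numeric(1))
  radii <- vapply(tracks, `[[`, numeric(1), "max_radius_um")
  if (any(!is.finite(slopes))) {
    stop_data("unfitted or non-finite repetition slope; fit all tracks first",
              class = "spherofall_invalid_track")
  }
  r_bar <- mean(radii)
  v_bar <- mean(slopes)
  phys <- spheroid_physical(v_bar, r_bar, fluid, g, wall_correction,
                            reynolds_threshold)
  # per-repetition densities/weights for the dispersion columns
  rho_i <- mass_density_from_motion(slopes, radii, fluid, g, wall_correction)
  w_i <- weight_and_volume(rho_i, radii)$weight_ng
  structure(
    list(spheroid_id = spheroid_id, condition = condition,
         n_repetitions = length(tracks),
         radius_um = r_bar, diameter_um = 2 * r_bar,
         terminal_velocity_um_s = v_bar,
         mass_density_fg_um3 = phys$mass_density_fg_um3,
         weight_ng = phys$weight_ng, volume_um3 = phys$volume_um3,
         reynolds = phys$reynolds, buoyancy_flag = phys$buoyancy_flag,
         diameter_sd = 2 * stats::sd(radii),
         velocity_sd = stats::sd(slopes),
         density_sd = stats::sd(rho_i), weight_sd = stats::sd(w_i),
         qc_flag = "kept", flagged_metrics = ""),
    class = "spheroid_result"
  )
}

#' @export
print.spheroid_result <- function(x, ...) {
  cat(sprintf(
    paste0("%s [%s]: diameter %.1f +/- %.1f um, weight %.1f ng, ",
           "density %.1f fg/um^3 (n = %d reps)\n"),
    x$spheroid_id, x$condition, x$diameter_um, x$diameter_sd, x$weight_ng,
    x$mass_density_fg_um3, x$n_repetitions
  ))
  invisible(x)
}

#' Tabulate spheroid results
#'
#' @param results List of `spheroid_result` objects (or a single one).
#' @return Data frame in the results.csv schema: `spheroid_id`,
#'   `condition`, `n_reps`, `diameter_um`, `diameter_sd`,
#'   `velocity_um_s`, `velocity_sd`, `mass_density_fg_um3`, `density_sd`,
#'   `weight_ng`, `weight_sd`, `qc_flag`, `flagged_metrics`.
#' @export
results_table <- function(results) {
  if (inherits(results, "spheroid_result")) results <- list(results)
  do.call(rbind, lapply(results, function(x) {
    data.frame(
      spheroid_id = x$spheroid_id, condition = x$condition,
      n_reps = x$n_repetitions, diameter_um = x$diameter_um,
      diameter_sd = x$diameter_sd,
      velocity_um_s = x$terminal_velocity_um_s,
      velocity_sd = x$velocity_sd,
      mass_density_fg_um3 = x$mass_density_fg_um3,
      density_sd = x$density_sd, weight_ng = x$weight_ng,
      weight_sd = x$weight_sd, qc_flag = x$qc_flag,
      flagged_metrics = x$flagged_metrics, stringsAsFactors = FALSE
    )
  }))
}

#' Measure a cohort from a position-track table
#'
#' Convenience wrapper running the per-repetition terminal-velocity
#' regression and the repetition aggregation for every spheroid in a
#' tracks table (shared tracks.csv schema).
#'
#' @param tracks Data frame with columns `spheroid_id`, `repetition`,
#'   `frame`, `time_s`, `row_px`, `radius_px`, `quality`.
#' @param pixel_size um/px.
#' @param frame_interval s (used only when `time_s` is absent).
#' @param fluid A [fluid_properties()] object.
#' @param condition Condition label stored on the results.
#' @param discard_first Initial detections to drop per repetition.
#' @param g,wall_correction,reynolds_threshold Passed to the physics.
#' @return Results data frame ([results_table()] schema).
#' @export
measure_tracks <- function(tracks, pixel_size, frame_interval = 1 / 30,
                           fluid = fluid_properties(),
                           condition = "untreated", discard_first = 0,
                           g = GRAVITY, wall_correction = 1,
                           reynolds_threshold = 0.1) {
  fluid <- as_fluid(fluid)
  results_table(lapply(unique(tracks$spheroid_id), function(id) {
    sub <- tracks[tracks$spheroid_id == id, , drop = FALSE]
    fitted <- lapply(sort(unique(sub$repetition)), function(r) {
      tr <- track_from_positions(sub[sub$repetition == r, , drop = FALSE],
                                 pixel_size, frame_interval,
                                 repetition_id = r)
      fit_terminal_velocity(tr, discard_first = discard_first)
    })
    aggregate_repetitions(fitted, fluid, spheroid_id = id,
                          condition = condition, g = g,
                          wall_correction = wall_correction,
                          reynolds_threshold = reynolds_threshold)
  }))
}

#' Shapiro-Wilk normality screen
#'
#' @param values Numeric vector of per-spheroid metric values (n >= 3).
#' @param alpha Significance level (default 0.05).
#' @return List with `statistic`, `p_value`, `normal` (p >= alpha).
#' @export
shapiro_screen <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) {
    stop_data("Shapiro-Wilk screen needs at least 3 finite values",
              class = "spherofall_insufficient_data")
  }
  if (diff(range(values)) == 0) {
    stop_data("Shapiro-Wilk screen undefined for a constant sample",
              class = "spherofall_degenerate_input")
  }
  ht <- stats::shapiro.test(values)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       normal = ht$p.value >= alpha)
}

#' Tukey box-plot fences and outlier flags
#'
#' Quartiles by linear interpolation between order statistics
#' (`stats::quantile` type 7); fences at Q1 - k IQR and Q3 + k IQR with
#' k = 1.5. Values strictly outside the fences are flagged; values exactly
#' on a fence are not.
#'
#' @param values Numeric vector (n >= 4).
#' @param ids Optional identifiers parallel to `values`; flagged ids are
#'   returned instead of indices.
#' @param k Fence multiplier (default 1.5).
#' @return List with `fences` (lower, upper), `flagged` (ids or indices),
#'   `quartiles`.
#' @export
tukey_outlier_flags <- function(values, ids = NULL, k = 1.5) {
  if (length(values) < 4L) {
    stop_data("Tukey fences need at least 4 values",
              class = "spherofall_insufficient_data")
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  fences <- c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
  out <- which(values < fences[1] | values > fences[2])
  flagged <- if (is.null(ids)) out else ids[out]
  list(fences = fences, flagged = flagged,
       quartiles = c(q1 = q[1], q3 = q[2]))
}

#' Multi-metric outlier removal over a cohort
#'
#' Runs the Shapiro-Wilk screen per metric (terminal velocity, mass
#' density, diameter, weight); where a metric is non-normal (or always,
#' with `force_screen = TRUE`), identifies Tukey-fence outliers for that
#' metric. One flag in any metric removes the spheroid (any-metric rule).
#' Normality is re-checked on the survivors.
#'
#' @param results Results data frame ([results_table()] schema), one cohort
#'   (one condition); n >= 4.
#' @param alpha Shapiro-Wilk significance level (default 0.05).
#' @param force_screen If `TRUE`, apply the Tukey screen to every metric
#'   regardless of the normality verdict.
#' @return Object of class `cohort_qc`: per-metric before/after
#'   Shapiro-Wilk results, per-metric fences (screened metrics only),
#'   outlier ledger (spheroid_id, metric, value), removed ids, and the
#'   results table with `qc_flag` / `flagged_metrics` updated.
#' @export
apply_removal_rule <- function(results, alpha = 0.05, force_screen = FALSE) {
  if (!is.data.frame(results) || nrow(results) < 4L) {
    stop_data("cohort QC needs at least 4 spheroids",
              class = "spherofall_insufficient_data")
  }
  missing_cols <- setdiff(unname(QC_METRICS), names(results))
  if (length(missing_cols) > 0) {
    stop_invalid(paste0("results table lacks metric column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  screen_one <- function(values) {
    tryCatch(shapiro_screen(values, alpha),
             spherofall_degenerate_input = function(e) {
               list(statistic = NA_real_, p_value = NA_real_, normal = NA,
                    degenerate = TRUE)
             })
  }
  before <- lapply(QC_METRICS, function(col) screen_one(results[[col]]))
  fences <- list()
  ledger <- list()
  for (m in names(QC_METRICS)) {
    sw <- before[[m]]
    degenerate <- isTRUE(sw$degenerate)
    screen <- !degenerate && (force_screen || !isTRUE(sw$normal))
    if (!screen) next
    tk <- tukey_outlier_flags(results[[QC_METRICS[m]]],
                              ids = results$spheroid_id)
    fences[[m]] <- tk$fences
    if (length(tk$flagged) > 0) {
      ledger[[m]] <- data.frame(
        spheroid_id = tk$flagged, metric = m,
        value = results[[QC_METRICS[m]]][match(tk$flagged,
                                               results$spheroid_id)],
        stringsAsFactors = FALSE
      )
    }
  }
  ledger <- if (length(ledger) > 0) do.call(rbind, ledger) else
    data.frame(spheroid_id = character(), metric = character(),
               value = numeric(), stringsAsFactors = FALSE)
  rownames(ledger) <- NULL
  removed <- unique(ledger$spheroid_id)
  keep <- !(results$spheroid_id %in% removed)
  if (sum(keep) < 3L) {
    stop_data("outlier removal left fewer than 3 spheroids in the cohort",
              class = "spherofall_cohort_degenerate")
  }
  results$qc_flag <- ifelse(keep, "kept", "removed")
  results$flagged_metrics <- vapply(results$spheroid_id, function(id) {
    paste(ledger$metric[ledger$spheroid_id == id], collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  after <- lapply(QC_METRICS, function(col) screen_one(results[[col]][keep]))
  structure(
    list(shapiro_before = before, shapiro_after = after, fences = fences,
         ledger = ledger, removed = removed, results = results,
         alpha = alpha, force_screen = force_screen,
         n_before = nrow(results), n_after = sum(keep)),
    class = "cohort_qc"
  )
}

#' @export
print.cohort_qc <- function(x, ...) {
  cat(sprintf("Cohort QC: %d -> %d spheroids (alpha = %g%s)\n",
              x$n_before, x$n_after, x$alpha,
              if (x$force_screen) ", forced screening" else ""))
  if (nrow(x$ledger) == 0) {
    cat("  no outliers flagged\n")
  } else {
    for (i in seq_len(nrow(x$ledger))) {
      cat(sprintf("  %s flagged on %s (%.4g)\n", x$ledger$spheroid_id[i],
                  x$ledger$metric[i], x$ledger$value[i]))
    }
  }
  invisible(x)
}

#' Compare two cohorts on one metric
#'
#' Percent change 100 (treated mean - control mean) / control mean
#' (signed; negative = loss under treatment) and a two-tailed unpaired
#' Student's t-test with pooled variance.
#'
#' @param control,treated Results data frames ([results_table()] schema),
#'   QC-passed, n >= 3 each.
#' @param metric One of `"velocity"`, `"density"`, `"diameter"`,
#'   `"weight"`.
#' @return One-row data frame: `metric`, `mean_ctrl`, `sd_ctrl`,
#'   `mean_treat`, `sd_treat`, `percent_change`, `t`, `p`, `n_ctrl`,
#'   `n_treat`.
#' @export
compare_cohorts <- function(control, treated, metric = "weight") {
  metric <- match.arg(metric, names(QC_METRICS))
  col <- QC_METRICS[[metric]]
  for (nm in c("control", "treated")) {
    tbl <- get(nm)
    if (!is.data.frame(tbl) || is.null(tbl[[col]])) {
      stop_invalid(sprintf("%s must be a results table with column %s",
                           nm, col))
    }
  }
  x <- control[[col]][is.finite(control[[col]])]
  y <- treated[[col]][is.finite(treated[[col]])]
  if (length(x) < 3L || length(y) < 3L) {
    stop_data("both cohorts need at least 3 spheroids after QC",
              class = "spherofall_insufficient_data")
  }
  if (mean(x) == 0) {
    stop_data("percent change undefined: control mean is zero",
              class = "spherofall_undefined_percent_change")
  }
  if (stats::var(x) + stats::var(y) == 0) {
    stop_data("pooled variance is zero: both cohorts are constant",
              class = "spherofall_degenerate_variance")
  }
  ht <- stats::t.test(y, x, var.equal = TRUE)
  data.frame(
    metric = metric, mean_ctrl = mean(x), sd_ctrl = stats::sd(x),
    mean_treat = mean(y), sd_treat = stats::sd(y),
    percent_change = 100 * (mean(y) - mean(x)) / mean(x),
    t = unname(ht$statistic), p = ht$p.value,
    n_ctrl = length(x), n_treat = length(y), stringsAsFactors = FALSE
  )
}

#' Compare two cohorts on all four metrics
#'
#' @inheritParams compare_cohorts
#' @param condition_pair Label stored on the output rows (e.g.
#'   "sw620 vs sw620_nk_6h").
#' @return Data frame with one [compare_cohorts()] row per metric, prefixed
#'   by `condition_pair`.
#' @export
compare_all_metrics <- function(control, treated, condition_pair = "") {
  out <- do.call(rbind, lapply(names(QC_METRICS), function(m) {
    compare_cohorts(control, treated, m)
  }))
  cbind(data.frame(condition_pair = condition_pair,
                   stringsAsFactors = FALSE), out)
}
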