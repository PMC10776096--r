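# Descriptive statistics, alignment-error comparison and the cosine
# correction for velocities measured along the horizontal image axis.

#' Descriptive summary of a numeric vector
#'
#' Reports the mean together with both standard-deviation conventions: the
#' population form (divide by n) and the sample form (divide by n - 1). The
#' bundled reference tables of the probe-alignment study use the population
#' convention, which `table_stats()` reproduces to two decimals.
#'
#' @param values Numeric vector, length >= 1.
#' @return An object of class `summary_stat`: `n`, `mean`, `std_population`,
#'   `std_sample` (0 for a single value).
#' @export
descriptive_stats <- function(values) {
  if (length(values) < 1 || !is.numeric(values))
    pa_stop("pa_param_error", "values must be a non-empty numeric vector")
  n <- length(values)
  m <- mean(values)
  sp <- sqrt(mean((values - m)^2))
  ss <- if (n > 1) sd(values) else 0
  structure(list(n = n, mean = m, std_population = sp, std_sample = ss),
            class = "summary_stat")
}

#' @export
print.summary_stat <- function(x, ...) {
  cat(sprintf("<summary_stat> n = %d, mean = %.4f, sd(pop) = %.4f, sd(sample) = %.4f\n",
              x$n, x$mean, x$std_population, x$std_sample))
  invisible(x)
}

#' Compare alignment-error means between conditions
#'
#' @param mean_manual Mean absolute alignment error during manual alignment
#'   (degrees, >= 0).
#' @param mean_automatic Mean absolute alignment error during automatic
#'   alignment (degrees, >= 0).
#' @return An object of class `condition_comparison`: `abs_difference`
#'   (degrees) and `ratio` (manual / automatic, NA when the automatic mean is
#'   zero).
#' @export
compare_alignment_error <- function(mean_manual, mean_automatic) {
  if (mean_manual < 0 || mean_automatic < 0)
    pa_stop("pa_param_error", "means must be non-negative")
  structure(list(
    mean_manual = mean_manual, mean_automatic = mean_automatic,
    abs_difference = abs(mean_manual - mean_automatic),
    ratio = if (mean_automatic > 0) mean_manual / mean_automatic else NA_real_
  ), class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> |diff| = %.2f deg, manual/automatic = %s\n",
              x$abs_difference,
              ifelse(is.na(x$ratio), "NA", sprintf("%.2f", x$ratio))))
  invisible(x)
}

#' Cosine correction of shear-wave velocity
#'
#' SWV is computed from displacements along the horizontal image axis; when
#' the shear wave follows fibers at angle theta to that axis, the measured
#' velocity is the projection `v cos(theta)` and thus underestimates the
#' along-fiber velocity by a factor of cos(theta). This function inverts the
#' projection.
#'
#' @param measured_swv Measured velocity in m/s (vectorized).
#' @param fiber_angle Fiber angle in degrees, `|angle| < 90` (vectorized).
#' @return Corrected SWV `measured_swv / cos(fiber_angle)` in m/s.
#' @export
cosine_correction <- function(measured_swv, fiber_angle) {
  if (any(abs(fiber_angle) >= 90))
    pa_stop("pa_domain_error", "|fiber_angle| must be below 90 degrees")
  measured_swv / cos(fiber_angle * pi / 180)
}

#' Alignment-error surrogate from a per-frame angle trace
#'
#' Computes the mean absolute fiber angle relative to the horizontal image
#' axis over a trial, applying the same leading 2-s discard as the SWV
#' analysis for contraction trial types. When a list of traces is supplied
#' (the repetitions of a task), each repetition is summarized and the
#' repetition means are averaged.
#'
#' @param per_frame_angles Numeric vector of per-frame angles in degrees, or
#'   a list of such vectors (one per repetition).
#' @param trial_type Trial-type label, see [normalize_trial_type()].
#' @param frame_rate Sampling rate of the trace in Hz.
#' @param discard_seconds Leading seconds discarded for contraction trials
#'   (default 2).
#' @return Mean absolute angle in degrees.
#' @export
angle_trace_summary <- function(per_frame_angles, trial_type, frame_rate,
                                discard_seconds = 2) {
  if (is.list(per_frame_angles)) {
    reps <- vapply(per_frame_angles, angle_trace_summary, numeric(1),
                   trial_type = trial_type, frame_rate = frame_rate,
                   discard_seconds = discard_seconds)
    return(mean(reps))
  }
  if (length(per_frame_angles) == 0)
    pa_stop("pa_param_error", "empty angle trace")
  trial_type <- normalize_trial_type(trial_type)
  n_discard <- if (trial_type == "passive") 0L else
    as.integer(ceiling(discard_seconds * frame_rate))
  if (n_discard >= length(per_frame_angles))
    pa_stop("pa_empty_trial_error", "no frames left after the discard window")
  mean(abs(per_frame_angles[(n_discard + 1):length(per_frame_angles)]))
}

#' Bundled reference measurements
#'
#' Two small reference tables from a ten-participant probe-alignment study,
#' shipped with the package: the ankle range of motion (maximal dorsiflexion,
#' maximal plantarflexion and neutral angle, in degrees) and the maximum
#' voluntary contraction ankle torque per alignment condition (in Nm). They
#' exercise the descriptive statistics in table-reproduction mode.
#'
#' @return data.frame with one row per participant.
#' @export
ankle_rom_data <- function() {
  read.csv(system.file("extdata", "ankle_range_of_motion.csv",
                       package = "pennalign"))
}

#' @rdname ankle_rom_data
#' @export
mvc_torque_data <- function() {
  read.csv(system.file("extdata", "mvc_torque.csv", package = "pennalign"))
}

#' Summary table in the reference layout
#'
#' Appends `mean` and `std` rows to a per-participant table, using the
#' population standard deviation and half-away-from-zero rounding to two
#' decimals (the conventions of the bundled reference tables).
#'
#' @param df data.frame whose first column identifies participants and whose
#'   remaining columns are numeric.
#' @return data.frame with the participant rows followed by `mean` and `std`
#'   rows.
#' @export
table_stats <- function(df) {
  vals <- df[, -1, drop = FALSE]
  stats <- lapply(vals, function(col) {
    s <- descriptive_stats(col)
    c(mean = round2(s$mean), std = round2(s$std_population))
  })
  out <- rbind(
    data.frame(id = as.character(df[[1]]), vals, check.names = FALSE),
    data.frame(id = "mean",
               as.data.frame(lapply(stats, `[[`, "mean")), check.names = FALSE),
    data.frame(id = "std",
               as.data.frame(lapply(stats, `[[`, "std")), check.names = FALSE)
  )
  names(out)[-1] <- names(vals)
  rownames(out) <- NULL
  out
}
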