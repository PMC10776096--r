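# SWE color-map quantification and quality control
#
# Mean shear-wave velocity per frame is extracted from the color map by
# classifying pixels as colored (valid) vs grayscale and decoding colored
# pixels through the scale's lookup table. Two-level quality control: a frame
# is valid when at least 75% of its ROI pixels are colored; a trial is
# included when at least 30% of its analyzed frames are valid. For
# contraction trials the first two seconds are discarded before aggregation,
# and the (up to) three repetitions of a task are averaged.

#' Decode one SWE color-map frame
#'
#' Classifies each ROI pixel as colored via the channel-spread test (see
#' [channel_sd()]), maps each colored pixel to the nearest lookup-table entry
#' of the scale, converts the LUT index to velocity
#' `v = v_min + (v_max - v_min) * index / 255`, and averages over colored
#' pixels only. The frame is valid when the colored fraction is at least
#' `valid_min` (inclusive).
#'
#' @param frame_roi RGB array of the color-map ROI.
#' @param scale A [swe_scale()].
#' @param std_threshold Channel-spread threshold in gray levels (default 10).
#' @param valid_min Minimum colored-pixel fraction for a valid frame
#'   (default 0.75, inclusive).
#' @param frame_index Optional index stored in the result.
#' @return An object of class `frame_measurement`: `frame_index`, `mean_swv`
#'   (NA when no pixel is colored), `valid_fraction`, `is_valid`.
#' @export
decode_frame <- function(frame_roi, scale, std_threshold = 10,
                         valid_min = 0.75, frame_index = NA_integer_) {
  stopifnot(inherits(scale, "swe_scale"))
  if (length(frame_roi) == 0) pa_stop("pa_param_error", "empty ROI")
  if (is.matrix(frame_roi))
    frame_roi <- gray_to_rgb(frame_roi)
  colored <- channel_sd(frame_roi) > std_threshold
  valid_fraction <- mean(colored)
  mean_swv <- NA_real_
  if (any(colored)) {
    # frames are 8-bit captures; quantize, then do the nearest-LUT search
    # once per distinct color instead of once per pixel
    pix <- round(cbind(frame_roi[, , 1][colored], frame_roi[, , 2][colored],
                       frame_roi[, , 3][colored]))
    key <- pix[, 1] * 65536 + pix[, 2] * 256 + pix[, 3]
    ukey <- unique(key)
    upix <- pix[match(ukey, key), , drop = FALSE]
    lut <- scale$lut
    # nearest LUT entry: argmax of 2 p.l - |l|^2  ==  argmin of |p - l|^2
    score <- 2 * (upix %*% t(lut)) -
      matrix(rowSums(lut^2), nrow(upix), 256, byrow = TRUE)
    uidx <- max.col(score, ties.method = "first") - 1L
    idx <- uidx[match(key, ukey)]
    v <- scale$v_min + (scale$v_max - scale$v_min) * idx / 255
    mean_swv <- mean(v)
  }
  structure(list(frame_index = frame_index, mean_swv = mean_swv,
                 valid_fraction = valid_fraction,
                 is_valid = valid_fraction >= valid_min),
            class = "frame_measurement")
}

#' Decode every frame of a synthetic trial recording
#'
#' @param recording A [generate_trial()] result with `render = "roi"`.
#' @param std_threshold,valid_min Passed to [decode_frame()].
#' @return data.frame with one row per frame: `frame_index`, `mean_swv`,
#'   `valid_fraction`, `is_valid`.
#' @export
decode_trial <- function(recording, std_threshold = 10, valid_min = 0.75) {
  stopifnot(inherits(recording, "trial_recording"))
  if (recording$render != "roi")
    pa_stop("pa_param_error", "decode_trial needs a recording rendered as 'roi'")
  rows <- lapply(seq_along(recording$frames), function(i) {
    fm <- decode_frame(recording$frames[[i]]$swe, recording$scale,
                       std_threshold = std_threshold, valid_min = valid_min,
                       frame_index = i)
    data.frame(frame_index = i, mean_swv = fm$mean_swv,
               valid_fraction = fm$valid_fraction, is_valid = fm$is_valid)
  })
  do.call(rbind, rows)
}

frames_to_df <- function(frames) {
  if (is.data.frame(frames)) return(frames)
  rows <- lapply(frames, function(f) {
    stopifnot(inherits(f, "frame_measurement"))
    data.frame(frame_index = f$frame_index, mean_swv = f$mean_swv,
               valid_fraction = f$valid_fraction, is_valid = f$is_valid)
  })
  do.call(rbind, rows)
}

#' Aggregate per-frame measurements into a trial summary
#'
#' For contraction trial types (everything except `"passive"`) the first
#' `ceiling(discard_seconds * frame_rate)` frames are dropped to reduce the
#' influence of motion artifacts. The valid-frame fraction is computed over
#' the analyzed frames (frames failing the 75% pixel rule still count in the
#' denominator), the trial mean SWV averages the per-frame means of valid
#' frames only, and the trial is included when the valid-frame fraction is at
#' least `include_min` (inclusive).
#'
#' @param frames data.frame from [decode_trial()] (or a list of
#'   [decode_frame()] results).
#' @param trial_type Trial-type label, see [normalize_trial_type()].
#' @param frame_rate Video rate in Hz.
#' @param include_min Minimum valid-frame fraction for inclusion
#'   (default 0.30, inclusive).
#' @param discard_seconds Leading seconds discarded for contraction trials
#'   (default 2).
#' @return An object of class `trial_summary`: `trial_type`,
#'   `n_frames_total`, `n_frames_analyzed`, `valid_frame_fraction`,
#'   `mean_swv`, `included`, plus the quality percentages `pixels_pct` (mean
#'   colored-pixel fraction over analyzed frames, in %) and `frames_pct`
#'   (valid-frame fraction in %).
#' @export
summarize_trial <- function(frames, trial_type, frame_rate,
                            include_min = 0.30, discard_seconds = 2) {
  df <- frames_to_df(frames)
  if (nrow(df) == 0) pa_stop("pa_param_error", "no frames supplied")
  if (frame_rate <= 0) pa_stop("pa_param_error", "frame_rate must be positive")
  trial_type <- normalize_trial_type(trial_type)
  n_total <- nrow(df)
  n_discard <- if (trial_type == "passive") 0L else
    as.integer(ceiling(discard_seconds * frame_rate))
  if (n_discard >= n_total)
    pa_stop("pa_empty_trial_error",
            "all %d frames fall within the %g-s discard window", n_total,
            discard_seconds)
  analyzed <- df[(n_discard + 1):n_total, , drop = FALSE]
  vff <- mean(analyzed$is_valid)
  valid_swv <- analyzed$mean_swv[analyzed$is_valid]
  structure(list(trial_type = trial_type, n_frames_total = n_total,
                 n_frames_analyzed = nrow(analyzed),
                 valid_frame_fraction = vff,
                 mean_swv = if (length(valid_swv)) mean(valid_swv) else NA_real_,
                 included = vff >= include_min,
                 pixels_pct = mean(analyzed$valid_fraction) * 100,
                 frames_pct = vff * 100),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf(paste0("<trial_summary> %s: %d/%d frames analyzed, %.1f%% valid",
                     " frames, mean SWV %s m/s, %s\n"),
              x$trial_type, x$n_frames_analyzed, x$n_frames_total,
              100 * x$valid_frame_fraction,
              ifelse(is.na(x$mean_swv), "NA", sprintf("%.2f", x$mean_swv)),
              if (x$included) "included" else "EXCLUDED"))
  invisible(x)
}

#' Average trial repetitions per condition
#'
#' For each trial type the arithmetic mean of the per-trial mean SWV is taken
#' over the included repetitions only; excluded repetitions are dropped, not
#' zero-filled. Trial types whose repetitions are all excluded are flagged
#' missing (NA).
#'
#' @param trials List of [summarize_trial()] results (1-3 per trial type).
#' @param angles Optional numeric vector, one per trial, of per-trial mean
#'   fiber angles (e.g. from [angle_trace_summary()]); averaged the same way.
#' @return data.frame with one row per trial type: `trial_type`,
#'   `n_repetitions`, `n_included`, `mean_swv` and, when angles are given,
#'   `mean_angle`.
#' @export
summarize_condition <- function(trials, angles = NULL) {
  stopifnot(all(vapply(trials, inherits, logical(1), "trial_summary")))
  if (!is.null(angles) && length(angles) != length(trials))
    pa_stop("pa_param_error", "angles must have one entry per trial")
  types <- vapply(trials, `[[`, character(1), "trial_type")
  out <- lapply(unique(types), function(tt) {
    sel <- which(types == tt)
    inc <- sel[vapply(trials[sel], `[[`, logical(1), "included")]
    swv <- vapply(trials[inc], `[[`, numeric(1), "mean_swv")
    data.frame(
      trial_type = tt, n_repetitions = length(sel), n_included = length(inc),
      mean_swv = if (length(inc)) mean(swv) else NA_real_,
      mean_angle = if (is.null(angles)) NA_real_
      else if (length(inc)) mean(angles[inc]) else NA_real_
    )
  })
  res <- do.call(rbind, out)
  if (is.null(angles)) res$mean_angle <- NULL
  res
}
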