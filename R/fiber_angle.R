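# Muscle fiber orientation from B-mode images
#
# Fascicles appear as bright, roughly parallel lines in longitudinal B-mode
# images. The orientation relative to the horizontal image axis is estimated
# by (1) Canny edge detection with an adaptively raised threshold, (2) a
# probabilistic Hough line transform with an adaptively lowered accumulator
# threshold, and (3) the median of the detected segment angles.

#' Adaptive Canny edge detection
#'
#' Applies the Canny detector with lower threshold `t` and upper threshold
#' `2 t`, starting at `t = start` and incrementing by `step` until fewer than
#' `max_fraction` of the ROI pixels are edges. The first passing edge image is
#' returned together with the threshold used.
#'
#' @param roi Grayscale matrix (values 0-255).
#' @param start Initial lower threshold (default 50).
#' @param step Threshold increment (default 10).
#' @param max_fraction Maximum allowed fraction of edge pixels (default 0.10,
#'   exclusive: the loop stops when the fraction is strictly below it).
#' @param max_threshold Give up beyond this lower threshold (default 255).
#' @return List with `edges` (logical matrix), `threshold` (the final lower
#'   threshold) and `edge_fraction`.
#' @export
adaptive_canny <- function(roi, start = 50, step = 10, max_fraction = 0.10,
                           max_threshold = 255) {
  if (length(roi) == 0) pa_stop("pa_param_error", "empty ROI")
  t <- start
  while (t <= max_threshold) {
    edges <- canny_cpp(roi, t, 2 * t)
    frac <- mean(edges)
    if (frac < max_fraction)
      return(list(edges = edges, threshold = t, edge_fraction = frac))
    t <- t + step
  }
  pa_stop("pa_edge_error",
          "edge fraction never fell below %.0f%% for thresholds up to %d",
          100 * max_fraction, max_threshold)
}

#' Adaptive probabilistic Hough line detection
#'
#' Runs the probabilistic Hough line transform with accumulator threshold `h`
#' starting at `start` and decreasing by 1 until at least `min_lines` segments
#' are found. Each run is deterministic for the fixed internal seed, so the
#' adaptive loop is exactly equivalent to a brute-force sweep over `h`.
#'
#' @param edges Logical (binary) edge matrix.
#' @param start Initial accumulator threshold (default 100).
#' @param step Threshold decrement, negative (default -1).
#' @param min_lines Minimum number of segments required (default 10).
#' @param floor_threshold Stop and fail below this threshold (default 10); the
#'   failure propagates rather than returning an unreliable angle.
#' @param min_length Minimum accepted segment length in px; default 20% of
#'   the ROI width.
#' @param max_gap Maximum bridged gap along a line in px (default 5).
#' @param seed Seed for the randomized point selection (default 42; keep
#'   fixed for reproducibility).
#' @return List with `segments` (n x 4 matrix of endpoints x1,y1,x2,y2 in
#'   0-based pixel coordinates) and `threshold` (the final accumulator
#'   threshold).
#' @export
adaptive_hough <- function(edges, start = 100, step = -1, min_lines = 10,
                           floor_threshold = 10, min_length = NULL,
                           max_gap = 5, seed = 42) {
  if (is.null(min_length)) min_length <- 0.2 * ncol(edges)
  if (step >= 0) pa_stop("pa_param_error", "step must be negative")
  h <- start
  while (h >= floor_threshold) {
    segs <- hough_prob_cpp(edges, h, min_length, max_gap, seed)
    if (nrow(segs) >= min_lines)
      return(list(segments = segs, threshold = h))
    h <- h + step
  }
  pa_stop("pa_line_error",
          "fewer than %d line segments found down to threshold %d",
          min_lines, floor_threshold)
}

#' Angles of line segments relative to the horizontal image axis
#'
#' For a segment with endpoints (xa, ya), (xb, yb) the angle is
#' `atan2(ya - yb, xb - xa)` mapped to (-90, 90] degrees. Since y increases
#' downward on screen, positive angles correspond to lines ascending from
#' left to right.
#'
#' @param segments n x 4 matrix of endpoints (x1, y1, x2, y2).
#' @return Numeric vector of angles in degrees.
#' @export
segment_angles <- function(segments) {
  if (nrow(segments) == 0) return(numeric(0))
  a <- atan2(segments[, 2] - segments[, 4],
             segments[, 3] - segments[, 1]) * 180 / pi
  a <- ifelse(a > 90, a - 180, a)
  ifelse(a <= -90, a + 180, a)
}

#' Estimate the muscle fiber orientation of a B-mode ROI
#'
#' Composes [adaptive_canny()] and [adaptive_hough()] and reports the median
#' of the per-segment angles (the mean of the two middle values for even
#' counts) as the fiber orientation. The median makes the estimate robust to
#' a minority of spurious segments.
#'
#' @param roi Grayscale matrix of the B-mode region of interest.
#' @param canny_start,canny_step,max_edge_fraction Passed to
#'   [adaptive_canny()].
#' @param hough_start,min_lines,floor_threshold,min_length,max_gap,seed Passed
#'   to [adaptive_hough()].
#' @return An object of class `fiber_orientation`: `angle` (degrees in
#'   (-90, 90], positive = ascending left to right), `n_lines`,
#'   `canny_threshold`, `hough_threshold`, `edge_fraction` and the raw
#'   `segments`.
#' @export
estimate_fiber_angle <- function(roi, canny_start = 50, canny_step = 10,
                                 max_edge_fraction = 0.10, hough_start = 100,
                                 min_lines = 10, floor_threshold = 10,
                                 min_length = NULL, max_gap = 5, seed = 42) {
  ce <- adaptive_canny(roi, start = canny_start, step = canny_step,
                       max_fraction = max_edge_fraction)
  hl <- adaptive_hough(ce$edges, start = hough_start, min_lines = min_lines,
                       floor_threshold = floor_threshold,
                       min_length = min_length, max_gap = max_gap, seed = seed)
  angles <- segment_angles(hl$segments)
  structure(list(angle = median(angles), n_lines = nrow(hl$segments),
                 canny_threshold = ce$threshold, hough_threshold = hl$threshold,
                 edge_fraction = ce$edge_fraction, segments = hl$segments),
            class = "fiber_orientation")
}

#' @export
print.fiber_orientation <- function(x, ...) {
  cat(sprintf(paste0("<fiber_orientation> %.2f deg (%d segments; canny t = %d,",
                     " hough t = %d, edge fraction %.3f)\n"),
              x$angle, x$n_lines, x$canny_threshold, x$hough_threshold,
              x$edge_fraction))
  invisible(x)
}
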