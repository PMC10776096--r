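# ROI detection on dual-panel scanner screen frames
#
# Four-step procedure: locate the "S" symbol of each panel, take their
# horizontal distance d, find the colored SWE color-map pixels by per-pixel
# channel spread, and translate the SWE ROI left by d to obtain the B-mode
# ROI (the two ROIs share vertical coordinates). Detection is intended to run
# once per recording on the initial frame and be reused.

#' Rectangular pixel region
#'
#' Boxes are half-open, `[x1, x2) x [y1, y2)`, in 0-based pixel coordinates
#' with the origin at the image top-left and y increasing downward.
#'
#' @param x1,y1 Top-left corner (inclusive).
#' @param x2,y2 Bottom-right corner (exclusive).
#' @return An object of class `roi_box` with `width`/`height` accessors via
#'   `$`.
#' @export
roi_box <- function(x1, y1, x2, y2) {
  x1 <- as.integer(x1); y1 <- as.integer(y1)
  x2 <- as.integer(x2); y2 <- as.integer(y2)
  if (x1 < 0 || y1 < 0 || x2 <= x1 || y2 <= y1)
    pa_stop("pa_param_error", "invalid ROI box [%d,%d)x[%d,%d)", x1, x2, y1, y2)
  structure(list(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                 width = x2 - x1, height = y2 - y1),
            class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box> [%d,%d) x [%d,%d)  (%d x %d px)\n",
              x$x1, x$x2, x$y1, x$y2, x$width, x$height))
  invisible(x)
}

#' @export
format.roi_box <- function(x, ...) {
  sprintf("roi_box(%d, %d, %d, %d)", x$x1, x$y1, x$x2, x$y2)
}

#' Locate the "S" panel symbols in a screen frame
#'
#' Normalized cross-correlation template matching of the corner glyph against
#' the grayscale frame. The two highest-scoring, horizontally separated
#' matches above `min_score` are returned; the leftmost is assigned to the
#' B-mode panel.
#'
#' @param frame RGB screen frame.
#' @param template Binary glyph image (default the built-in [s_glyph()]).
#' @param min_score NCC acceptance score in (0, 1]; default 0.8.
#' @return An object of class `panel_anchors`: list with `s_bmode`, `s_swe`
#'   (each `c(x, y)` of the match's top-left corner), the horizontal distance
#'   `d`, and the two match scores.
#' @export
locate_symbols <- function(frame, template = s_glyph(), min_score = 0.8) {
  gray <- to_gray(frame)
  th <- nrow(template); tw <- ncol(template)
  if (th >= nrow(gray) || tw >= ncol(gray))
    pa_stop("pa_param_error", "template must be smaller than the frame")
  scores <- ncc_match_cpp(gray, template)
  hits <- which(scores >= min_score, arr.ind = TRUE)
  if (nrow(hits) < 1)
    pa_stop("pa_anchor_error", "no template matches above score %.2f", min_score)
  cand <- data.frame(x = hits[, 2] - 1L, y = hits[, 1] - 1L,
                     score = scores[hits])
  cand <- cand[order(-cand$score), , drop = FALSE]
  # greedy non-maximum suppression over the template footprint
  picked <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(picked) == 0 ||
        all(abs(picked$x - p$x) >= tw | abs(picked$y - p$y) >= th))
      picked <- rbind(picked, p)
    if (nrow(picked) >= 2) break
  }
  if (nrow(picked) < 2)
    pa_stop("pa_anchor_error",
            "fewer than two template matches above score %.2f", min_score)
  if (picked$x[1] == picked$x[2])
    pa_stop("pa_anchor_error",
            "the two matches are not horizontally separated (d must be > 0)")
  left <- picked[which.min(picked$x), ]
  right <- picked[which.max(picked$x), ]
  structure(list(s_bmode = c(x = left$x, y = left$y),
                 s_swe = c(x = right$x, y = right$y),
                 d = right$x - left$x,
                 scores = c(bmode = left$score, swe = right$score)),
            class = "panel_anchors")
}

#' @export
print.panel_anchors <- function(x, ...) {
  cat(sprintf("<panel_anchors> B-mode S at (%d, %d), SWE S at (%d, %d), d = %d px\n",
              x$s_bmode["x"], x$s_bmode["y"], x$s_swe["x"], x$s_swe["y"], x$d))
  invisible(x)
}

#' Locate the SWE color-map ROI
#'
#' Classifies a pixel as colored when the population standard deviation of
#' its three 8-bit channel values exceeds `std_threshold` (i.e. the pixel is
#' not a grayscale color) and returns the tight bounding box of all colored
#' pixels. When anchors are supplied the search is restricted to the region
#' right of the midpoint between the two "S" symbols, so colored UI elements
#' near the B-mode panel cannot leak in; without anchors the whole frame is
#' searched.
#'
#' @param frame RGB screen frame with 8-bit channel values.
#' @param anchors Optional [locate_symbols()] result.
#' @param std_threshold Channel-spread threshold in gray levels (default 10).
#' @return A [roi_box()] in frame coordinates.
#' @export
locate_swe_roi <- function(frame, anchors = NULL, std_threshold = 10) {
  spread <- channel_sd(frame)
  colored <- spread > std_threshold
  if (!is.null(anchors)) {
    x_min <- floor((anchors$s_bmode["x"] + anchors$s_swe["x"]) / 2)
    if (x_min > 0) colored[, seq_len(min(x_min, ncol(colored)))] <- FALSE
  }
  idx <- which(colored, arr.ind = TRUE)
  if (nrow(idx) == 0)
    pa_stop("pa_roi_error", "no colored pixels found (SWE ROI not detected)")
  xs <- idx[, 2] - 1L; ys <- idx[, 1] - 1L
  roi_box(min(xs), min(ys), max(xs) + 1L, max(ys) + 1L)
}

#' Translate the SWE ROI to the B-mode ROI
#'
#' Applies the panel correspondence `x_B = x_SWE - d`, `y_B = y_SWE`: the box
#' keeps its size, shifts left by the anchor distance `d`, and keeps its
#' vertical coordinates.
#'
#' @param swe_roi A [roi_box()] for the SWE color map.
#' @param anchors A [locate_symbols()] result (or any list with a `d` field).
#' @return A [roi_box()] for the B-mode panel.
#' @export
translate_to_bmode_roi <- function(swe_roi, anchors) {
  stopifnot(inherits(swe_roi, "roi_box"))
  d <- as.integer(anchors$d)
  if (swe_roi$x1 - d < 0)
    pa_stop("pa_geometry_error",
            "translated B-mode ROI exits the frame (x1 = %d, d = %d)",
            swe_roi$x1, d)
  roi_box(swe_roi$x1 - d, swe_roi$y1, swe_roi$x2 - d, swe_roi$y2)
}

#' Detect the full screen layout of a frame
#'
#' Convenience wrapper chaining [locate_symbols()], [locate_swe_roi()] and
#' [translate_to_bmode_roi()]. Run it on the initial frame of a recording and
#' reuse the result for subsequent frames.
#'
#' @inheritParams locate_symbols
#' @inheritParams locate_swe_roi
#' @return List with `s_bmode`, `s_swe`, `d`, `swe_roi`, `bmode_roi`.
#' @export
detect_layout <- function(frame, template = s_glyph(), min_score = 0.8,
                          std_threshold = 10) {
  anchors <- locate_symbols(frame, template, min_score)
  swe_roi <- locate_swe_roi(frame, anchors, std_threshold)
  bmode_roi <- translate_to_bmode_roi(swe_roi, anchors)
  list(s_bmode = anchors$s_bmode, s_swe = anchors$s_swe, d = anchors$d,
       swe_roi = swe_roi, bmode_roi = bmode_roi)
}

#' Write a detected layout as JSON
#' @param layout A [detect_layout()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_layout_json <- function(layout, path) {
  enc <- list(
    s_bmode = as.list(layout$s_bmode), s_swe = as.list(layout$s_swe),
    d = layout$d,
    swe_roi = layout$swe_roi[c("x1", "y1", "x2", "y2")],
    bmode_roi = layout$bmode_roi[c("x1", "y1", "x2", "y2")]
  )
  jsonlite::write_json(enc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
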