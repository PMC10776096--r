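# Synthetic phantom generator
#
# Everything downstream (ROI detection, fiber-angle estimation, SWE
# quantification, closed-loop control) is exercised against images produced
# here, with machine-readable ground truth, so no scanner is needed.

#' Phantom configuration for B-mode-like pennate muscle images
#'
#' Describes a synthetic B-mode texture: parallel bright fascicle-like lines
#' at a fixed angle over a darker background, with additive Gaussian speckle
#' surrogate noise and an optional bright aponeurosis band.
#'
#' @param image_width,image_height Image size in pixels.
#' @param fiber_angle Fiber orientation in degrees relative to the horizontal
#'   image axis, in (-90, 90]; positive angles ascend from left to right on
#'   screen (y increases downward).
#' @param fiber_spacing Perpendicular distance between line centers (px).
#' @param fiber_thickness Line thickness (px).
#' @param fiber_intensity,background_intensity 8-bit gray levels in [0, 255].
#' @param speckle_sigma Standard deviation of additive Gaussian noise (gray
#'   levels); `0` disables noise.
#' @param aponeurosis Optional `list(y = row, thickness = px,
#'   intensity = gray)` describing a bright horizontal band.
#' @param seed Integer seed; identical configurations render bit-identical
#'   images.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_width = 200, image_height = 200,
                           fiber_angle = 20, fiber_spacing = 28,
                           fiber_thickness = 3, fiber_intensity = 200,
                           background_intensity = 40, speckle_sigma = 5,
                           aponeurosis = NULL, seed = 1L) {
  if (image_width < 1 || image_height < 1)
    pa_stop("pa_param_error", "image dimensions must be positive")
  if (fiber_angle <= -90 || fiber_angle > 90)
    pa_stop("pa_param_error", "fiber_angle must lie in (-90, 90]")
  ints <- c(fiber_intensity, background_intensity)
  if (any(ints < 0 | ints > 255))
    pa_stop("pa_param_error", "intensities must lie in [0, 255]")
  if (speckle_sigma < 0)
    pa_stop("pa_param_error", "speckle_sigma must be >= 0")
  if (fiber_spacing <= 0 || fiber_thickness <= 0)
    pa_stop("pa_param_error", "fiber_spacing and fiber_thickness must be positive")
  structure(list(
    image_width = as.integer(image_width), image_height = as.integer(image_height),
    fiber_angle = fiber_angle, fiber_spacing = fiber_spacing,
    fiber_thickness = fiber_thickness, fiber_intensity = fiber_intensity,
    background_intensity = background_intensity, speckle_sigma = speckle_sigma,
    aponeurosis = aponeurosis, seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Render a synthetic B-mode phantom image
#'
#' Draws anti-aliased parallel bright lines at the configured angle, adds the
#' optional aponeurosis band and Gaussian speckle surrogate, and clips to
#' [0, 255]. Deterministic for a fixed seed.
#'
#' @param config A [phantom_config()].
#' @return Grayscale matrix `image_height x image_width`.
#' @export
generate_bmode_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  w <- config$image_width; h <- config$image_height
  th <- config$fiber_angle * pi / 180
  X <- matrix(0:(w - 1), h, w, byrow = TRUE)
  Y <- matrix(0:(h - 1), h, w)
  # signed distance along the normal (sin th, cos th) of the line family;
  # positive fiber_angle means lines ascend left->right in screen coordinates
  s <- sin(th) * X + cos(th) * Y
  sp <- config$fiber_spacing
  m <- (s - sp / 2) %% sp
  d <- pmin(m, sp - m)
  # full intensity inside the line, 1-px linear anti-aliasing rolloff
  prof <- clamp(config$fiber_thickness / 2 + 1 - d, 0, 1)
  img <- config$background_intensity +
    (config$fiber_intensity - config$background_intensity) * prof
  if (!is.null(config$aponeurosis)) {
    ap <- config$aponeurosis
    rows <- clamp(ap$y + seq_len(ap$thickness) - 1, 0, h - 1) + 1
    img[unique(rows), ] <- ap$intensity
  }
  if (config$speckle_sigma > 0) {
    img <- img + with_seed(config$seed,
                           matrix(rnorm(h * w, 0, config$speckle_sigma), h, w))
  }
  clamp(img, 0, 255)
}

#' SWE color scale definition
#'
#' Maps shear-wave velocities in `[v_min, v_max]` onto a 256-entry RGB lookup
#' table. The default is a blue-to-red gradient `(i, 0, 255 - i)` whose
#' entries are all strongly non-gray (per-pixel channel spread >= 69 gray
#' levels) and pairwise distinct; the real scanner colormap is unpublished, so
#' the scale is explicit configuration.
#'
#' @param v_min,v_max Velocity limits in m/s, `v_max > v_min`.
#' @param lut Optional 256 x 3 matrix of 8-bit RGB values ordered from
#'   `v_min` to `v_max`.
#' @return An object of class `swe_scale`.
#' @export
swe_scale <- function(v_min = 0, v_max = 10, lut = NULL) {
  if (v_max <= v_min) pa_stop("pa_param_error", "v_max must exceed v_min")
  if (is.null(lut)) lut <- cbind(0:255, 0L, 255:0)
  lut <- as.matrix(lut)
  if (!all(dim(lut) == c(256L, 3L)))
    pa_stop("pa_param_error", "lut must be a 256 x 3 RGB matrix")
  spread <- sqrt(rowMeans((lut - rowMeans(lut))^2))
  if (any(spread <= 10))
    pa_stop("pa_param_error",
            "all LUT entries must be non-gray (channel spread > 10)")
  if (anyDuplicated(lut))
    pa_stop("pa_param_error", "LUT entries must be pairwise distinct")
  structure(list(v_min = v_min, v_max = v_max, lut = lut), class = "swe_scale")
}

#' Encode a shear-wave velocity field as an SWE color map
#'
#' Each unmasked pixel is colored by the nearest lookup-table entry of the
#' scale; masked (invalid) pixels are rendered as grayscale, by default the
#' supplied underlay (e.g. the B-mode texture underneath, which is how the
#' scanner displays invalid regions).
#'
#' @param field Numeric matrix of velocities (m/s).
#' @param scale A [swe_scale()].
#' @param invalid_mask Optional logical matrix, `TRUE` for invalid pixels.
#' @param underlay Optional grayscale matrix used for invalid pixels; default
#'   is a mid-gray of 128.
#' @return RGB array `c(nrow(field), ncol(field), 3)`.
#' @export
encode_swv_field <- function(field, scale, invalid_mask = NULL, underlay = NULL) {
  stopifnot(inherits(scale, "swe_scale"))
  h <- nrow(field); w <- ncol(field)
  if (is.null(invalid_mask)) invalid_mask <- matrix(FALSE, h, w)
  valid <- !invalid_mask
  v <- field[valid]
  if (length(v) && (any(v < scale$v_min) || any(v > scale$v_max)))
    pa_stop("pa_param_error", "velocities outside [%g, %g] m/s",
            scale$v_min, scale$v_max)
  idx <- matrix(0L, h, w)
  idx[valid] <- as.integer(round((field[valid] - scale$v_min) /
                                   (scale$v_max - scale$v_min) * 255))
  if (is.null(underlay)) underlay <- matrix(128, h, w)
  out <- array(0, dim = c(h, w, 3L))
  for (k in 1:3) {
    ch <- matrix(scale$lut[idx + 1L, k], h, w)
    ch[invalid_mask] <- underlay[invalid_mask]
    out[, , k] <- ch
  }
  out
}

#' The "S" corner glyph template
#'
#' A fixed 9x9 binary template stamped into the top-left corner of each panel
#' of a generated screen frame; the same template drives the detector in
#' [locate_symbols()].
#'
#' @return 9x9 numeric matrix of 0/1.
#' @export
s_glyph <- function() {
  rows <- c(
    "111111111",
    "111111111",
    "110000000",
    "110000000",
    "111111111",
    "000000011",
    "000000011",
    "111111111",
    "111111111"
  )
  do.call(rbind, lapply(strsplit(rows, ""), as.numeric))
}

#' Screen frame layout for the dual-panel scanner display
#'
#' Geometry of a synthetic 640x480 scanner screen: the B-mode panel on the
#' left, an identical panel shifted right by `panel_offset` carrying the SWE
#' color map, an "S" glyph at the top-left corner of each panel, and the
#' color-map ROI at a fixed offset inside the right panel. The SWE and B-mode
#' ROIs share vertical coordinates by construction.
#'
#' @param frame_width,frame_height Frame size (default 640 x 480).
#' @param bmode_origin `c(x, y)` of the B-mode panel's top-left corner.
#' @param panel_offset Horizontal distance d between the two panels (px).
#' @param roi_offset `c(x, y)` of the color-map ROI inside its panel.
#' @param glyph_offset `c(x, y)` of the "S" glyph inside each panel.
#' @param background Frame background gray level.
#' @return An object of class `screen_layout_spec`.
#' @export
screen_layout_spec <- function(frame_width = 640, frame_height = 480,
                               bmode_origin = c(40, 80), panel_offset = 300,
                               roi_offset = c(30, 30), glyph_offset = c(4, 4),
                               background = 20) {
  structure(list(frame_width = as.integer(frame_width),
                 frame_height = as.integer(frame_height),
                 bmode_origin = as.integer(bmode_origin),
                 panel_offset = as.integer(panel_offset),
                 roi_offset = as.integer(roi_offset),
                 glyph_offset = as.integer(glyph_offset),
                 background = background),
            class = "screen_layout_spec")
}

#' Compose a dual-panel scanner screen frame
#'
#' Places the B-mode image as the left panel and a copy as the right panel
#' with the SWE color map composited at the ROI offset, stamps the "S" glyph
#' at the top-left corner of each panel, and records the ground-truth layout
#' (anchor positions, horizontal distance d, SWE and B-mode ROI boxes) as the
#' `"layout"` attribute for testing.
#'
#' @param bmode Grayscale panel image.
#' @param swe_panel RGB image of the color-map ROI contents.
#' @param layout A [screen_layout_spec()].
#' @return RGB array `frame_height x frame_width x 3` with attribute
#'   `"layout"`.
#' @export
generate_screen_frame <- function(bmode, swe_panel, layout = screen_layout_spec()) {
  stopifnot(inherits(layout, "screen_layout_spec"))
  ph <- nrow(bmode); pw <- ncol(bmode)
  fw <- layout$frame_width; fh <- layout$frame_height
  bx <- layout$bmode_origin[1]; by <- layout$bmode_origin[2]
  d <- layout$panel_offset
  if (d < pw)
    pa_stop("pa_param_error", "panels overlap: panel_offset %d < panel width %d", d, pw)
  if (bx + d + pw > fw || by + ph > fh || bx < 0 || by < 0)
    pa_stop("pa_param_error", "panels do not fit within the %dx%d frame", fw, fh)
  rh <- dim(swe_panel)[1]; rw <- dim(swe_panel)[2]
  rx <- layout$roi_offset[1]; ry <- layout$roi_offset[2]
  if (rx + rw > pw || ry + rh > ph)
    pa_stop("pa_param_error", "SWE ROI does not fit inside its panel")

  frame <- array(layout$background, dim = c(fh, fw, 3L))
  put_gray <- function(x0, y0, img) {
    for (k in 1:3) frame[(y0 + 1):(y0 + nrow(img)), (x0 + 1):(x0 + ncol(img)), k] <<- img
  }
  put_gray(bx, by, bmode)        # left: plain B-mode panel
  put_gray(bx + d, by, bmode)    # right: same B-mode under the color map
  for (k in 1:3)
    frame[(by + ry + 1):(by + ry + rh),
          (bx + d + rx + 1):(bx + d + rx + rw), k] <- swe_panel[, , k]

  glyph <- s_glyph() * 255
  gx <- layout$glyph_offset[1]; gy <- layout$glyph_offset[2]
  put_gray(bx + gx, by + gy, glyph)
  put_gray(bx + d + gx, by + gy, glyph)

  truth <- list(
    s_bmode = c(x = bx + gx, y = by + gy),
    s_swe = c(x = bx + d + gx, y = by + gy),
    d = d,
    swe_roi = roi_box(bx + d + rx, by + ry, bx + d + rx + rw, by + ry + rh),
    bmode_roi = roi_box(bx + rx, by + ry, bx + rx + rw, by + ry + rh)
  )
  attr(frame, "layout") <- truth
  frame
}

#' Trial protocol for synthetic recordings
#'
#' Describes a measurement trial: trial type, duration, frame rate and the
#' activation-dependent dynamics of pennation angle, shear-wave velocity and
#' per-pixel SWE validity. Defaults follow the experimental protocol the
#' package emulates: passive and MVC trials last 5 s, submaximal contractions
#' (25/50/75% MVC) last 7 s, video rate 19 Hz. The activation profile ramps
#' to the target level over `ramp_time` seconds and holds; the pennation and
#' velocity models are affine in activation,
#' `theta(t) = theta_rest + delta_theta * a(t)` and
#' `v(t) = v_rest + delta_v * a(t)`.
#'
#' @param trial_type One of `"passive"`, `"mvc25"`, `"mvc50"`, `"mvc75"`,
#'   `"mvc"` (aliases like `"25% MVC"` are accepted).
#' @param duration Trial length in seconds; default 5 s for passive/MVC, 7 s
#'   for submaximal levels.
#' @param frame_rate Video sampling rate in Hz (default 19).
#' @param theta_rest Resting pennation angle (degrees, default 20).
#' @param delta_theta Pennation increase at full activation (degrees,
#'   default 8, matching the observed rise during MVC).
#' @param v_rest Resting shear-wave velocity (m/s, default 2).
#' @param delta_v SWV increase at full activation (m/s, default 5).
#' @param activation_profile Optional `function(t)` in [0, 1]; overrides the
#'   default ramp-and-hold.
#' @param valid_pixel_model Optional `function(a)` giving the probability that
#'   an SWE pixel is valid (colored) at activation `a`; the default
#'   `0.97 - 0.6 a^2` reproduces the strong quality loss at high contraction
#'   levels.
#' @param frame_valid_sigma Between-frame standard deviation of the validity
#'   probability (default 0.15), emulating frame-to-frame quality
#'   fluctuations.
#' @param ramp_time Seconds to reach the target activation (default 1).
#' @return An object of class `trial_protocol`.
#' @export
trial_protocol <- function(trial_type, duration = NULL, frame_rate = 19,
                           theta_rest = 20, delta_theta = 8,
                           v_rest = 2, delta_v = 5,
                           activation_profile = NULL,
                           valid_pixel_model = NULL,
                           frame_valid_sigma = 0.15, ramp_time = 1) {
  trial_type <- normalize_trial_type(trial_type)
  level <- switch(trial_type, passive = 0, mvc25 = 0.25, mvc50 = 0.5,
                  mvc75 = 0.75, mvc = 1)
  if (is.null(duration))
    duration <- if (trial_type %in% c("passive", "mvc")) 5 else 7
  if (duration <= 0 || frame_rate <= 0)
    pa_stop("pa_param_error", "duration and frame_rate must be positive")
  if (is.null(activation_profile)) {
    activation_profile <- function(t) level * clamp(t / ramp_time, 0, 1)
  }
  if (is.null(valid_pixel_model)) {
    valid_pixel_model <- function(a) clamp(0.97 - 0.6 * a^2, 0, 1)
  }
  th_max <- theta_rest + delta_theta
  if (th_max > 90 || theta_rest <= -90)
    pa_stop("pa_param_error", "pennation model leaves (-90, 90]")
  structure(list(trial_type = trial_type, duration = duration,
                 frame_rate = frame_rate, theta_rest = theta_rest,
                 delta_theta = delta_theta, v_rest = v_rest, delta_v = delta_v,
                 activation_profile = activation_profile,
                 valid_pixel_model = valid_pixel_model,
                 frame_valid_sigma = frame_valid_sigma),
            class = "trial_protocol")
}

#' Normalize trial-type labels
#'
#' @param x Label such as `"passive"`, `"MVC"`, `"25% MVC"`, `"mvc75"`.
#' @return Canonical label: one of `"passive"`, `"mvc25"`, `"mvc50"`,
#'   `"mvc75"`, `"mvc"`.
#' @export
normalize_trial_type <- function(x) {
  key <- gsub("[^a-z0-9]", "", tolower(x))
  out <- switch(key,
                passive = "passive", rest = "passive",
                mvc = "mvc",
                "25mvc" = "mvc25", mvc25 = "mvc25",
                "50mvc" = "mvc50", mvc50 = "mvc50",
                "75mvc" = "mvc75", mvc75 = "mvc75",
                NULL)
  if (is.null(out))
    pa_stop("pa_param_error", "unknown trial type '%s'", x)
  out
}

#' Generate a synthetic multi-frame trial
#'
#' Renders `duration * frame_rate` frames whose pennation angle, shear-wave
#' velocity and SWE pixel validity follow the protocol's activation dynamics,
#' and stores per-frame ground truth alongside. Deterministic per seed.
#'
#' @param protocol A [trial_protocol()].
#' @param config A [phantom_config()]; its `fiber_angle` is overridden per
#'   frame by the protocol's pennation model.
#' @param scale A [swe_scale()].
#' @param seed Integer seed (default the config seed).
#' @param render `"roi"` (default) stores the B-mode ROI and SWE color-map ROI
#'   per frame; `"screen"` composes full 640x480 dual-panel frames (memory
#'   heavy for long trials); `"none"` stores ground truth only.
#' @param layout A [screen_layout_spec()] used when `render = "screen"`.
#' @return An object of class `trial_recording`: list with `frames` (per-frame
#'   images), `ground_truth` (data.frame: frame_index, time, activation,
#'   theta_deg, swv_mps, valid_fraction), the protocol, config, scale and, for
#'   screen rendering, the ground-truth layout.
#' @export
generate_trial <- function(protocol, config, scale = swe_scale(),
                           seed = config$seed,
                           render = c("roi", "screen", "none"),
                           layout = screen_layout_spec()) {
  stopifnot(inherits(protocol, "trial_protocol"),
            inherits(config, "phantom_config"), inherits(scale, "swe_scale"))
  render <- match.arg(render)
  n <- as.integer(round(protocol$duration * protocol$frame_rate))
  tt <- (seq_len(n) - 1) / protocol$frame_rate
  a <- protocol$activation_profile(tt)
  theta <- protocol$theta_rest + protocol$delta_theta * a
  v <- protocol$v_rest + protocol$delta_v * a
  if (any(v < scale$v_min) || any(v > scale$v_max))
    pa_stop("pa_param_error", "SWV model leaves the color scale range")
  p_base <- protocol$valid_pixel_model(a)

  h <- config$image_height; w <- config$image_width
  frames <- vector("list", n)
  valid_frac <- numeric(n)
  for (i in seq_len(n)) {
    fseed <- derive_seed(seed, i)
    cfg_i <- config
    cfg_i$fiber_angle <- theta[i]
    cfg_i$seed <- as.integer(fseed %% 2147483647)
    bmode <- generate_bmode_phantom(cfg_i)
    p_i <- with_seed(fseed + 1, clamp(p_base[i] + rnorm(1, 0, protocol$frame_valid_sigma), 0, 1))
    invalid <- with_seed(fseed + 2, matrix(runif(h * w) >= p_i, h, w))
    valid_frac[i] <- 1 - mean(invalid)
    if (render == "none") next
    field <- matrix(v[i], h, w)
    swe <- encode_swv_field(field, scale, invalid_mask = invalid, underlay = bmode)
    if (render == "roi") {
      frames[[i]] <- list(bmode = bmode, swe = swe)
    } else {
      # crop the ROI-sized center region into the screen layout
      rx <- layout$roi_offset[1]; ry <- layout$roi_offset[2]
      rw <- w - 2 * rx; rh <- h - 2 * ry
      if (rw < 1 || rh < 1)
        pa_stop("pa_param_error", "phantom too small for the screen ROI offsets")
      box <- roi_box(rx, ry, rx + rw, ry + rh)
      frames[[i]] <- list(frame = generate_screen_frame(bmode, crop_roi(swe, box), layout))
    }
  }
  gt <- data.frame(frame_index = seq_len(n), time = tt, activation = a,
                   theta_deg = theta, swv_mps = v, valid_fraction = valid_frac)
  structure(list(frames = frames, ground_truth = gt, protocol = protocol,
                 config = config, scale = scale, render = render,
                 layout = if (render == "screen") attr(frames[[1]]$frame, "layout")),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %s: %d frames @ %g Hz (render = %s)\n",
              x$protocol$trial_type, nrow(x$ground_truth),
              x$protocol$frame_rate, x$render))
  cat(sprintf("  theta %g..%g deg, swv %g..%g m/s, mean valid fraction %.2f\n",
              min(x$ground_truth$theta_deg), max(x$ground_truth$theta_deg),
              min(x$ground_truth$swv_mps), max(x$ground_truth$swv_mps),
              mean(x$ground_truth$valid_fraction)))
  invisible(x)
}
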