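# Fixtures are built in code; no binary test data is shipped.

make_phantom <- function(angle, sigma = 5, seed = 1, ...) {
  generate_bmode_phantom(phantom_config(fiber_angle = angle,
                                        speckle_sigma = sigma,
                                        seed = seed, ...))
}

# Independent brute-force oracle for the adaptive Canny stopping rule:
# smallest threshold in {start, start+step, ...} whose edge fraction is
# strictly below max_fraction.
oracle_canny_threshold <- function(roi, start = 50, step = 10,
                                   max_fraction = 0.10) {
  for (t in seq(start, 255, by = step)) {
    if (mean(pennalign:::canny_cpp(roi, t, 2 * t)) < max_fraction) return(t)
  }
  NA_integer_
}

# Independent brute-force oracle for the adaptive Hough stopping rule:
# largest threshold <= start yielding at least min_lines segments (every
# per-threshold run is deterministic for the fixed seed).
oracle_hough_threshold <- function(edges, start = 100, min_lines = 10,
                                   floor_threshold = 10, min_length = NULL,
                                   max_gap = 5, seed = 42) {
  if (is.null(min_length)) min_length <- 0.2 * ncol(edges)
  hits <- integer(0)
  for (h in floor_threshold:start) {
    n <- nrow(pennalign:::hough_prob_cpp(edges, h, min_length, max_gap, seed))
    if (n >= min_lines) hits <- c(hits, h)
  }
  if (length(hits)) max(hits) else NA_integer_
}

# Per-pixel brute-force SWE decoder (independent of decode_frame's
# vectorized/deduplicated path): nearest LUT entry by explicit distance.
oracle_decode_pixel <- function(rgb, scale) {
  d2 <- colSums((t(scale$lut) - rgb)^2)
  idx <- which.min(d2) - 1
  scale$v_min + (scale$v_max - scale$v_min) * idx / 255
}

# Fixture set used for the stopping-rule equivalence checks: phantoms across
# angles, noise levels and line densities.
stopping_rule_fixtures <- function() {
  specs <- list(
    list(angle = 0, sigma = 0, seed = 1),
    list(angle = 15, sigma = 5, seed = 2),
    list(angle = -10, sigma = 10, seed = 3),
    list(angle = 25, sigma = 15, seed = 4),
    list(angle = 5, sigma = 20, seed = 5),
    list(angle = -20, sigma = 25, seed = 6),
    list(angle = 12, sigma = 30, seed = 7),
    list(angle = 8, sigma = 5, seed = 8, fiber_spacing = 60),
    list(angle = -5, sigma = 10, seed = 9, fiber_spacing = 45),
    list(angle = 30, sigma = 5, seed = 10, fiber_thickness = 2)
  )
  lapply(specs, function(s) {
    extra <- s[setdiff(names(s), c("angle", "sigma", "seed"))]
    do.call(make_phantom, c(list(angle = s$angle, sigma = s$sigma,
                                 seed = s$seed), extra))
  })
}
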