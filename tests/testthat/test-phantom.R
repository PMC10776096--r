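test_that("phantom_config validates its invariants", {
  expect_error(phantom_config(image_width = 0), class = "pa_param_error")
  expect_error(phantom_config(fiber_angle = -90), class = "pa_param_error")
  expect_error(phantom_config(fiber_angle = 91), class = "pa_param_error")
  expect_error(phantom_config(fiber_intensity = 300), class = "pa_param_error")
  expect_error(phantom_config(speckle_sigma = -1), class = "pa_param_error")
  expect_s3_class(phantom_config(fiber_angle = 90), "phantom_config")
})

test_that("B-mode phantom rendering is deterministic and respects degenerate cases", {
  cfg <- phantom_config(fiber_angle = 17, speckle_sigma = 8, seed = 11)
  expect_identical(generate_bmode_phantom(cfg), generate_bmode_phantom(cfg))

  # zero contrast: uniform texture, no structure beyond noise
  flat <- phantom_config(fiber_intensity = 100, background_intensity = 100,
                         speckle_sigma = 0)
  expect_equal(length(unique(as.vector(generate_bmode_phantom(flat)))), 1L)

  # axis-aligned, noiseless: every line pixel lies on exactly horizontal rows
  hz <- generate_bmode_phantom(phantom_config(fiber_angle = 0, speckle_sigma = 0))
  bright_rows <- which(apply(hz, 1, max) > 100)
  for (r in bright_rows) expect_equal(length(unique(hz[r, ])), 1L)

  expect_true(all(generate_bmode_phantom(cfg) >= 0) &&
                all(generate_bmode_phantom(cfg) <= 255))
})

test_that("generator ground truth is recoverable by the estimator", {
  img <- make_phantom(15, sigma = 5, seed = 1)
  expect_lt(abs(estimate_fiber_angle(img)$angle - 15), 1)
})

test_that("swe_scale enforces LUT invariants", {
  sc <- swe_scale()
  expect_equal(dim(sc$lut), c(256L, 3L))
  spread <- sqrt(rowMeans((sc$lut - rowMeans(sc$lut))^2))
  expect_true(all(spread > 10))
  expect_error(swe_scale(v_min = 2, v_max = 2), class = "pa_param_error")
  gray_lut <- matrix(rep(0:255, 3), 256, 3)
  expect_error(swe_scale(lut = gray_lut), class = "pa_param_error")
})

test_that("encode_swv_field maps scale boundaries to LUT boundaries", {
  sc <- swe_scale(0, 10)
  lo <- encode_swv_field(matrix(0, 4, 4), sc)
  hi <- encode_swv_field(matrix(10, 4, 4), sc)
  expect_true(all(lo[, , 1] == sc$lut[1, 1] & lo[, , 2] == sc$lut[1, 2] &
                    lo[, , 3] == sc$lut[1, 3]))
  expect_true(all(hi[, , 1] == sc$lut[256, 1] & hi[, , 2] == sc$lut[256, 2] &
                    hi[, , 3] == sc$lut[256, 3]))
  expect_error(encode_swv_field(matrix(11, 2, 2), sc), class = "pa_param_error")
})

test_that("encode/decode round trip stays within one LUT quantization step", {
  sc <- swe_scale(0, 10)
  step <- (sc$v_max - sc$v_min) / 255
  fm <- decode_frame(encode_swv_field(matrix(3.0, 10, 10), sc), sc)
  expect_lt(abs(fm$mean_swv - 3.0), step)
  # per-pixel, against the independent brute-force decoder
  set.seed(42)
  field <- matrix(runif(64, 0, 10), 8, 8)
  enc <- encode_swv_field(field, sc)
  for (i in 1:8) for (j in 1:8) {
    v <- oracle_decode_pixel(enc[i, j, ], sc)
    expect_lt(abs(v - field[i, j]), step)
  }
})

test_that("screen frames carry exact ground-truth layout", {
  bm <- make_phantom(20, sigma = 5, seed = 3)
  swe <- encode_swv_field(matrix(3, 140, 140), swe_scale())
  lay <- screen_layout_spec(panel_offset = 250)
  fr <- generate_screen_frame(bm, swe, lay)
  gt <- attr(fr, "layout")
  expect_equal(dim(fr), c(480L, 640L, 3L))
  expect_equal(gt$d, 250)
  # the B-mode ROI is the SWE ROI shifted left by d
  expect_equal(gt$bmode_roi$x1, gt$swe_roi$x1 - 250)
  expect_equal(gt$bmode_roi$y1, gt$swe_roi$y1)
  expect_equal(gt$bmode_roi$width, gt$swe_roi$width)
  # overlapping panels rejected
  expect_error(generate_screen_frame(bm, swe,
                                     screen_layout_spec(panel_offset = 100)),
               class = "pa_param_error")
})

test_that("an all-gray SWE panel defeats ROI detection", {
  bm <- make_phantom(20, sigma = 5, seed = 3)
  gray_panel <- gray_to_rgb(matrix(90, 140, 140))
  fr <- generate_screen_frame(bm, gray_panel, screen_layout_spec())
  expect_error(locate_swe_roi(fr), class = "pa_roi_error")
})

test_that("trial generation matches the protocol arithmetic", {
  cfg <- phantom_config(image_width = 60, image_height = 60, seed = 5)
  rec <- generate_trial(trial_protocol("passive"), cfg, render = "none")
  expect_equal(nrow(rec$ground_truth), 95L) # 5 s x 19 Hz
  rec75 <- generate_trial(trial_protocol("75% MVC"), cfg, render = "none")
  expect_equal(nrow(rec75$ground_truth), 133L) # 7 s x 19 Hz

  # constant zero activation: identity dynamics
  pr0 <- trial_protocol("mvc", activation_profile = function(t) rep(0, length(t)))
  rec0 <- generate_trial(pr0, cfg, render = "none")
  expect_true(all(rec0$ground_truth$theta_deg == pr0$theta_rest))
  expect_true(all(rec0$ground_truth$swv_mps == pr0$v_rest))
})

test_that("trial generation is deterministic per seed", {
  cfg <- phantom_config(image_width = 40, image_height = 40)
  pr <- trial_protocol("mvc25", duration = 0.5)
  a <- generate_trial(pr, cfg, seed = 9)
  b <- generate_trial(pr, cfg, seed = 9)
  expect_identical(a$frames, b$frames)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("lowering pixel validity never increases the valid fraction", {
  cfg <- phantom_config(image_width = 40, image_height = 40)
  for (s in 1:5) {
    hi <- trial_protocol("mvc50", duration = 1,
                         valid_pixel_model = function(a) rep(0.9, length(a)))
    lo <- trial_protocol("mvc50", duration = 1,
                         valid_pixel_model = function(a) rep(0.6, length(a)))
    vf_hi <- generate_trial(hi, cfg, seed = s, render = "none")$ground_truth$valid_fraction
    vf_lo <- generate_trial(lo, cfg, seed = s, render = "none")$ground_truth$valid_fraction
    expect_true(all(vf_lo <= vf_hi))
  }
})

test_that("trial type labels normalize", {
  expect_equal(normalize_trial_type("25% MVC"), "mvc25")
  expect_equal(normalize_trial_type("MVC"), "mvc")
  expect_equal(normalize_trial_type("Passive"), "passive")
  expect_error(normalize_trial_type("sprint"), class = "pa_param_error")
})
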