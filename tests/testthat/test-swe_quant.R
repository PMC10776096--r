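fm_row <- function(swv, valid) {
  data.frame(frame_index = seq_along(swv), mean_swv = swv,
             valid_fraction = ifelse(valid, 1, 0), is_valid = valid)
}

test_that("decode_frame recovers encoded velocities and validity", {
  sc <- swe_scale(0, 10)
  step <- 10 / 255
  fm <- decode_frame(encode_swv_field(matrix(3, 20, 20), sc), sc)
  expect_lt(abs(fm$mean_swv - 3), step)
  expect_equal(fm$valid_fraction, 1)
  expect_true(fm$is_valid)

  gray <- gray_to_rgb(matrix(77, 10, 10))
  fm0 <- decode_frame(gray, sc)
  expect_equal(fm0$valid_fraction, 0)
  expect_true(is.na(fm0$mean_swv))
  expect_false(fm0$is_valid)

  expect_error(decode_frame(array(0, c(0, 0, 3)), sc), class = "pa_param_error")
})

test_that("frame validity flips exactly at 75% colored pixels", {
  sc <- swe_scale(0, 10)
  n <- 400 # 20 x 20 ROI
  mask <- matrix(FALSE, 20, 20)
  mask[seq_len(n - 300)] <- TRUE # exactly 300 colored
  fm <- decode_frame(encode_swv_field(matrix(4, 20, 20), sc, invalid_mask = mask), sc)
  expect_equal(fm$valid_fraction, 0.75)
  expect_true(fm$is_valid)

  mask[n - 300 + 1] <- TRUE # 299 colored: one pixel below the bound
  fm2 <- decode_frame(encode_swv_field(matrix(4, 20, 20), sc, invalid_mask = mask), sc)
  expect_equal(fm2$valid_fraction, 0.75 - 1 / n)
  expect_false(fm2$is_valid)
})

test_that("invalid pixels are excluded from the frame mean, not zero-imputed", {
  sc <- swe_scale(0, 10)
  mask <- matrix(c(TRUE, FALSE), 10, 10)
  enc <- encode_swv_field(matrix(6, 10, 10), sc, invalid_mask = mask,
                          underlay = matrix(50, 10, 10))
  fm <- decode_frame(enc, sc)
  expect_lt(abs(fm$mean_swv - 6), 10 / 255)
})

test_that("summarize_trial applies the 2-s discard to contraction trials only", {
  df <- fm_row(rep(2, 133), rep(TRUE, 133))
  ts <- summarize_trial(df, "mvc75", 19)
  expect_equal(ts$n_frames_analyzed, 95L) # 133 - ceil(2*19)
  expect_equal(ts$n_frames_total, 133L)

  dfp <- fm_row(rep(2, 95), rep(TRUE, 95))
  tsp <- summarize_trial(dfp, "passive", 19)
  expect_equal(tsp$n_frames_analyzed, 95L) # no discard

  short <- fm_row(rep(2, 10), rep(TRUE, 10))
  expect_error(summarize_trial(short, "mvc", 19), class = "pa_empty_trial_error")
})

test_that("trial inclusion flips exactly at 30% valid frames", {
  valid30 <- fm_row(rep(2, 100), c(rep(TRUE, 30), rep(FALSE, 70)))
  expect_true(summarize_trial(valid30, "passive", 19)$included)
  valid29 <- fm_row(rep(2, 100), c(rep(TRUE, 29), rep(FALSE, 71)))
  expect_false(summarize_trial(valid29, "passive", 19)$included)
})

test_that("trial mean averages valid frames only and quality follows table semantics", {
  df <- data.frame(frame_index = 1:4,
                   mean_swv = c(2, 4, 8, 100),
                   valid_fraction = c(1, 0.8, 0.9, 0.2),
                   is_valid = c(TRUE, TRUE, TRUE, FALSE))
  ts <- summarize_trial(df, "passive", 19)
  expect_equal(ts$mean_swv, mean(c(2, 4, 8)))
  expect_equal(ts$pixels_pct, mean(c(1, 0.8, 0.9, 0.2)) * 100)
  expect_equal(ts$frames_pct, 75)
})

test_that("condition summaries average included repetitions only", {
  mk <- function(swv, included) {
    structure(list(trial_type = "mvc50", mean_swv = swv, included = included),
              class = "trial_summary")
  }
  all_in <- summarize_condition(list(mk(2.0, TRUE), mk(2.2, TRUE), mk(2.4, TRUE)))
  expect_equal(all_in$mean_swv, 2.2)
  one_out <- summarize_condition(list(mk(2.0, TRUE), mk(2.2, FALSE), mk(2.4, TRUE)))
  expect_equal(one_out$mean_swv, 2.2)
  expect_equal(one_out$n_included, 2L)
  none <- summarize_condition(list(mk(2.0, FALSE), mk(2.2, FALSE)))
  expect_true(is.na(none$mean_swv)) # missing marker, not 0
})

test_that("decoding a generated trial tracks the ground-truth SWV trace", {
  cfg <- phantom_config(image_width = 60, image_height = 60, seed = 21)
  pr <- trial_protocol("mvc25", duration = 1.5,
                       valid_pixel_model = function(a) rep(1, length(a)),
                       frame_valid_sigma = 0)
  rec <- generate_trial(pr, cfg, seed = 21)
  df <- decode_trial(rec)
  step <- (rec$scale$v_max - rec$scale$v_min) / 255
  expect_true(all(abs(df$mean_swv - rec$ground_truth$swv_mps) <= step))
  expect_equal(df$valid_fraction, rec$ground_truth$valid_fraction)
})
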