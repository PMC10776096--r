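test_that("adaptive Canny honors its stopping rule", {
  # uniform ROI: zero gradients, passes immediately at the start threshold
  res <- adaptive_canny(matrix(100, 50, 50))
  expect_equal(res$threshold, 50)
  expect_equal(res$edge_fraction, 0)

  # noisy phantom: returned threshold equals the brute-force sweep and the
  # fraction satisfies the bound
  roi <- make_phantom(12, sigma = 20, seed = 4)
  res <- adaptive_canny(roi)
  expect_lt(res$edge_fraction, 0.10)
  expect_gt(res$threshold, 50) # noise forces adaptation upward
  expect_equal(res$threshold, oracle_canny_threshold(roi))

  # a bound that can never be met fails
  expect_error(adaptive_canny(roi, max_fraction = 0), class = "pa_edge_error")
})

test_that("adaptive Hough honors its stopping rule", {
  edges <- adaptive_canny(make_phantom(20, sigma = 0, seed = 1))$edges
  res <- adaptive_hough(edges)
  expect_gte(nrow(res$segments), 10)
  ang <- segment_angles(res$segments)
  expect_true(all(abs(ang - 20) < 1))
  expect_equal(res$threshold, oracle_hough_threshold(edges))

  # sparse fixture that forces the threshold below the start value
  sparse <- adaptive_canny(make_phantom(8, sigma = 5, seed = 2,
                                        fiber_spacing = 60))$edges
  res2 <- adaptive_hough(sparse)
  expect_lt(res2$threshold, 100)
  expect_equal(res2$threshold, oracle_hough_threshold(sparse))

  # blank edge image: nothing to detect
  expect_error(adaptive_hough(matrix(FALSE, 60, 60)), class = "pa_line_error")
})

test_that("segment angles use the screen sign convention and map to (-90, 90]", {
  # ascending left->right on screen: y decreases as x increases
  expect_equal(segment_angles(rbind(c(0, 10, 10, 0))), 45)
  expect_equal(segment_angles(rbind(c(0, 0, 10, 10))), -45)
  # orientation of a segment is direction-free
  expect_equal(segment_angles(rbind(c(10, 0, 0, 10))), 45)
  expect_equal(segment_angles(rbind(c(0, 0, 10, 0))), 0)
  expect_equal(segment_angles(rbind(c(0, 10, 0, 0))), 90)
})

test_that("estimate_fiber_angle recovers generator ground truth", {
  expect_lt(abs(estimate_fiber_angle(make_phantom(0, sigma = 5))$angle), 0.5)
  expect_lt(abs(estimate_fiber_angle(make_phantom(15, sigma = 5))$angle - 15), 1)
  est <- estimate_fiber_angle(make_phantom(-10, sigma = 5))
  expect_lt(abs(est$angle + 10), 1) # sign convention: negative stays negative
  expect_gte(est$n_lines, 10)
  expect_lt(est$edge_fraction, 0.10)
})

test_that("estimation is symmetric about zero", {
  for (theta in c(5, 15, 25)) {
    a_pos <- estimate_fiber_angle(make_phantom(theta, sigma = 5, seed = 6))$angle
    a_neg <- estimate_fiber_angle(make_phantom(-theta, sigma = 5, seed = 6))$angle
    expect_lt(abs(a_pos + a_neg), 1)
  }
})

test_that("the median resists spurious segments", {
  # 12 long segments at 15 deg
  base <- t(vapply(0:11, function(i) {
    y0 <- 20 + i * 12
    c(0, y0, 100, y0 - round(100 * tan(15 * pi / 180)))
  }, numeric(4)))
  clean <- median(segment_angles(base))
  # inject 4 outliers at 80 deg
  spur <- t(vapply(1:4, function(i) c(10 * i, 100, 10 * i + 17, 0), numeric(4)))
  polluted <- median(segment_angles(rbind(base, spur)))
  expect_lt(abs(polluted - clean), 1)
})

test_that("estimates are deterministic", {
  roi <- make_phantom(18, sigma = 10, seed = 13)
  expect_identical(estimate_fiber_angle(roi), estimate_fiber_angle(roi))
})
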