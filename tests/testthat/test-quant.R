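make_gray <- function(m, px_per_mm = 20) strip_image(m, px_per_mm)

test_that("3x3 smoothing implements the 1-2-1 binomial kernel with edge replication", {
  # constants are preserved exactly
  const <- make_gray(matrix(128, 10, 10))
  expect_equal(smooth_image(const)$pixels, const$pixels)

  # unit impulse of 16 spreads as the outer product of (1,2,1)/4
  m <- matrix(0, 5, 5); m[3, 3] <- 16
  sm <- smooth_image(make_gray(m))$pixels
  expect_equal(sm[3, 3], 4)
  expect_equal(sm[2, 3], 2); expect_equal(sm[3, 2], 2)
  expect_equal(sm[2, 2], 1); expect_equal(sm[4, 4], 1)
  expect_equal(sum(sm), 16)   # kernel is normalised

  # i.i.d. noise variance strictly reduced
  set.seed(1)
  noisy <- matrix(128 + rnorm(100 * 100, 0, 10), 100, 100)
  expect_lt(sd(smooth_image(make_gray(noisy))$pixels[10:90, 10:90]),
            sd(noisy[10:90, 10:90]))

  expect_error(smooth_image(make_gray(matrix(0, 2, 5))),
               class = "lfa_input_error")
})

test_that("grayscale conversion uses the luma weights and is idempotent", {
  px <- array(0, c(4, 4, 3))
  px[, , 1] <- 255                         # pure red
  red <- strip_image(px, 20)
  expect_true(all(to_gray(red)$pixels == 76))   # round(0.299 * 255)

  px2 <- array(90, c(4, 4, 3))             # neutral gray stays put
  expect_true(all(to_gray(strip_image(px2, 20))$pixels == 90))

  g <- to_gray(red)
  expect_identical(to_gray(g), g)          # single channel passes through
})

test_that("profile collapse takes the row median", {
  m <- matrix(c(10, 200, 12), nrow = 1)[rep(1, 3), ]
  p <- collapse_profile(make_gray(m))
  expect_equal(p$values, rep(12, 3))       # median suppresses the outlier

  m2 <- matrix(c(1, 2, 3, 100), nrow = 4, ncol = 4, byrow = TRUE)
  p2 <- collapse_profile(make_gray(m2))
  expect_equal(p2$values, rep(2.5, 4))     # even width: mean of middle two
  expect_length(p2$values, nrow(m2))
})

test_that("minima detection applies the bilateral prominence-10 rule", {
  flat <- rep(100, 20)
  dip <- function(depth) { v <- flat; v[10] <- 100 - depth; v }

  expect_equal(nrow(find_minima(dip(9))), 0)    # just under threshold
  d10 <- find_minima(dip(10))                   # at threshold: detected
  expect_equal(nrow(d10), 1)
  expect_equal(d10$index, 10)
  expect_equal(d10$depth, 10)

  # strictly monotone profile has no local minima
  expect_equal(nrow(find_minima(seq(0, 190, by = 10))), 0)

  # a shoulder dip without its own bilateral rise is absorbed into the
  # valley; only the valley's true minimum is reported
  v <- c(100, 100, 60, 65, 64, 63, 62, 61, 60, 59, 100, 100)
  det <- find_minima(v)
  expect_equal(det$index, 10)
  expect_equal(det$depth, 41)

  # sub-threshold wiggle at a dip bottom neither splits nor masks the line
  w <- c(100, 100, 60, 62, 61, 100, 100)
  detw <- find_minima(w)
  expect_equal(nrow(detw), 1)
  expect_equal(detw$index, 3)
  expect_equal(detw$depth, 40)

  # plateau minimum reports its centre index
  v2 <- c(rep(100, 5), rep(80, 4), rep(100, 5))
  expect_equal(find_minima(v2)$index, 7)   # floor((6 + 9) / 2)
})

test_that("minima detection matches the brute-force oracle on random profiles", {
  set.seed(424242)
  cfg <- quant_config()
  for (i in 1:1000) {
    v <- random_profile()
    got <- find_minima(v, cfg)
    want <- brute_minima(v, cfg$min_depth)
    expect_identical(unname(as.matrix(got)), unname(as.matrix(want)),
                     label = sprintf("profile %d", i))
  }
})

test_that("line assignment follows depth then flow order", {
  det <- data.frame(index = c(100L, 160L), min_value = c(150, 100),
                    left_baseline = 200, right_baseline = 200,
                    depth = c(50, 100))
  lines <- assign_lines(det)
  expect_equal(lines$test$index, 100)      # upstream line is the test line
  expect_equal(lines$control$index, 160)

  # spurious shallow third detection dropped with a warning
  det3 <- rbind(det, data.frame(index = 30L, min_value = 188,
                                left_baseline = 200, right_baseline = 200,
                                depth = 12))
  expect_warning(lines3 <- assign_lines(det3), "3 detections")
  expect_equal(sort(c(lines3$test$index, lines3$control$index)), c(100, 160))

  expect_error(assign_lines(det[1, ]), class = "lfa_invalid_test")
})

test_that("T/C ratio modes behave as documented", {
  mk <- function(depth, minv) data.frame(index = 1L, min_value = minv,
                                         left_baseline = 200,
                                         right_baseline = 200, depth = depth)
  expect_equal(tc_ratio(mk(60, 140), mk(60, 140)), 1.0)
  expect_equal(tc_ratio(mk(30, 170), mk(60, 140)), 0.5)
  expect_error(tc_ratio(mk(30, 170), mk(0, 200)),
               class = "lfa_invalid_test")
  raw <- quant_config(tc_mode = "raw_min_ratio")
  expect_equal(tc_ratio(mk(30, 170), mk(60, 85), raw), 2.0)
})

test_that("full analysis recovers the rendered T/C and flags blanks", {
  r <- render_strip(strip_spec(noise_sd = 0, test_line_depth = 40,
                               control_line_depth = 80))
  a <- analyze_strip(r$image)
  expect_equal(a$tc, 0.5, tolerance = 0.02)
  expect_equal(a$log$n_detections, 2)
  expect_equal(a$test$index, unname(r$truth$line_centers_px["test"]),
               tolerance = 1)
  # depths recovered within 1 gray level on a noiseless render
  expect_equal(a$test$depth, 40, tolerance = 1)
  expect_equal(a$control$depth, 80, tolerance = 1)

  blank <- strip_image(matrix(200, 200, 40), 20)
  expect_error(analyze_strip(blank), class = "lfa_invalid_test")
  expect_true(is_invalid_test(analyze_strip(blank)))
})

test_that("depth-mode T/C is invariant to constant illumination offsets", {
  r <- render_strip(strip_spec(noise_sd = 4, seed = 21L))
  shifted <- strip_image(pmin(r$image$pixels + 20, 255), r$image$px_per_mm)
  expect_lt(abs(analyze_strip(shifted)$tc - analyze_strip(r$image)$tc),
            1e-9)
})

test_that("a linear illumination ramp leaves the T/C nearly unchanged", {
  flat <- render_strip(strip_spec(noise_sd = 0, seed = 2L))
  ramp <- render_strip(strip_spec(noise_sd = 0, seed = 2L,
                                  illumination_slope = 0.05))
  expect_equal(analyze_strip(ramp$image)$tc, analyze_strip(flat$image)$tc,
               tolerance = 0.02)
})

test_that("ROI cropping confines the search window", {
  r <- render_strip(strip_spec(noise_sd = 0))
  # crop away the control line (at 14 mm = row 280 of 500)
  a <- tryCatch(analyze_strip(r$image, quant_config(roi = c(0, 0.5))),
                lfa_invalid_test = function(e) "invalid")
  expect_identical(a, "invalid")           # only one line left in view
  # a generous crop keeps both lines and the T/C
  full <- analyze_strip(r$image)
  crop <- analyze_strip(r$image, quant_config(roi = c(0.1, 0.9)))
  expect_equal(crop$tc, full$tc, tolerance = 1e-6)
})
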