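test_that("line profiles: constants, width invariance, spot localization", {
  const <- cal_image(matrix(4, 40, 40), 0.1)
  p <- line_profile(const, cbind(c(2, 35), c(10, 10)))
  expect_true(all(abs(p$intensity - 4) < 1e-12))
  # width averaging changes nothing when the image is perpendicular-constant
  p3 <- line_profile(const, cbind(c(2, 35), c(10, 10)), width = 3)
  expect_equal(p3$intensity, p$intensity)
  # profile through a Gaussian spot peaks at the spot's path coordinate
  sim <- generate_puncta_field(one_spot_spec())
  o <- sim$truth$objects
  ln <- cbind(c(0, 63), c(round(o$y_px), round(o$y_px)))
  prof <- line_profile(sim$image, ln)
  expect_lt(abs(prof$position_um[which.max(prof$intensity)] - o$x_px * 0.1),
            0.051)  # half a pixel at 0.1 um/px
  expect_error(line_profile(const, cbind(c(5, 5), c(5, 5))), "degenerate")
})

test_that("peak-to-peak distance: identical profiles give zero, offsets recover", {
  x <- seq(0, 6, by = 0.1)
  prof <- data.frame(position_um = x, intensity = exp(-(x - 3)^2))
  expect_equal(peak_to_peak(prof, prof), 0)
  prof2 <- data.frame(position_um = x, intensity = exp(-(x - 3.4)^2 / 0.5))
  expect_equal(peak_to_peak(prof, prof2), 0.4, tolerance = 0.05)
  flat <- data.frame(position_um = x, intensity = rep(1, length(x)))
  expect_error(peak_to_peak(prof, flat), "no peak|flat")
})

test_that("generated 0.4 um pairs give 0.4 um peak-to-peak along the pair axis", {
  d <- vapply(1:10, function(s) {
    f <- generate_two_channel_field(two_channel_spec(
      puncta_field_spec(image_shape = c(64, 64), pixel_size = 0.04,
                        n_puncta = 1, psf_sigma = 2, background = 5,
                        noise = list(poisson_scale = 0.5, gaussian_sd = 1),
                        seed = s),
      mode = "center_offset", center_offset = 0.4, offset_direction = 0))
    o <- f$truth$objects
    y0 <- round(o$y_px[1])
    ln <- cbind(c(max(0, o$x_px[1] - 12), min(63, o$x_px[2] + 12)), c(y0, y0))
    peak_to_peak(line_profile(f$ch1, ln, width = 3),
                 line_profile(f$ch2, ln, width = 3))
  }, numeric(1))
  expect_equal(median(d), 0.4, tolerance = 0.05)
  expect_true(all(abs(d - 0.4) < 0.06))
})

test_that("wrap-around pixel shift: identity at full width, composition", {
  m <- matrix(rnorm(40 * 100), 40, 100)
  expect_identical(shifted_null(m, 100), m)
  expect_identical(shifted_null(shifted_null(m, 40), 40), shifted_null(m, 80))
  img <- cal_image(m, 0.1)
  expect_equal(shifted_null(img, 100)$data, m)
})

test_that("distance distributions are percent-normalized within the cutoff", {
  set.seed(3)
  d <- runif(500, 0, 1.5)
  nd <- runif(500, 0, 1.5)
  dist <- distance_distribution(d, nd)
  expect_equal(sum(dist$freq_data_pct), 100, tolerance = 1e-6)
  expect_equal(sum(dist$freq_null_pct), 100, tolerance = 1e-6)
  expect_equal(nrow(dist), 20)
  expect_true(all(dist$bin_hi <= 1.2 + 1e-12))
})

test_that("center-of-mass distance: zero against itself, exact offsets, invariance", {
  f <- generate_two_channel_field(two_channel_spec(
    puncta_field_spec(image_shape = c(64, 64), pixel_size = 0.04, n_puncta = 1,
                      psf_sigma = 2, background = 5,
                      noise = list(poisson_scale = 0, gaussian_sd = 0), seed = 7),
    mode = "center_offset", center_offset = 0.4, offset_direction = 120))
  rr <- full_roi(64, 64)
  expect_equal(center_distance(f$ch1, f$ch1, rr)$d_nm, 0)
  cd <- center_distance(f$ch1, f$ch2, rr)
  expect_equal(cd$d_nm, 400, tolerance = 0.05)
  # translating both channels by the same vector leaves d unchanged
  sh1 <- cal_image(shifted_null(f$ch1$data, 5), 0.04)
  sh2 <- cal_image(shifted_null(f$ch2$data, 5), 0.04)
  cd2 <- center_distance(sh1, sh2, rr)
  expect_equal(cd2$d_nm, cd$d_nm, tolerance = 0.02)
  expect_error(center_distance(cal_image(matrix(0, 8, 8), 1),
                               cal_image(matrix(0, 8, 8), 1),
                               full_roi(8, 8), thr1 = -1, thr2 = -1),
               "zero total intensity")
})
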