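test_that("maximum projection matches a brute-force slice maximum", {
  # single slice: identity
  one <- cal_image(array(matrix(1:20, 4, 5), dim = c(4, 5, 1)), 0.1, axes = "yxz")
  expect_equal(project_stack(one)$data, matrix(1:20, 4, 5))

  # two slices, pixelwise max
  two <- cal_image(array(c(3, 7), dim = c(1, 1, 2)), 0.1, axes = "yxz")
  expect_equal(as.vector(project_stack(two)$data), 7)

  # 40 slices, central 20: equals brute force and ignores excluded slices
  set.seed(11)
  arr <- array(rnorm(16 * 16 * 40), dim = c(16, 16, 40))
  stack <- cal_image(arr, 0.1, axes = "yxz")
  zr <- 11:30
  got <- project_stack(stack, zr)$data
  expect_equal(got, apply(arr[, , zr], c(1, 2), max))
  arr2 <- arr
  arr2[, , c(1:10, 31:40)] <- arr2[, , c(1:10, 31:40)] + 100
  expect_equal(project_stack(cal_image(arr2, 0.1, axes = "yxz"), zr)$data, got)

  expect_error(project_stack(stack, integer(0)), "empty z_range")
  expect_error(project_stack(stack, 41), "outside")
})

test_that("find_maxima agrees with brute-force prominence on small images", {
  set.seed(21)
  for (rep in 1:5) {
    img <- matrix(runif(24 * 24), 24, 24)
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), 1.5))
    tol <- 0.05
    seeds <- find_maxima(img, tol)
    got <- sort(which(seeds > 0))
    want <- brute_force_prominent_maxima(img, tol)
    expect_equal(got, want)
  }
})

test_that("well-separated puncta are recovered within 5%", {
  spec <- puncta_field_spec(image_shape = c(256, 256), n_puncta = 60,
                            psf_sigma = 2, min_separation = 8,
                            amplitude_range = c(80, 120), background = 20,
                            noise = list(poisson_scale = 1, gaussian_sd = 18),
                            seed = 13)
  sim <- generate_puncta_field(spec)
  tab <- segment_particles(sim$image, NULL, detection_config(
    threshold = 45, maxima_prominence = 35, min_particle_area = 10,
    background_method = "percentile"))
  expect_lte(abs(nrow(tab) - 60) / 60, 0.05)
})

test_that("two touching Gaussians with distinct maxima split into 2 particles", {
  m <- matrix(5, 48, 48)
  m <- m + 100 * exp(-((row(m) - 24)^2 + (col(m) - 18)^2) / (2 * 4))
  m <- m + 100 * exp(-((row(m) - 24)^2 + (col(m) - 27)^2) / (2 * 4))
  img <- cal_image(m, 0.1)
  tab <- segment_particles(img, NULL, detection_config(
    threshold = 10, maxima_prominence = 20, background_method = "none",
    min_particle_area = 4))
  expect_equal(nrow(tab), 2)
  # the dividing line lies between the two centroids
  labels <- attr(tab, "label_image")
  lab_left <- labels[24, 18]; lab_right <- labels[24, 27]
  expect_true(lab_left != lab_right && lab_left > 0 && lab_right > 0)
  boundary_col <- max(which(labels[24, 1:27] == lab_left))
  expect_gt(boundary_col, 18)
  expect_lt(boundary_col, 27)
})

test_that("uniform image below threshold yields an empty table, ROI errors stay loud", {
  img <- cal_image(matrix(3, 32, 32), 0.1)
  tab <- segment_particles(img, NULL, detection_config(
    threshold = 10, background_method = "none"))
  expect_equal(nrow(tab), 0)
  far <- roi("polygon", cbind(c(100, 110, 110), c(100, 100, 110)))
  expect_error(segment_particles(img, far, detection_config()), "ROI is empty")
})

test_that("watershed labels partition the threshold mask", {
  sim <- generate_puncta_field(puncta_field_spec(
    image_shape = c(128, 128), n_puncta = 15, min_separation = 6,
    background = 5, noise = list(poisson_scale = 0, gaussian_sd = 0), seed = 17))
  tab <- segment_particles(sim$image, NULL, detection_config(
    threshold = 5, maxima_prominence = 10, background_method = "none",
    min_particle_area = 0))
  labels <- attr(tab, "label_image")
  mask <- attr(tab, "mask")
  expect_true(all((labels > 0) == mask))
})

test_that("raising the threshold never increases the masked area", {
  sim <- generate_puncta_field(puncta_field_spec(
    image_shape = c(128, 128), n_puncta = 20, seed = 19))
  areas <- vapply(c(25, 40, 60, 90), function(thr) {
    tab <- segment_particles(sim$image, NULL, detection_config(
      threshold = thr, background_method = "none", min_particle_area = 0))
    sum(attr(tab, "mask"))
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("field summaries: density, sum intensity per area, percent of control", {
  tab <- structure(data.frame(id = 1:10, x_px = 0, y_px = 0, x_um = 0, y_um = 0,
                              area_um2 = 0.5, integrated_density = 200,
                              mean_intensity = 40),
                   class = c("particle_table", "data.frame"))
  s <- summarize_field(tab, reference_area = 5)
  expect_equal(s$density_per_um2, 2)
  expect_equal(s$sum_intensity_per_area, 400)
  # control normalized to itself is exactly 100%
  s2 <- summarize_field(tab, 5, control_mean = c(density_per_um2 = s$density_per_um2))
  expect_equal(s2$density_per_um2_pct, 100)
  expect_error(summarize_field(tab, 5, control_mean = c(density_per_um2 = 0)),
               "zero")
  # noiseless field: measured sum intensity / area matches truth within 1%
  sim <- generate_puncta_field(puncta_field_spec(
    image_shape = c(256, 256), pixel_size = 0.1, n_puncta = 25,
    min_separation = 12, background = 0,
    noise = list(poisson_scale = 0, gaussian_sd = 0), seed = 23))
  ptab <- segment_particles(sim$image, NULL, detection_config(
    threshold = 0.2, maxima_prominence = 20, background_method = "none"))
  s3 <- summarize_field(ptab)
  truth_rate <- sum(sim$truth$objects$integrated_intensity) / (25.6^2)
  expect_equal(s3$sum_intensity_per_area, truth_rate, tolerance = 0.01)
})

test_that("ring diameter is the closed form 2 sqrt(A/pi)", {
  expect_equal(ring_diameter(pi), 2)
  expect_equal(ring_diameter(0), 0)
  expect_error(ring_diameter(-1), "non-negative")
  # pixelated-disk oracle: a rasterized disk of radius 0.14 um
  px <- 0.004
  r_px <- 0.14 / px
  n <- 101
  disk <- raster_ellipse(n, n, 50, 50, r_px, r_px)
  area_um2 <- sum(disk) * px^2
  expect_equal(ring_diameter(area_um2), 0.28, tolerance = 0.02)
})

test_that("cytoplasmic intensity excludes blurred-threshold active zones", {
  ny <- 64
  bouton <- roi("polygon", cbind(c(4, 59, 59, 4), c(4, 4, 59, 59)))
  # background 50 plus bright AZ spots
  m <- matrix(50, ny, ny)
  for (cx in c(20, 40)) m <- m + 150 * exp(-((row(m) - 30)^2 + (col(m) - cx)^2) / (2 * 4))
  res <- cytoplasmic_intensity(cal_image(m, 0.1), bouton, blur_sigma = 2,
                               az_threshold = 80)
  expect_equal(res$mean_intensity, 50, tolerance = 0.02)
  expect_gt(res$excluded_fraction, 0)
  # nothing above threshold: plain mean over the bouton
  flat <- cytoplasmic_intensity(cal_image(matrix(12, ny, ny), 0.1), bouton,
                                az_threshold = 30)
  expect_equal(flat$mean_intensity, 12)
  expect_equal(flat$excluded_fraction, 0)
  # fully bright bouton: no cytoplasmic pixels left
  expect_error(cytoplasmic_intensity(cal_image(matrix(100, ny, ny), 0.1),
                                     bouton, az_threshold = 30),
               "no cytoplasmic pixels")
})
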