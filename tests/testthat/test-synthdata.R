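test_that("empty puncta field is constant background with empty truth", {
  spec <- puncta_field_spec(image_shape = c(32, 32), n_puncta = 0,
                            background = 10,
                            noise = list(poisson_scale = 0, gaussian_sd = 0))
  sim <- generate_puncta_field(spec)
  expect_true(all(sim$image$data == 10))
  expect_equal(nrow(sim$truth$objects), 0)
})

test_that("a single Gaussian spot integrates to amplitude * 2 pi sigma^2", {
  sim <- generate_puncta_field(one_spot_spec(amplitude = 100, psf_sigma = 2))
  integrated <- sum(sim$image$data - 10)
  expect_equal(integrated, 100 * 2 * pi * 4, tolerance = 1e-3)
  expect_equal(sim$truth$objects$integrated_intensity, 100 * 2 * pi * 4)
})

test_that("equal seeds give bit-identical generator output", {
  spec <- puncta_field_spec(image_shape = c(128, 128), n_puncta = 200,
                            min_separation = 2, seed = 1)
  a <- generate_puncta_field(spec)
  b <- generate_puncta_field(spec)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth$objects, b$truth$objects)

  mspec <- transport_movie_spec(n_particles = 3, n_frames = 10, seed = 4)
  expect_identical(generate_transport_movie(mspec)$movie$data,
                   generate_transport_movie(mspec)$movie$data)

  espec <- ephys_trace_spec(noise_sd = 0.5, seed = 9)
  expect_identical(generate_ephys_trace(espec)$trace,
                   generate_ephys_trace(espec)$trace)
})

test_that("noiseless total intensity is conserved: background + truth sum", {
  spec <- puncta_field_spec(image_shape = c(256, 256), n_puncta = 30,
                            psf_sigma = 2, background = 7, min_separation = 12,
                            noise = list(poisson_scale = 0, gaussian_sd = 0),
                            seed = 5)
  sim <- generate_puncta_field(spec)
  expect_false(any(sim$truth$objects$clipped))
  total <- sum(sim$image$data)
  expected <- 7 * 256 * 256 + sum(sim$truth$objects$integrated_intensity)
  expect_equal(total, expected, tolerance = 0.005)
})

test_that("infeasible spot density raises an explicit error", {
  spec <- puncta_field_spec(image_shape = c(32, 32), n_puncta = 200,
                            min_separation = 10)
  expect_error(generate_puncta_field(spec), "infeasible density")
})

test_that("two-channel shared_fraction mode controls shared centroids", {
  base <- puncta_field_spec(image_shape = c(128, 128), n_puncta = 20,
                            min_separation = 8, seed = 2,
                            noise = list(poisson_scale = 0, gaussian_sd = 0))
  all_shared <- generate_two_channel_field(two_channel_spec(base, shared_fraction = 1))
  o <- all_shared$truth$objects
  c1 <- o[o$channel == 1, ]; c2 <- o[o$channel == 2, ]
  expect_equal(c1[, c("x_px", "y_px")], c2[, c("x_px", "y_px")],
               ignore_attr = TRUE)

  none <- generate_two_channel_field(two_channel_spec(base, shared_fraction = 0))
  o <- none$truth$objects
  c1 <- o[o$channel == 1, ]; c2 <- o[o$channel == 2, ]
  dmin <- min(sqrt(outer(c1$x_px, c2$x_px, "-")^2 +
                   outer(c1$y_px, c2$y_px, "-")^2))
  expect_gte(dmin, base$min_separation)
})

test_that("center_offset mode places pairs at the exact pixel offset", {
  base <- puncta_field_spec(image_shape = c(96, 96), pixel_size = 0.04,
                            n_puncta = 5, min_separation = 15, seed = 3)
  f <- generate_two_channel_field(
    two_channel_spec(base, mode = "center_offset", center_offset = 0.4,
                     offset_direction = 37))
  o <- f$truth$objects
  c1 <- o[o$channel == 1, ]; c2 <- o[o$channel == 2, ]
  d_px <- sqrt((c1$x_px - c2$x_px)^2 + (c1$y_px - c2$y_px)^2)
  expect_equal(d_px, rep(10, 5), tolerance = 1e-12)
})

test_that("transport truth obeys exact kinematics without pauses", {
  spec <- transport_movie_spec(n_particles = 1, n_frames = 11,
                               velocity_range = c(0.8, 0.8), pause_prob = 0,
                               cotransport_fraction = 1, seed = 6,
                               noise = list(poisson_scale = 0, gaussian_sd = 0))
  sim <- generate_transport_movie(spec)
  expect_true(all(sim$truth$objects$cotransport))
  # displacement after 10 frames = 8 um: the bright centroid moved 80 px
  pos_of <- function(frame) {
    m <- sim$movie$data[, , 1, frame]
    w <- m - 20
    sum(w * rep(0:(ncol(m) - 1), each = nrow(m))) / sum(w)
  }
  expect_equal(pos_of(11) - pos_of(1), 80, tolerance = 1e-6)
})

test_that("zero-velocity particles are static in every frame", {
  spec <- transport_movie_spec(n_particles = 1, n_frames = 6,
                               velocity_range = c(0, 0), seed = 8,
                               noise = list(poisson_scale = 0, gaussian_sd = 0))
  sim <- generate_transport_movie(spec)
  for (f in 2:6)
    expect_identical(sim$movie$data[, , 1, f], sim$movie$data[, , 1, 1])
})

test_that("EM section truth carries the drawn axes", {
  spec <- em_section_spec(n_objects = 1, region_area = 200 * 200,
                          pixel_size = 1, seed = 5)
  sim <- generate_em_sections(spec, axes = cbind(72, 41))
  expect_equal(sim$truth$objects$elongation, 72 / 41)
  circle <- generate_em_sections(spec, axes = cbind(60, 60))
  expect_equal(circle$truth$objects$long_diameter_nm,
               circle$truth$objects$short_diameter_nm)
  # region with no objects has zero areal fraction
  none <- generate_em_sections(em_section_spec(n_objects = 0, seed = 1))
  expect_equal(volume_fraction(none$labels)$volume_fraction, 0)
})

test_that("ephys traces are peak-normalized and linear", {
  tr <- generate_ephys_trace(ephys_trace_spec(amplitude = -75, noise_sd = 0))
  expect_equal(min(tr$trace$current_nA) - (-2), -75, tolerance = 1e-3)
  # no stimuli: flat baseline
  flat <- generate_ephys_trace(ephys_trace_spec(stim_times = numeric(0),
                                                noise_sd = 0, duration = 0.1))
  expect_true(all(flat$trace$current_nA == -2))
  # two pulses at long ISI: both transients reach the same depth
  two <- generate_ephys_trace(ephys_trace_spec(amplitude = -75, noise_sd = 0,
                                               stim_times = c(0.05, 0.3)))
  t <- two$trace$time_s; i <- two$trace$current_nA
  p1 <- min(i[t < 0.3]); p2 <- min(i[t >= 0.3])
  expect_equal(p1, p2, tolerance = 1e-3)
  expect_error(ephys_trace_spec(sample_rate = -1), "sample_rate")
})

test_that("ground truth and spec sidecars are written to disk", {
  dir <- withr::local_tempdir()
  sim <- generate_puncta_field(one_spot_spec())
  write_ground_truth(sim$truth, dir, "demo")
  expect_true(file.exists(file.path(dir, "demo_truth.csv")))
  sp <- jsonlite::read_json(file.path(dir, "demo_spec.json"))
  expect_equal(sp$spec_class, "puncta_field_spec")
  expect_equal(sp$n_puncta, 1)
})
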