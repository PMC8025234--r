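static_scene <- function(seed = 4, shape = c(64, 96)) {
  generate_puncta_field(puncta_field_spec(
    image_shape = shape, n_puncta = 20, psf_sigma = 2, background = 10,
    noise = list(poisson_scale = 0, gaussian_sd = 0), seed = seed))$image$data
}

roll_mat <- function(M, dx, dy) {
  ny <- nrow(M); nx <- ncol(M)
  M <- M[((seq_len(ny) - 1 - dy) %% ny) + 1, , drop = FALSE]
  M[, ((seq_len(nx) - 1 - dx) %% nx) + 1, drop = FALSE]
}

test_that("phase-correlation registration inverts known integer shifts", {
  base <- static_scene()
  true_sh <- cbind(dx = c(0, 2, -1, 3, 0, -4), dy = c(0, 1, 0, -2, 3, 0))
  arr <- array(0, c(64, 96, 6))
  set.seed(1)
  for (f in 1:6) arr[, , f] <- roll_mat(base, true_sh[f, 1], true_sh[f, 2]) +
    rnorm(64 * 96, 0, 1)
  reg <- register_movie(cal_image(arr, 0.1, 1, "yxt"))
  expect_true(all(abs(attr(reg, "shifts") - true_sh) <= 0.5))
  # a static movie registers with all-zero shifts
  reg0 <- register_movie(cal_image(replicate(4, base), 0.1, 1, "yxt"))
  expect_true(all(attr(reg0, "shifts") == 0))
  expect_error(register_movie(cal_image(array(base, c(64, 96, 1)), 0.1, 1, "yxt")),
               "at least 2 frames")
})

test_that("kymograph geometry: one row per frame, deleting a frame removes its row", {
  spec <- transport_movie_spec(n_particles = 1, n_frames = 12, seed = 3)
  sim <- generate_transport_movie(spec)
  k <- build_kymograph(sim$movie, spec$path, width = 5)
  expect_equal(nrow(k$matrix), 12)
  sub <- cal_image(sim$movie$data[, , , -7, drop = FALSE], 0.1, 1, "yxct")
  k2 <- build_kymograph(sub, spec$path, width = 5)
  expect_equal(k2$matrix, k$matrix[-7, ])
})

test_that("kymograph width does not matter for perpendicular-constant movies", {
  arr <- array(rep(matrix(rep(1:80, each = 24), 24, 80), 5), c(24, 80, 5))
  mv <- cal_image(arr, 0.1, 1, "yxt")
  path <- cbind(c(2, 77), c(12, 12))
  k3 <- build_kymograph(mv, path, width = 3, prefilter = FALSE)
  k10 <- build_kymograph(mv, path, width = 10, prefilter = FALSE)
  expect_equal(k3$matrix, k10$matrix, tolerance = 1e-12)
  expect_error(build_kymograph(mv, cbind(c(-5, 70), c(12, 12))), "exits frame")
})

test_that("a registered static particle gives a vertical streak", {
  spec <- transport_movie_spec(n_particles = 1, n_frames = 8,
                               velocity_range = c(0, 0), seed = 5,
                               noise = list(poisson_scale = 0, gaussian_sd = 0))
  sim <- generate_transport_movie(spec)
  reg <- register_movie(sim$movie)
  k <- build_kymograph(reg, spec$path, width = 5)
  cols <- apply(k$matrix, 1, which.max)
  expect_true(all(cols == cols[1]))
})

test_that("track detection recovers speed and direction from generated movies", {
  spec <- transport_movie_spec(n_particles = 1, n_frames = 61,
                               velocity_range = c(0.8, 0.8),
                               cotransport_fraction = 1, seed = 2)
  sim <- generate_transport_movie(spec)
  tr <- detect_tracks(build_kymograph(sim$movie, spec$path, width = 5))
  expect_equal(nrow(tr), 1)
  expect_lt(abs(tr$speed_um_s - 0.8) / 0.8, 0.1)
  expect_equal(tr$direction, "anterograde")

  spec2 <- transport_movie_spec(n_particles = 1, n_frames = 61,
                                velocity_range = c(-0.5, -0.5), seed = 3)
  sim2 <- generate_transport_movie(spec2)
  tr2 <- detect_tracks(build_kymograph(sim2$movie, spec2$path, width = 5))
  expect_equal(tr2$direction, "retrograde")
  expect_lt(abs(tr2$speed_um_s - 0.5) / 0.5, 0.1)
})

test_that("length and duration gates are inclusive at exactly 4 um and 30 s", {
  # painted kymograph: 31 rows spanning exactly 30 s, 40 px = 4.0 um
  k <- structure(list(matrix = paint_streak(35, 200, 1, 50, 31, 90),
                      frame_interval = 1, position_step = 0.1,
                      path = cbind(c(0, 199), c(0, 0)), width = 1),
                 class = "kymograph")
  tr <- detect_tracks(k, min_length = 4, min_duration = 30, threshold = 50)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$path_length_um, 4)
  expect_equal(tr$duration_s, 30)
  # just below either gate: rejected
  k_short <- structure(list(matrix = paint_streak(35, 200, 1, 50, 31, 88),
                            frame_interval = 1, position_step = 0.1,
                            path = cbind(c(0, 199), c(0, 0)), width = 1),
                       class = "kymograph")
  expect_equal(nrow(detect_tracks(k_short, 4, 30, threshold = 50)), 0)
  k_brief <- structure(list(matrix = paint_streak(35, 200, 1, 50, 29, 90),
                            frame_interval = 1, position_step = 0.1,
                            path = cbind(c(0, 199), c(0, 0)), width = 1),
                       class = "kymograph")
  expect_equal(nrow(detect_tracks(k_brief, 4, 30, threshold = 50)), 0)
})

test_that("cotransport classification follows the generator's co flags", {
  spec <- transport_movie_spec(n_particles = 1, n_frames = 61,
                               velocity_range = c(0.6, 0.6),
                               cotransport_fraction = 1, seed = 11)
  sim <- generate_transport_movie(spec)
  k1 <- build_kymograph(sim$movie, spec$path, width = 5, channel = 1)
  k2 <- build_kymograph(sim$movie, spec$path, width = 5, channel = 2)
  tr <- classify_cotransport(detect_tracks(k1), k2)
  expect_true(all(tr$co_positive))
  expect_gte(min(tr$co_frames), 3)

  spec0 <- transport_movie_spec(n_particles = 1, n_frames = 61,
                                velocity_range = c(0.6, 0.6),
                                cotransport_fraction = 0, seed = 12)
  sim0 <- generate_transport_movie(spec0)
  k1 <- build_kymograph(sim0$movie, spec0$path, width = 5, channel = 1)
  k2 <- build_kymograph(sim0$movie, spec0$path, width = 5, channel = 2)
  tr0 <- classify_cotransport(detect_tracks(k1), k2, co_threshold = 30)
  expect_false(any(tr0$co_positive))
})
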