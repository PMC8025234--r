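#' Synthetic imaging and electrophysiology data with ground truth
#'
#' These generators emulate the input classes of the quantification pipeline
#' — diffraction-blurred puncta fields, two-channel colocalization /
#' segregation fields, axonal transport movies, EM vesicle sections and
#' evoked-current traces — with full per-object ground truth, so every
#' downstream stage can be validated against known parameters.
#'
#' Spots are rendered as analytic 2D Gaussians (amplitude x
#' Gaussian(psf_sigma)), giving an exact noiseless integrated intensity of
#' `amplitude * 2 * pi * psf_sigma^2` per spot. Noise is Poisson shot noise
#' on `signal / poisson_scale` rescaled back, plus additive Gaussian read
#' noise. Identical seeds give bit-identical outputs.
#'
#' @name synthdata
NULL

#' Specification of a synthetic puncta field
#'
#' @param image_shape `c(ny, nx)` in pixels.
#' @param pixel_size µm per pixel.
#' @param n_puncta number of spots (>= 0).
#' @param amplitude_range `c(lo, hi)` peak amplitudes, arbitrary units.
#' @param psf_sigma Gaussian PSF sigma in pixels (> 0).
#' @param background constant background level, AU.
#' @param noise list `poisson_scale` (0 disables shot noise; AU per photon)
#'   and `gaussian_sd` (0 disables read noise; AU).
#' @param min_separation minimum center-to-center distance between spots, px.
#' @param seed integer RNG seed.
#' @return a `puncta_field_spec`.
#' @export
puncta_field_spec <- function(image_shape = c(256, 256), pixel_size = 0.1,
                              n_puncta = 50, amplitude_range = c(80, 120),
                              psf_sigma = 2, background = 20,
                              noise = list(poisson_scale = 1, gaussian_sd = 2),
                              min_separation = 8, seed = 1) {
  stopifnot(n_puncta >= 0, psf_sigma > 0, min_separation >= 0, pixel_size > 0,
            length(image_shape) == 2, all(image_shape >= 8))
  if (is.null(noise$poisson_scale)) noise$poisson_scale <- 0
  if (is.null(noise$gaussian_sd)) noise$gaussian_sd <- 0
  structure(list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
                 n_puncta = as.integer(n_puncta), amplitude_range = amplitude_range,
                 psf_sigma = psf_sigma, background = background, noise = noise,
                 min_separation = min_separation, seed = seed),
            class = "puncta_field_spec")
}

# Rejection-sample n point centers with a minimum pairwise separation.
# Errors with "infeasible density" after bounded retries.
place_points <- function(n, ny, nx, margin, min_sep, max_tries = 200L) {
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (tr in seq_len(max_tries)) {
      x <- runif(1, margin, nx - 1 - margin)
      y <- runif(1, margin, ny - 1 - margin)
      if (length(xs) == 0 || min((xs - x)^2 + (ys - y)^2) >= min_sep^2) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("infeasible density: could not place ", n,
                  " points with min_separation ", min_sep)
    xs <- c(xs, x); ys <- c(ys, y)
  }
  cbind(x = xs, y = ys)
}

# Add Gaussian spots to matrix img (0-based coordinates).
render_gaussians <- function(img, x, y, amp, sigma) {
  ny <- nrow(img); nx <- ncol(img)
  w <- ceiling(6 * sigma)
  for (i in seq_along(x)) {
    cx <- x[i]; cy <- y[i]
    x0 <- max(0, floor(cx) - w); x1 <- min(nx - 1, ceiling(cx) + w)
    y0 <- max(0, floor(cy) - w); y1 <- min(ny - 1, ceiling(cy) + w)
    xs <- x0:x1; ys <- y0:y1
    gx <- exp(-(xs - cx)^2 / (2 * sigma^2))
    gy <- exp(-(ys - cy)^2 / (2 * sigma^2))
    img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + amp[i] * outer(gy, gx)
  }
  img
}

apply_noise <- function(img, noise) {
  if (!is.null(noise$poisson_scale) && noise$poisson_scale > 0) {
    img <- matrix(stats::rpois(length(img), pmax(img, 0) / noise$poisson_scale),
                  nrow(img), ncol(img)) * noise$poisson_scale
  }
  if (!is.null(noise$gaussian_sd) && noise$gaussian_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, noise$gaussian_sd),
                        nrow(img), ncol(img))
  }
  img
}

#' Generate a single-channel puncta field
#'
#' @param spec a [puncta_field_spec()].
#' @return list with `image` (a [cal_image()]) and `truth` (a `ground_truth`:
#'   `$objects` has one row per spot with 0-based pixel centroid, centroid in
#'   µm, amplitude, noiseless integrated intensity `amplitude * 2π σ²`, and a
#'   `clipped` flag for spots within `3 σ` of the border).
#' @export
generate_puncta_field <- function(spec) {
  stopifnot(inherits(spec, "puncta_field_spec"))
  with_seed(spec$seed, {
    ny <- spec$image_shape[1]; nx <- spec$image_shape[2]
    img <- matrix(spec$background, ny, nx)
    if (spec$n_puncta > 0) {
      margin <- min(2 * spec$psf_sigma, (min(ny, nx) - 1) / 4)
      pts <- place_points(spec$n_puncta, ny, nx, margin, spec$min_separation)
      amp <- runif(spec$n_puncta, spec$amplitude_range[1], spec$amplitude_range[2])
      img <- render_gaussians(img, pts[, "x"], pts[, "y"], amp, spec$psf_sigma)
      clipped <- pts[, "x"] < 3 * spec$psf_sigma | pts[, "x"] > nx - 1 - 3 * spec$psf_sigma |
        pts[, "y"] < 3 * spec$psf_sigma | pts[, "y"] > ny - 1 - 3 * spec$psf_sigma
      objects <- data.frame(id = seq_len(spec$n_puncta),
                            x_px = pts[, "x"], y_px = pts[, "y"],
                            x_um = pts[, "x"] * spec$pixel_size,
                            y_um = pts[, "y"] * spec$pixel_size,
                            amplitude = amp,
                            integrated_intensity = amp * 2 * pi * spec$psf_sigma^2,
                            clipped = clipped)
    } else {
      objects <- data.frame(id = integer(0), x_px = numeric(0), y_px = numeric(0),
                            x_um = numeric(0), y_um = numeric(0),
                            amplitude = numeric(0),
                            integrated_intensity = numeric(0), clipped = logical(0))
    }
    img <- apply_noise(img, spec$noise)
    list(image = cal_image(img, spec$pixel_size),
         truth = ground_truth(objects, spec))
  })
}

#' Specification of a two-channel field
#'
#' Two modes: `shared_fraction` places that fraction of spots at identical
#' centroids in both channels (amplitudes drawn independently per channel);
#' `center_offset` generates spot pairs whose channel-2 member is displaced
#' by exactly `center_offset` µm along `offset_direction` degrees.
#'
#' @param base a [puncta_field_spec()] used for both channels.
#' @param mode `"shared_fraction"` or `"center_offset"`.
#' @param shared_fraction fraction of colocalized spots in `[0, 1]`.
#' @param center_offset pair offset in µm (>= 0).
#' @param offset_direction offset direction in degrees (0 = +x).
#' @return a `two_channel_spec`.
#' @export
two_channel_spec <- function(base, mode = c("shared_fraction", "center_offset"),
                             shared_fraction = 1, center_offset = 0.4,
                             offset_direction = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(base, "puncta_field_spec"),
            shared_fraction >= 0, shared_fraction <= 1, center_offset >= 0)
  structure(list(base = base, mode = mode, shared_fraction = shared_fraction,
                 center_offset = center_offset, offset_direction = offset_direction),
            class = "two_channel_spec")
}

#' Generate a two-channel puncta field
#'
#' @param spec a [two_channel_spec()].
#' @return list with `ch1`, `ch2` (both [cal_image()]) and `truth`; truth
#'   objects carry `channel` (1/2), `pair_id` (shared identity across
#'   channels, NA if unpaired) and `shared`/offset columns per mode.
#' @export
generate_two_channel_field <- function(spec) {
  stopifnot(inherits(spec, "two_channel_spec"))
  b <- spec$base
  with_seed(b$seed, {
    ny <- b$image_shape[1]; nx <- b$image_shape[2]
    n <- b$n_puncta
    if (spec$mode == "shared_fraction") {
      n_shared <- round(n * spec$shared_fraction)
      n_total <- n + (n - n_shared)  # ch1 spots + ch2-only spots
      margin <- min(2 * b$psf_sigma, (min(ny, nx) - 1) / 4)
      pts <- if (n_total > 0) place_points(n_total, ny, nx, margin, b$min_separation)
             else cbind(x = numeric(0), y = numeric(0))
      # ch1: first n points; ch2: first n_shared (shared) + last n - n_shared
      i1 <- seq_len(n)
      i2 <- c(seq_len(n_shared), if (n > n_shared) (n + 1):n_total)
      a1 <- runif(n, b$amplitude_range[1], b$amplitude_range[2])
      a2 <- runif(length(i2), b$amplitude_range[1], b$amplitude_range[2])
      img1 <- render_gaussians(matrix(b$background, ny, nx),
                               pts[i1, "x"], pts[i1, "y"], a1, b$psf_sigma)
      img2 <- render_gaussians(matrix(b$background, ny, nx),
                               pts[i2, "x"], pts[i2, "y"], a2, b$psf_sigma)
      objects <- rbind(
        data.frame(channel = 1L, id = i1, x_px = pts[i1, "x"], y_px = pts[i1, "y"],
                   amplitude = a1,
                   pair_id = ifelse(i1 <= n_shared, i1, NA_integer_),
                   shared = i1 <= n_shared),
        data.frame(channel = 2L, id = seq_along(i2), x_px = pts[i2, "x"],
                   y_px = pts[i2, "y"], amplitude = a2,
                   pair_id = ifelse(seq_along(i2) <= n_shared,
                                    seq_along(i2), NA_integer_),
                   shared = seq_along(i2) <= n_shared))
    } else {
      dx <- spec$center_offset / b$pixel_size * cos(spec$offset_direction * pi / 180)
      dy <- spec$center_offset / b$pixel_size * sin(spec$offset_direction * pi / 180)
      margin <- min(2 * b$psf_sigma, (min(ny, nx) - 1) / 4) +
        max(abs(dx), abs(dy))
      pts <- if (n > 0) place_points(n, ny, nx, margin, b$min_separation)
             else cbind(x = numeric(0), y = numeric(0))
      a1 <- runif(n, b$amplitude_range[1], b$amplitude_range[2])
      a2 <- runif(n, b$amplitude_range[1], b$amplitude_range[2])
      img1 <- render_gaussians(matrix(b$background, ny, nx),
                               pts[, "x"], pts[, "y"], a1, b$psf_sigma)
      img2 <- render_gaussians(matrix(b$background, ny, nx),
                               pts[, "x"] + dx, pts[, "y"] + dy, a2, b$psf_sigma)
      objects <- rbind(
        data.frame(channel = 1L, id = seq_len(n), x_px = pts[, "x"],
                   y_px = pts[, "y"], amplitude = a1,
                   pair_id = seq_len(n), shared = FALSE),
        data.frame(channel = 2L, id = seq_len(n), x_px = pts[, "x"] + dx,
                   y_px = pts[, "y"] + dy, amplitude = a2,
                   pair_id = seq_len(n), shared = FALSE))
    }
    objects$x_um <- objects$x_px * b$pixel_size
    objects$y_um <- objects$y_px * b$pixel_size
    objects$integrated_intensity <- objects$amplitude * 2 * pi * b$psf_sigma^2
    img1 <- apply_noise(img1, b$noise)
    img2 <- apply_noise(img2, b$noise)
    list(ch1 = cal_image(img1, b$pixel_size),
         ch2 = cal_image(img2, b$pixel_size),
         truth = ground_truth(objects, spec))
  })
}

#' Specification of an axonal transport movie
#'
#' Particles move along a 1D path coordinate rendered into 2D frames; a set
#' fraction of channel-1 particles carry a channel-2 signal at the same
#' position in every frame (cotransport). Positive velocities move toward
#' increasing path coordinate (anterograde; the path starts at the proximal
#' end).
#'
#' @param image_shape `c(ny, nx)` px.
#' @param pixel_size µm/px.
#' @param n_frames number of frames.
#' @param frame_interval seconds per frame (> 0).
#' @param path n x 2 polyline of (x, y) pixel coordinates, proximal end first.
#' @param n_particles number of particles.
#' @param velocity_range `c(lo, hi)` signed velocities in µm/s.
#' @param cotransport_fraction fraction of particles positive in channel 2.
#' @param pause_prob per-frame probability that a particle does not move.
#' @param particle_sigma rendered Gaussian sigma, px.
#' @param amplitude_range particle peak amplitude range, AU.
#' @param background,noise as in [puncta_field_spec()].
#' @param seed integer RNG seed.
#' @return a `transport_movie_spec`.
#' @export
transport_movie_spec <- function(image_shape = c(24, 520), pixel_size = 0.1,
                                 n_frames = 60, frame_interval = 1,
                                 path = cbind(x = c(4, 515), y = c(12, 12)),
                                 n_particles = 1,
                                 velocity_range = c(0.3, 1.2),
                                 cotransport_fraction = 0.5,
                                 pause_prob = 0, particle_sigma = 1.5,
                                 amplitude_range = c(80, 120),
                                 background = 20,
                                 noise = list(poisson_scale = 1, gaussian_sd = 2),
                                 seed = 1) {
  stopifnot(frame_interval > 0, all(is.finite(velocity_range)),
            cotransport_fraction >= 0, cotransport_fraction <= 1,
            pause_prob >= 0, pause_prob < 1, n_frames >= 1)
  path <- as.matrix(path)
  if (polyline_length(path, pixel_size) < 4)
    stop("path length must be at least 4 µm")
  if (is.null(noise$poisson_scale)) noise$poisson_scale <- 0
  if (is.null(noise$gaussian_sd)) noise$gaussian_sd <- 0
  structure(list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
                 n_frames = as.integer(n_frames), frame_interval = frame_interval,
                 path = path, n_particles = as.integer(n_particles),
                 velocity_range = velocity_range,
                 cotransport_fraction = cotransport_fraction,
                 pause_prob = pause_prob, particle_sigma = particle_sigma,
                 amplitude_range = amplitude_range, background = background,
                 noise = noise, seed = seed),
            class = "transport_movie_spec")
}

# Map arclength s (px) along a polyline to (x, y) pixel coordinates.
path_point <- function(path, s) {
  seg <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  s <- pmin(pmax(s, 0), L)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(i, length(seg))
  f <- (s - cum[i]) / seg[i]
  cbind(x = path[i, 1] + f * (path[i + 1, 1] - path[i, 1]),
        y = path[i, 2] + f * (path[i + 1, 2] - path[i, 2]))
}

#' Generate a two-channel axonal transport movie
#'
#' Each particle's start position is drawn so that it stays on the path for
#' the whole movie when the path is long enough; otherwise it is truncated
#' at the path end and flagged in the truth table.
#'
#' @param spec a [transport_movie_spec()].
#' @return list with `movie` (a 4D [cal_image()], axes `yxct`, 2 channels)
#'   and `truth` (per particle: velocity µm/s, direction, cotransport flag,
#'   start path coordinate µm, frames visible, truncated flag).
#' @export
generate_transport_movie <- function(spec) {
  stopifnot(inherits(spec, "transport_movie_spec"))
  with_seed(spec$seed, {
    ny <- spec$image_shape[1]; nx <- spec$image_shape[2]
    L_px <- polyline_length(spec$path)
    n <- spec$n_particles
    v <- runif(n, spec$velocity_range[1], spec$velocity_range[2])
    co <- rep(FALSE, n)
    if (n > 0) co[seq_len(round(n * spec$cotransport_fraction))] <- TRUE
    amp1 <- runif(n, spec$amplitude_range[1], spec$amplitude_range[2])
    amp2 <- runif(n, spec$amplitude_range[1], spec$amplitude_range[2])
    dur <- (spec$n_frames - 1) * spec$frame_interval
    travel_px <- abs(v) * dur / spec$pixel_size
    s0 <- numeric(n); truncated <- logical(n)
    for (i in seq_len(n)) {
      if (travel_px[i] <= L_px) {
        if (v[i] >= 0) s0[i] <- runif(1, 0, L_px - travel_px[i])
        else s0[i] <- runif(1, travel_px[i], L_px)
      } else {
        s0[i] <- if (v[i] >= 0) 0 else L_px
        truncated[i] <- TRUE
      }
    }
    # per-frame path coordinate (px); pauses freeze the coordinate
    s <- matrix(NA_real_, spec$n_frames, n)
    if (n > 0) {
      s[1, ] <- s0
      step <- v * spec$frame_interval / spec$pixel_size
      for (f in seq_len(spec$n_frames - 1)) {
        moving <- if (spec$pause_prob > 0) runif(n) >= spec$pause_prob else rep(TRUE, n)
        s[f + 1, ] <- pmin(pmax(s[f, ] + step * moving, 0), L_px)
      }
    }
    movie <- array(spec$background, dim = c(ny, nx, 2, spec$n_frames))
    frames_visible <- integer(n)
    for (f in seq_len(spec$n_frames)) {
      f1 <- matrix(spec$background, ny, nx)
      f2 <- matrix(spec$background, ny, nx)
      if (n > 0) {
        pt <- path_point(spec$path, s[f, ])
        vis <- s[f, ] >= 0 & s[f, ] <= L_px
        frames_visible <- frames_visible + vis
        f1 <- render_gaussians(f1, pt[vis, 1], pt[vis, 2], amp1[vis],
                               spec$particle_sigma)
        keep <- vis & co
        f2 <- render_gaussians(f2, pt[keep, 1], pt[keep, 2], amp2[keep],
                               spec$particle_sigma)
      }
      movie[, , 1, f] <- apply_noise(f1, spec$noise)
      movie[, , 2, f] <- apply_noise(f2, spec$noise)
    }
    objects <- data.frame(id = seq_len(n), velocity_um_s = v,
                          direction = ifelse(v >= 0, "anterograde", "retrograde"),
                          cotransport = co,
                          start_um = s0 * spec$pixel_size,
                          frames_visible = frames_visible,
                          truncated = truncated)
    list(movie = cal_image(movie, spec$pixel_size, spec$frame_interval, "yxct",
                           channels = c("cargo", "co")),
         truth = ground_truth(objects, spec))
  })
}

#' Specification of a synthetic EM section of vesicle profiles
#'
#' Elliptical profiles with lognormally-clamped normal axis distributions,
#' non-overlapping within a square region.
#'
#' @param n_objects number of ellipse profiles.
#' @param long_diameter_dist `c(mean, sd)` of the long diameter, nm.
#' @param elongation_dist `c(mean, sd)` of the long/short ratio (>= 1).
#' @param region_area region area in nm² (a square region is used).
#' @param pixel_size nm per pixel.
#' @param seed integer RNG seed.
#' @return an `em_section_spec`.
#' @export
em_section_spec <- function(n_objects = 30, long_diameter_dist = c(72, 10),
                            elongation_dist = c(1.79, 0.3),
                            region_area = 1e6, pixel_size = 2, seed = 1) {
  stopifnot(n_objects >= 0, elongation_dist[1] >= 1, region_area > 0,
            pixel_size > 0)
  structure(list(n_objects = as.integer(n_objects),
                 long_diameter_dist = long_diameter_dist,
                 elongation_dist = elongation_dist,
                 region_area = region_area, pixel_size = pixel_size, seed = seed),
            class = "em_section_spec")
}

#' Generate a labeled EM section of elliptical vesicle profiles
#'
#' @param spec an [em_section_spec()].
#' @param axes optional n x 2 matrix of fixed (long, short) diameters in nm,
#'   bypassing the random draws (orientation still random).
#' @return list with `labels` (integer label matrix), `pixel_size` (nm/px)
#'   and `truth` (per object: long/short diameter nm, elongation, area nm²).
#' @export
generate_em_sections <- function(spec, axes = NULL) {
  stopifnot(inherits(spec, "em_section_spec"))
  with_seed(spec$seed, {
    side_px <- round(sqrt(spec$region_area) / spec$pixel_size)
    n <- spec$n_objects
    if (is.null(axes)) {
      long_d <- pmax(stats::rnorm(n, spec$long_diameter_dist[1],
                                  spec$long_diameter_dist[2]), 4 * spec$pixel_size)
      elong <- pmax(stats::rnorm(n, spec$elongation_dist[1],
                                 spec$elongation_dist[2]), 1)
    } else {
      axes <- as.matrix(axes)
      long_d <- axes[, 1]; elong <- axes[, 1] / axes[, 2]
      n <- nrow(axes)
    }
    short_d <- long_d / elong
    theta <- runif(n, 0, pi)
    # place non-overlapping (conservative: disjoint bounding circles)
    r_px <- long_d / 2 / spec$pixel_size
    xs <- numeric(0); ys <- numeric(0)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (tr in 1:500) {
        x <- runif(1, r_px[i] + 1, side_px - r_px[i] - 2)
        y <- runif(1, r_px[i] + 1, side_px - r_px[i] - 2)
        if (length(xs) == 0 ||
            all((xs - x)^2 + (ys - y)^2 >= (r_px[seq_along(xs)] + r_px[i] + 1)^2)) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("infeasible packing: cannot place ", n, " objects in region")
      xs <- c(xs, x); ys <- c(ys, y)
    }
    labels <- matrix(0L, side_px, side_px)
    xg <- matrix(rep(0:(side_px - 1), each = side_px), side_px, side_px)
    yg <- matrix(rep(0:(side_px - 1), times = side_px), side_px, side_px)
    for (i in seq_len(n)) {
      a <- long_d[i] / 2 / spec$pixel_size
      b <- short_d[i] / 2 / spec$pixel_size
      u <- (xg - xs[i]) * cos(theta[i]) + (yg - ys[i]) * sin(theta[i])
      w <- -(xg - xs[i]) * sin(theta[i]) + (yg - ys[i]) * cos(theta[i])
      inside <- (u / a)^2 + (w / b)^2 <= 1
      labels[inside] <- i
    }
    objects <- data.frame(id = seq_len(n), x_px = xs, y_px = ys,
                          long_diameter_nm = long_d, short_diameter_nm = short_d,
                          elongation = long_d / short_d,
                          theta = theta,
                          area_nm2 = pi * long_d * short_d / 4)
    list(labels = labels, pixel_size = spec$pixel_size,
         truth = ground_truth(objects, spec))
  })
}

#' Specification of an evoked-current trace
#'
#' The transient is a difference of exponentials,
#' `amplitude * (exp(-t/decay_tau) - exp(-t/rise_tau))`, normalized so the
#' peak equals `amplitude` (inward currents negative).
#'
#' @param sample_rate Hz (> 0).
#' @param duration total trace duration, s (default spans all stimuli).
#' @param baseline holding current, nA.
#' @param amplitude signed peak amplitude, nA.
#' @param rise_tau,decay_tau kinetics in ms; `decay_tau > rise_tau > 0`.
#' @param stim_times stimulus onset times, s.
#' @param noise_sd additive Gaussian noise SD, nA.
#' @param seed integer RNG seed.
#' @return an `ephys_trace_spec`.
#' @export
ephys_trace_spec <- function(sample_rate = 10000, duration = NULL,
                             baseline = -2, amplitude = -75,
                             rise_tau = 1, decay_tau = 5.5,
                             stim_times = 0.05, noise_sd = 0, seed = 1) {
  if (sample_rate <= 0) stop("sample_rate must be positive")
  stopifnot(decay_tau > rise_tau, rise_tau > 0)
  if (is.null(duration))
    duration <- (if (length(stim_times)) max(stim_times) else 0) +
      20 * decay_tau / 1000 + 0.05
  structure(list(sample_rate = sample_rate, duration = duration,
                 baseline = baseline, amplitude = amplitude,
                 rise_tau = rise_tau, decay_tau = decay_tau,
                 stim_times = stim_times, noise_sd = noise_sd, seed = seed),
            class = "ephys_trace_spec")
}

# Peak-normalized biexponential kernel; t in seconds, taus in ms.
biexp_kernel <- function(t, rise_tau, decay_tau) {
  tr <- rise_tau / 1000; td <- decay_tau / 1000
  tpk <- log(td / tr) * td * tr / (td - tr)
  norm <- exp(-tpk / td) - exp(-tpk / tr)
  k <- ifelse(t >= 0, exp(-t / td) - exp(-t / tr), 0) / norm
  k
}

#' Generate an evoked-current trace
#'
#' @param spec an [ephys_trace_spec()].
#' @return list with `trace` (data.frame `time_s`, `current_nA`) and `truth`.
#' @export
generate_ephys_trace <- function(spec) {
  stopifnot(inherits(spec, "ephys_trace_spec"))
  with_seed(spec$seed, {
    t <- seq(0, spec$duration, by = 1 / spec$sample_rate)
    i <- rep(spec$baseline, length(t))
    for (ts in spec$stim_times)
      i <- i + spec$amplitude * biexp_kernel(t - ts, spec$rise_tau, spec$decay_tau)
    if (spec$noise_sd > 0) i <- i + stats::rnorm(length(t), 0, spec$noise_sd)
    objects <- data.frame(stim_time_s = if (length(spec$stim_times)) spec$stim_times else numeric(0),
                          amplitude_nA = rep(spec$amplitude, length(spec$stim_times)),
                          rise_tau_ms = rep(spec$rise_tau, length(spec$stim_times)),
                          decay_tau_ms = rep(spec$decay_tau, length(spec$stim_times)))
    list(trace = data.frame(time_s = t, current_nA = i),
         truth = ground_truth(objects, spec))
  })
}

#' Ground-truth container
#'
#' One record per generated object plus an echo of the generator spec.
#'
#' @param objects data.frame of per-object truth (units in column names).
#' @param spec the generator specification.
#' @return a `ground_truth`.
#' @export
ground_truth <- function(objects, spec) {
  structure(list(objects = objects, spec = spec), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", nrow(x$objects), " objects from ",
      class(x$spec)[1], "\n", sep = "")
  invisible(x)
}

#' Write ground truth (CSV) and generator spec (sidecar JSON) to a directory
#'
#' @param truth a `ground_truth`.
#' @param dir output directory (created if needed).
#' @param stem file stem for `<stem>_truth.csv` and `<stem>_spec.json`.
#' @return the directory, invisibly.
#' @export
write_ground_truth <- function(truth, dir, stem = "sim") {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(truth$objects, file.path(dir, paste0(stem, "_truth.csv")),
                   row.names = FALSE)
  sp <- truth$spec
  sp_list <- lapply(unclass(sp), function(el) {
    if (inherits(el, "puncta_field_spec")) unclass(el) else el
  })
  sp_list$spec_class <- class(sp)[1]
  jsonlite::write_json(sp_list, file.path(dir, paste0(stem, "_spec.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Random planar sections through a sphere suspension
#'
#' Simulates the stereological sampling situation: spheres of one radius at
#' a known volume fraction in a periodic box, cut by planes at random
#' heights. Each section is returned as a label image of circle profiles;
#' running [volume_fraction()] on the sections and averaging tests the
#' Delesse areal-fraction estimator against the known truth.
#'
#' @param n_sections number of random section planes.
#' @param target_vf target sphere volume fraction (the realized truth is
#'   returned; it differs only by rounding the sphere count).
#' @param radius_nm sphere radius, nm.
#' @param box_nm periodic box edge length, nm.
#' @param pixel_size section rasterization, nm/px.
#' @param seed integer RNG seed.
#' @return list with `sections` (list of integer label matrices),
#'   `pixel_size` and `truth` (realized volume fraction, sphere count).
#' @export
generate_sphere_sections <- function(n_sections = 100, target_vf = 0.02,
                                     radius_nm = 25, box_nm = 2000,
                                     pixel_size = 2, seed = 1) {
  stopifnot(target_vf > 0, target_vf < 0.2, radius_nm < box_nm / 4)
  with_seed(seed, {
    v_sphere <- 4 / 3 * pi * radius_nm^3
    n_spheres <- round(target_vf * box_nm^3 / v_sphere)
    vf_true <- n_spheres * v_sphere / box_nm^3
    cx <- runif(n_spheres, 0, box_nm)
    cy <- runif(n_spheres, 0, box_nm)
    cz <- runif(n_spheres, 0, box_nm)
    side_px <- round(box_nm / pixel_size)
    sections <- lapply(seq_len(n_sections), function(i) {
      z0 <- runif(1, 0, box_nm)
      dz <- abs(cz - z0)
      dz <- pmin(dz, box_nm - dz)  # periodic in z
      hit <- which(dz < radius_nm)
      lab <- matrix(0L, side_px, side_px)
      for (k in seq_along(hit)) {
        j <- hit[k]
        rho_px <- sqrt(radius_nm^2 - dz[j]^2) / pixel_size
        x0 <- cx[j] / pixel_size; y0 <- cy[j] / pixel_size
        w <- ceiling(rho_px)
        xs <- (floor(x0) - w):(ceiling(x0) + w)
        ys <- (floor(y0) - w):(ceiling(y0) + w)
        inside <- outer((ys - y0)^2, (xs - x0)^2, "+") <= rho_px^2
        # periodic wrap of the local window
        xi <- (xs %% side_px) + 1L
        yi <- (ys %% side_px) + 1L
        sub <- lab[yi, xi]
        sub[inside] <- k
        lab[yi, xi] <- sub
      }
      lab
    })
    list(sections = sections, pixel_size = pixel_size,
         truth = list(volume_fraction = vf_true, n_spheres = n_spheres,
                      radius_nm = radius_nm, box_nm = box_nm))
  })
}
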