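# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# Quiet single-spot field with exact truth.
one_spot_spec <- function(amplitude = 100, psf_sigma = 2, background = 10,
                          noise = list(poisson_scale = 0, gaussian_sd = 0),
                          seed = 1, shape = c(64, 64)) {
  puncta_field_spec(image_shape = shape, pixel_size = 0.1, n_puncta = 1,
                    amplitude_range = c(amplitude, amplitude),
                    psf_sigma = psf_sigma, background = background,
                    noise = noise, min_separation = 0, seed = seed)
}

# Full-frame rectangular polygon ROI for an ny x nx image.
full_roi <- function(ny, nx) {
  roi("polygon", cbind(c(0, nx - 1, nx - 1, 0), c(0, 0, ny - 1, ny - 1)))
}

# Rasterize a filled ellipse (0-based pixel centers) into a label matrix.
raster_ellipse <- function(ny, nx, cx, cy, a_px, b_px, theta = 0, label = 1L) {
  xg <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  yg <- matrix(rep(0:(ny - 1), times = nx), ny, nx)
  u <- (xg - cx) * cos(theta) + (yg - cy) * sin(theta)
  w <- -(xg - cx) * sin(theta) + (yg - cy) * cos(theta)
  m <- matrix(0L, ny, nx)
  m[(u / a_px)^2 + (w / b_px)^2 <= 1] <- label
  m
}

# Voxelized ball in an n^3 array (1-based center), radius in voxels.
raster_ball <- function(n, r, ctr = (n + 1) / 2) {
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  array(as.integer((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= r^2),
        dim = c(n, n, n))
}

# Brute-force prominence of every strict local maximum of a matrix, by
# descending level scan with an explicit 8-connected flood fill
# (independent of find_maxima's union-find implementation).
brute_force_prominent_maxima <- function(img, prominence) {
  ny <- nrow(img); nx <- ncol(img)
  is_max <- matrix(FALSE, ny, nx)
  for (y in 1:ny) for (x in 1:nx) {
    nb <- expand.grid(yy = max(1, y - 1):min(ny, y + 1),
                      xx = max(1, x - 1):min(nx, x + 1))
    nb <- nb[!(nb$yy == y & nb$xx == x), ]
    is_max[y, x] <- all(img[y, x] > as.numeric(img[cbind(nb$yy, nb$xx)]))
  }
  # 8-connected component of {img >= L} containing p, via queue flood fill
  component_of <- function(p, L) {
    inset <- img >= L
    seen <- matrix(FALSE, ny, nx)
    seen[p] <- TRUE
    queue <- p
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      y <- (q - 1) %% ny + 1; x <- (q - 1) %/% ny + 1
      for (yy in max(1, y - 1):min(ny, y + 1)) {
        for (xx in max(1, x - 1):min(nx, x + 1)) {
          r <- (xx - 1) * ny + yy
          if (!seen[r] && inset[r]) { seen[r] <- TRUE; queue <- c(queue, r) }
        }
      }
    }
    which(seen)
  }
  connected_higher <- function(p, L) {
    comp <- component_of(p, L)
    max(img[comp]) > img[p]
  }
  peaks <- which(is_max)
  global_max <- peaks[which.max(img[peaks])]
  keep <- logical(length(peaks))
  levels_desc <- sort(unique(as.vector(img)), decreasing = TRUE)
  for (i in seq_along(peaks)) {
    p <- peaks[i]
    if (p == global_max) { keep[i] <- TRUE; next }
    # connectivity to higher ground is monotone in the level: binary-search
    # the highest level at which the peak's component contains a higher pixel
    cand <- levels_desc[levels_desc <= img[p]]
    lo <- 1L; hi <- length(cand)
    if (!connected_higher(p, cand[hi])) { keep[i] <- TRUE; next }  # never merges
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (connected_higher(p, cand[mid])) hi <- mid else lo <- mid + 1L
    }
    prom <- img[p] - cand[lo]
    keep[i] <- prom >= prominence
  }
  sort(peaks[keep])
}

# Straight-line kymograph painted directly: a streak from (row0, col0) to
# (row1, col1) on a quiet background.
paint_streak <- function(n_rows, n_cols, row0, col0, row1, col1,
                         value = 100, background = 0) {
  m <- matrix(background, n_rows, n_cols)
  rows <- row0:row1
  cols <- round(seq(col0, col1, length.out = length(rows)))
  m[cbind(rows, cols + 1)] <- value
  m
}
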