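#' Translation-only movie registration by phase correlation
#'
#' Aligns every frame of a time-lapse to the first frame using FFT phase
#' correlation; the recovered integer shift is undone by a circular
#' translation. Registration uses channel 1 when the movie has a channel
#' axis and applies the same shift to all channels of a frame.
#'
#' @param movie a [cal_image()] with a time axis (`yxt` or `yxct`).
#' @return the registered movie; attribute `"shifts"` holds the per-frame
#'   recovered (dx, dy) in pixels.
#' @export
register_movie <- function(movie) {
  stopifnot(inherits(movie, "cal_image"))
  ax <- strsplit(movie$axes, "")[[1]]
  if (!"t" %in% ax) stop("movie has no time axis")
  has_c <- "c" %in% ax
  nt <- dim(movie$data)[length(ax)]
  if (nt < 2) stop("registration needs at least 2 frames")
  ref <- if (has_c) movie$data[, , 1, 1] else movie$data[, , 1]
  Fref <- stats::fft(ref)
  out <- movie$data
  shifts <- matrix(0, nt, 2, dimnames = list(NULL, c("dx", "dy")))
  ny <- nrow(ref); nx <- ncol(ref)
  for (f in 2:nt) {
    cur <- if (has_c) movie$data[, , 1, f] else movie$data[, , f]
    Fc <- stats::fft(cur)
    R <- Fref * Conj(Fc)
    R <- R / pmax(Mod(R), .Machine$double.eps)
    corr <- Re(stats::fft(R, inverse = TRUE))
    pk <- which.max(corr)
    py <- ((pk - 1) %% ny)
    px <- ((pk - 1) %/% ny)
    # correlation peak sits at minus the shift of cur relative to ref
    dy <- -(if (py > ny / 2) py - ny else py)
    dx <- -(if (px > nx / 2) px - nx else px)
    shifts[f, ] <- c(dx, dy)
    roll <- function(m, dx, dy) {
      if (dy != 0) m <- m[((seq_len(ny) - 1 - dy) %% ny) + 1, , drop = FALSE]
      if (dx != 0) m <- m[, ((seq_len(nx) - 1 - dx) %% nx) + 1, drop = FALSE]
      m
    }
    if (has_c) {
      for (ch in seq_len(dim(movie$data)[3]))
        out[, , ch, f] <- roll(movie$data[, , ch, f], -dx, -dy)
    } else out[, , f] <- roll(cur, -dx, -dy)
  }
  res <- cal_image(out, movie$pixel_size, movie$frame_interval, movie$axes,
                   movie$channels)
  attr(res, "shifts") <- shifts
  res
}

#' Build a kymograph along a path
#'
#' For each frame, the intensity profile along the path (bilinear sampling,
#' perpendicular mean over `width` pixels) forms one row; rows are stacked
#' in time order. Each frame is background-subtracted (percentile) and
#' lightly blurred (sigma 0.5 px) before sampling.
#'
#' @param movie a [cal_image()] with a time axis.
#' @param path an [roi()] polyline or n x 2 point matrix (px), proximal end
#'   first.
#' @param width perpendicular averaging width in pixels, in `[1, 20]`.
#' @param channel channel to sample (default 1).
#' @param prefilter apply background subtraction and blur (default TRUE).
#' @return a `kymograph`: list with `matrix` (time rows x position
#'   columns), `frame_interval` (s), `position_step` (µm; one pixel),
#'   `path`, `width`.
#' @export
build_kymograph <- function(movie, path, width = 5, channel = 1,
                            prefilter = TRUE) {
  stopifnot(inherits(movie, "cal_image"), width >= 1, width <= 20)
  ax <- strsplit(movie$axes, "")[[1]]
  if (!"t" %in% ax) stop("movie has no time axis")
  has_c <- "c" %in% ax
  nt <- dim(movie$data)[length(ax)]
  pts <- if (inherits(path, "roi")) path$points else as.matrix(path)
  ny <- dim(movie$data)[1]; nx <- dim(movie$data)[2]
  if (any(pts[, 1] < 0 | pts[, 1] > nx - 1 | pts[, 2] < 0 | pts[, 2] > ny - 1))
    stop("path exits frame bounds")
  rows <- vector("list", nt)
  for (f in seq_len(nt)) {
    frame <- if (has_c) movie$data[, , channel, f] else movie$data[, , f]
    if (prefilter) {
      frame <- pmax(frame - stats::quantile(frame, 0.25, names = FALSE), 0)
      frame <- blur_if(frame, 0.5)
    }
    prof <- line_profile(cal_image(frame, movie$pixel_size), pts, width = width)
    rows[[f]] <- prof$intensity
  }
  structure(list(matrix = do.call(rbind, rows),
                 frame_interval = movie$frame_interval,
                 position_step = movie$pixel_size,
                 path = pts, width = width),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat("<kymograph> ", nrow(x$matrix), " frames x ", ncol(x$matrix),
      " positions (", x$frame_interval, " s, ", x$position_step, " µm steps)\n",
      sep = "")
  invisible(x)
}

#' Detect transport tracks (streaks) in a kymograph
#'
#' Thresholds the kymograph, finds connected components in (time,
#' position), reduces each component to per-frame intensity-weighted
#' positions, and accepts a component as a track when it is unidirectional
#' (at most `reversal_tolerance` of frame-to-frame steps oppose the net
#' direction; pauses do not count), spans at least `min_length` µm of path
#' AND at least `min_duration` s (both bounds inclusive). Speed is the
#' spatial extent divided by the temporal extent; direction follows the
#' slope sign (increasing path coordinate = anterograde, path origin =
#' proximal).
#'
#' @param kymo a `kymograph`.
#' @param min_length minimum path-length extent, µm (default 4).
#' @param min_duration minimum temporal extent, s (default 30).
#' @param threshold intensity threshold; default Otsu on the kymograph.
#' @param reversal_tolerance max fraction of opposing steps (default 0.1).
#' @param max_step_px largest per-frame displacement (px) bridged when
#'   linking a streak across rows (default 15; a particle moving v µm/s
#'   steps `v * frame_interval / position_step` px between rows).
#' @return data.frame of track records: `start_s`, `end_s`,
#'   `start_um`, `end_um`, `path_length_um`, `duration_s`, `speed_um_s`,
#'   `direction`; attribute `"tracks_xy"` holds per-track row/position
#'   vectors for downstream cotransport checks. Empty data.frame when
#'   nothing qualifies.
#' @export
detect_tracks <- function(kymo, min_length = 4, min_duration = 30,
                          threshold = NULL, reversal_tolerance = 0.1,
                          max_step_px = 15) {
  stopifnot(inherits(kymo, "kymograph"))
  m <- kymo$matrix
  if (is.null(threshold)) threshold <- otsu_threshold(as.vector(m))
  mask <- m > threshold
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      start_um = numeric(0), end_um = numeric(0),
                      path_length_um = numeric(0), duration_s = numeric(0),
                      speed_um_s = numeric(0), direction = character(0),
                      co_positive = logical(0), co_frames = integer(0))
  if (!any(mask)) {
    attr(empty, "tracks_xy") <- list()
    return(empty)
  }
  # bridge per-frame jumps: a streak of a particle moving several px per
  # frame is not pixel-connected across rows, so label a horizontally
  # dilated copy but keep statistics on the original above-threshold pixels
  kern <- matrix(1, 1, 2 * ceiling(max_step_px / 2) + 1)
  linked <- EBImage::dilate(EBImage::Image(mask), kern) > 0
  lab <- EBImage::bwlabel(EBImage::Image(linked))
  lab <- EBImage::imageData(lab)
  recs <- list(); txy <- list()
  for (id in seq_len(max(lab))) {
    sel <- (lab == id) & mask
    if (sum(sel) < 3) next
    rows <- which(rowSums(sel) > 0)
    # per-frame weighted position (path coordinate, columns)
    posc <- vapply(rows, function(r) {
      w <- m[r, ] * sel[r, ]
      sum(w * (seq_len(ncol(m)) - 1)) / sum(w)
    }, numeric(1))
    dur <- (max(rows) - min(rows)) * kymo$frame_interval
    plen <- abs(posc[length(posc)] - posc[1]) * kymo$position_step
    if (length(posc) >= 3) {
      steps <- diff(posc)
      net <- sign(posc[length(posc)] - posc[1])
      if (net == 0) next  # no net movement
      moving <- steps[abs(steps) > 0.25]  # ignore pauses (sub-quarter-pixel)
      if (length(moving) > 0 &&
          mean(sign(moving) != net) > reversal_tolerance) next
    }
    if (dur + 1e-9 < min_duration || plen + 1e-9 < min_length) next
    speed <- plen / dur
    recs[[length(recs) + 1]] <- data.frame(
      start_s = (min(rows) - 1) * kymo$frame_interval,
      end_s = (max(rows) - 1) * kymo$frame_interval,
      start_um = posc[1] * kymo$position_step,
      end_um = posc[length(posc)] * kymo$position_step,
      path_length_um = plen, duration_s = dur, speed_um_s = speed,
      direction = if (posc[length(posc)] >= posc[1]) "anterograde" else "retrograde",
      co_positive = NA, co_frames = NA_integer_)
    txy[[length(txy) + 1]] <- list(rows = rows, pos = posc)
  }
  out <- if (length(recs)) do.call(rbind, recs) else empty
  attr(out, "tracks_xy") <- txy
  out
}

#' Classify cotransport of detected tracks against a second channel
#'
#' Samples the second channel's kymograph along each track's per-frame
#' positions within a tolerance band of +/- 2 px; a track is cotransport-
#' positive when the co-channel intensity exceeds `co_threshold` in at
#' least `min_co_frames` distinct time rows.
#'
#' @param tracks track table from [detect_tracks()] (with its
#'   `"tracks_xy"` attribute).
#' @param kymo_other the co-channel `kymograph` (same geometry).
#' @param co_threshold intensity threshold in the co-channel; default Otsu.
#' @param min_co_frames minimum positive rows (default 3).
#' @param band half-width of the sampling band in px (default 2).
#' @return the track table with `co_positive` and `co_frames` filled in.
#' @export
classify_cotransport <- function(tracks, kymo_other, co_threshold = NULL,
                                 min_co_frames = 3, band = 2) {
  stopifnot(inherits(kymo_other, "kymograph"))
  txy <- attr(tracks, "tracks_xy")
  if (nrow(tracks) == 0) return(tracks)
  m <- kymo_other$matrix
  if (is.null(co_threshold)) co_threshold <- otsu_threshold(as.vector(m))
  for (i in seq_len(nrow(tracks))) {
    tr <- txy[[i]]
    if (any(tr$rows > nrow(m)) || any(tr$pos > ncol(m) - 1 + band))
      stop("geometry mismatch between track and co-channel kymograph")
    hits <- vapply(seq_along(tr$rows), function(k) {
      cols <- round(tr$pos[k]) + (-band:band)
      cols <- cols[cols >= 0 & cols <= ncol(m) - 1]
      max(m[tr$rows[k], cols + 1]) > co_threshold
    }, logical(1))
    tracks$co_frames[i] <- sum(hits)
    tracks$co_positive[i] <- sum(hits) >= min_co_frames
  }
  tracks
}
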