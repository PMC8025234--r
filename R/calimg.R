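#' Calibrated image container
#'
#' A thin wrapper around a numeric array carrying physical calibration.
#' Spatial axes come first, in `y, x` order (matrix rows are `y`), followed
#' by optional `z`, `c` (channel) and `t` (time) axes as declared by `axes`.
#' Pixel coordinates are 0-based with pixel centers at integer coordinates;
#' physical positions are `coordinate * pixel_size`.
#'
#' @param data numeric array (2-4 dimensions).
#' @param pixel_size pixel edge length in micrometres per pixel.
#' @param frame_interval frame interval in seconds (time series only).
#' @param axes character string naming the array axes in order, one letter
#'   per dimension out of `"y" "x" "z" "c" "t"`; default `"yx"` for a matrix.
#' @param channels optional character vector of channel labels.
#' @return an object of class `cal_image`.
#' @export
cal_image <- function(data, pixel_size, frame_interval = NA_real_,
                      axes = NULL, channels = NULL) {
  if (!is.array(data) && !is.matrix(data)) data <- as.matrix(data)
  if (is.null(axes)) {
    axes <- switch(as.character(length(dim(data))),
                   "2" = "yx", "3" = "yxc", "4" = "yxct",
                   stop("cannot infer axes for a ", length(dim(data)), "-d array"))
  }
  ax <- strsplit(axes, "")[[1]]
  if (length(ax) != length(dim(data)))
    stop("axes '", axes, "' does not match array dimensionality ", length(dim(data)))
  if (!all(ax %in% c("y", "x", "z", "c", "t")) || anyDuplicated(ax))
    stop("axes must be distinct letters from y,x,z,c,t")
  if (!identical(ax[1:2], c("y", "x")))
    stop("first two axes must be y,x")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a positive scalar (µm/px)")
  structure(list(data = data, pixel_size = pixel_size,
                 frame_interval = frame_interval, axes = axes,
                 channels = channels),
            class = "cal_image")
}

#' @export
print.cal_image <- function(x, ...) {
  cat("<cal_image> ", paste(dim(x$data), collapse = " x "),
      " [", x$axes, "], ", x$pixel_size, " µm/px", sep = "")
  if (!is.na(x$frame_interval)) cat(", ", x$frame_interval, " s/frame", sep = "")
  if (!is.null(x$channels)) cat(", channels: ", paste(x$channels, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.cal_image <- function(x) dim(x$data)

#' Extract one channel / time point as a 2D calibrated image
#'
#' @param img a `cal_image`.
#' @param channel channel index (if the image has a `c` axis).
#' @param frame time index (if the image has a `t` axis).
#' @return a 2D `cal_image` (axes `"yx"`; a `z` axis, if present, is kept).
#' @export
get_plane <- function(img, channel = NULL, frame = NULL) {
  stopifnot(inherits(img, "cal_image"))
  ax <- strsplit(img$axes, "")[[1]]
  idx <- lapply(dim(img$data), seq_len)
  if (!is.null(channel)) {
    if (!"c" %in% ax) stop("image has no channel axis")
    idx[[which(ax == "c")]] <- channel
  }
  if (!is.null(frame)) {
    if (!"t" %in% ax) stop("image has no time axis")
    idx[[which(ax == "t")]] <- frame
  }
  out <- do.call(`[`, c(list(img$data), idx, list(drop = FALSE)))
  keep <- vapply(seq_along(ax), function(i) dim(out)[i] > 1L || ax[i] %in% c("y", "x", "z"),
                 logical(1))
  # drop singleton c/t axes only
  newdim <- dim(out)[keep]
  newax <- ax[keep]
  out <- array(out, dim = newdim)
  cal_image(out, img$pixel_size, img$frame_interval, paste(newax, collapse = ""),
            channels = if (is.null(channel)) img$channels else img$channels[channel])
}

#' Write a calibrated image as multi-page TIFF with a JSON sidecar
#'
#' Pixel data are stored as 32-bit TIFF pages (one page per plane of the
#' trailing axes) holding integer quantization levels `j = round((value -
#' offset) * 2^k)`, with the integer `offset` and the power-of-two step
#' `2^-k` recorded in the sidecar (`<path>.json`) next to calibration and
#' axes. `k` is the largest exponent (at most 20) keeping the levels below
#' 2^31, so the round trip is bit-exact for integer-valued and
#' dyadic-rational data and accurate to `2^-k` otherwise.
#'
#' @param img a `cal_image`.
#' @param path output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_cal_image <- function(img, path) {
  stopifnot(inherits(img, "cal_image"))
  d <- img$data
  offset <- min(0, floor(min(d)))  # integer shift keeps the transform exact
  d <- d - offset
  k <- min(20, floor(log2((2^31 - 1) / max(d, 1))))
  nd <- dim(d)
  nplanes <- prod(nd) / (nd[1] * nd[2])
  # half-level bias makes the writer's internal truncation exact
  j <- (round(d * 2^k) + 0.5) / (2^32 - 1)
  planes <- lapply(seq_len(nplanes), function(i) {
    matrix(j[((i - 1) * nd[1] * nd[2] + 1):(i * nd[1] * nd[2])], nd[1], nd[2])
  })
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  sidecar <- list(pixel_size_um = img$pixel_size,
                  frame_interval_s = img$frame_interval,
                  axes = img$axes, dim = nd, level_exp = k, offset = offset,
                  channels = img$channels)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a calibrated image written by [write_cal_image()]
#'
#' Calibration is taken from the JSON sidecar, or from `pixel_size` /
#' `frame_interval` arguments when no sidecar exists. A missing calibration
#' is an error naming the missing field.
#'
#' @param path TIFF path.
#' @param pixel_size,frame_interval calibration overrides (µm/px, s).
#' @param axes axis string override.
#' @return a `cal_image`.
#' @export
read_cal_image <- function(path, pixel_size = NULL, frame_interval = NULL,
                           axes = NULL) {
  sidecar_path <- paste0(path, ".json")
  sc <- if (file.exists(sidecar_path)) jsonlite::read_json(sidecar_path, simplifyVector = TRUE) else NULL
  quantized <- !is.null(sc$level_exp)
  planes <- tiff::readTIFF(path, all = TRUE, as.is = quantized)
  if (!is.list(planes)) planes <- list(planes)
  px <- if (!is.null(pixel_size)) pixel_size else sc$pixel_size_um
  if (is.null(px)) stop("missing calibration field: pixel_size")
  fi <- if (!is.null(frame_interval)) frame_interval else sc$frame_interval_s
  if (is.null(fi) || is.character(fi)) fi <- NA_real_
  ax <- if (!is.null(axes)) axes else sc$axes
  d <- if (!is.null(sc$dim)) sc$dim else c(dim(planes[[1]]), if (length(planes) > 1) length(planes))
  offset <- if (!is.null(sc$offset)) sc$offset else 0
  arr <- array(as.numeric(unlist(planes, use.names = FALSE)), dim = d)
  if (quantized) arr <- arr / 2^sc$level_exp
  arr <- arr + offset
  if (is.null(ax)) ax <- switch(as.character(length(d)), "2" = "yx", "3" = "yxc", "4" = "yxct")
  ch <- if (!is.null(sc$channels) && length(sc$channels)) sc$channels else NULL
  cal_image(arr, px, fi, ax, channels = ch)
}
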