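#' Detection configuration for puncta segmentation
#'
#' Mirrors the standard confocal workflow: maximum projection, background
#' subtraction, manual threshold mask, light Gaussian blur for segmentation
#' only, maxima-seeded watershed splitting, and per-particle statistics on
#' the original (pre-blur, post-background) intensities via a min-mask
#' projection.
#'
#' @param background_method `"rolling_ball"` (grayscale opening with a disc
#'   of `background_radius` px, the de-facto standard) or `"percentile"`
#'   (subtract the `background_percentile` quantile) or `"none"`.
#' @param background_radius rolling-ball radius in px.
#' @param background_percentile percentile in `[0, 100]`.
#' @param blur_sigma segmentation blur sigma in px (default 0.5).
#' @param threshold `"otsu"` or a manual numeric threshold (AU, applied to
#'   background-subtracted intensities).
#' @param maxima_prominence minimum prominence for seed maxima, AU.
#' @param min_particle_area minimum particle area, px².
#' @return a `detection_config`.
#' @export
detection_config <- function(background_method = c("rolling_ball", "percentile", "none"),
                             background_radius = 50,
                             background_percentile = 25,
                             blur_sigma = 0.5,
                             threshold = "otsu",
                             maxima_prominence = 10,
                             min_particle_area = 4) {
  background_method <- match.arg(background_method)
  stopifnot(blur_sigma >= 0, min_particle_area >= 0, maxima_prominence >= 0)
  structure(list(background_method = background_method,
                 background_radius = background_radius,
                 background_percentile = background_percentile,
                 blur_sigma = blur_sigma, threshold = threshold,
                 maxima_prominence = maxima_prominence,
                 min_particle_area = min_particle_area),
            class = "detection_config")
}

#' Maximum projection of a z-stack
#'
#' @param stack a [cal_image()] with a `z` axis (axes `"yxz"`).
#' @param z_range integer slice indices to project (default all).
#' @return a 2D [cal_image()]; each pixel is the maximum over the selected
#'   slices. Calibration is preserved.
#' @export
project_stack <- function(stack, z_range = NULL) {
  stopifnot(inherits(stack, "cal_image"))
  ax <- strsplit(stack$axes, "")[[1]]
  if (!"z" %in% ax) {
    if (length(dim(stack$data)) == 2) return(stack)
    stop("stack has no z axis")
  }
  zdim <- which(ax == "z")
  nz <- dim(stack$data)[zdim]
  if (is.null(z_range)) z_range <- seq_len(nz)
  if (length(z_range) == 0) stop("empty z_range")
  if (any(z_range < 1 | z_range > nz)) stop("z_range outside stack depth")
  sub <- if (zdim == 3) stack$data[, , z_range, drop = FALSE]
         else stop("z axis must be the third axis")
  out <- apply(sub, c(1, 2), max)
  cal_image(out, stack$pixel_size, stack$frame_interval, "yx",
            channels = stack$channels)
}

subtract_background <- function(m, cfg) {
  switch(cfg$background_method,
         none = m,
         percentile = pmax(m - stats::quantile(m, cfg$background_percentile / 100,
                                               names = FALSE), 0),
         rolling_ball = {
           r <- min(cfg$background_radius, floor((min(dim(m)) - 1) / 2))
           brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
           bg <- EBImage::opening(EBImage::Image(m), brush)
           pmax(m - as.matrix(bg), 0)
         })
}

#' Segment fluorescent puncta and measure per-particle statistics
#'
#' Pipeline order is fixed: restrict to ROI, subtract background, build a
#' threshold mask from the (unblurred) intensities, blur a copy for
#' segmentation, find prominence-filtered local maxima inside the mask,
#' split touching particles by maxima-seeded watershed, then measure each
#' particle on the original pre-blur intensities (the binary mask projected
#' back by a per-pixel min).
#'
#' @param img 2D [cal_image()].
#' @param roi polygon [roi()] restricting the analysis, or `NULL` for the
#'   whole image.
#' @param cfg a [detection_config()].
#' @return a `particle_table`: data.frame with one row per particle
#'   (id, centroid in px and µm, `area_um2`, `integrated_density`,
#'   `mean_intensity`) plus attributes `reference_area_um2` (ROI area),
#'   `threshold`, `label_image` and `mask`.
#' @export
segment_particles <- function(img, roi = NULL, cfg = detection_config()) {
  stopifnot(inherits(img, "cal_image"))
  m <- if (length(dim(img$data)) == 2) img$data else
    stop("segment_particles expects a 2D image; project first")
  if (!is.null(roi)) {
    rmask <- roi_mask(roi, dim(m))
    if (!any(rmask)) stop("ROI is empty")
  } else rmask <- matrix(TRUE, nrow(m), ncol(m))
  work <- subtract_background(m, cfg)
  work[!rmask] <- 0
  thr <- if (identical(cfg$threshold, "otsu")) otsu_threshold(work[rmask])
         else as.numeric(cfg$threshold)
  mask <- work > thr & rmask
  px_area <- img$pixel_size^2
  empty <- data.frame(id = integer(0), x_px = numeric(0), y_px = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), integrated_density = numeric(0),
                      mean_intensity = numeric(0))
  if (!any(mask)) {
    return(structure(empty, class = c("particle_table", "data.frame"),
                     reference_area_um2 = sum(rmask) * px_area,
                     threshold = thr,
                     label_image = matrix(0L, nrow(m), ncol(m)),
                     mask = mask))
  }
  blurred <- blur_if(work, cfg$blur_sigma)
  seeds <- find_maxima(blurred, cfg$maxima_prominence, mask)
  if (max(seeds) == 0) {
    labels <- matrix(0L, nrow(m), ncol(m))
  } else {
    labels <- EBImage::imageData(EBImage::propagate(
      EBImage::Image(blurred), EBImage::Image(seeds), mask = mask))
    storage.mode(labels) <- "integer"
  }
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (length(ids) == 0) {
    return(structure(empty, class = c("particle_table", "data.frame"),
                     reference_area_um2 = sum(rmask) * px_area,
                     threshold = thr, label_image = labels, mask = mask))
  }
  # min-mask projection: statistics on pre-blur (post-background) intensities
  ny <- nrow(m)
  lin <- which(labels > 0)
  lab <- labels[lin]
  val <- work[lin]
  xs <- (lin - 1L) %/% ny
  ys <- (lin - 1L) %% ny
  area_px <- tapply(rep(1, length(lab)), lab, sum)
  intden <- tapply(val, lab, sum)
  cx <- tapply(val * xs, lab, sum) / pmax(intden, .Machine$double.eps)
  cy <- tapply(val * ys, lab, sum) / pmax(intden, .Machine$double.eps)
  keep <- area_px >= cfg$min_particle_area
  tab <- data.frame(id = seq_len(sum(keep)),
                    x_px = as.numeric(cx[keep]), y_px = as.numeric(cy[keep]),
                    x_um = as.numeric(cx[keep]) * img$pixel_size,
                    y_um = as.numeric(cy[keep]) * img$pixel_size,
                    area_um2 = as.numeric(area_px[keep]) * px_area,
                    integrated_density = as.numeric(intden[keep]),
                    mean_intensity = as.numeric(intden[keep] / area_px[keep]))
  # relabel the label image to match surviving ids
  old_ids <- as.integer(names(area_px))[keep]
  relab <- integer(max(labels))
  relab[old_ids] <- seq_along(old_ids)
  labels[labels > 0] <- relab[labels[labels > 0]]
  structure(tab, class = c("particle_table", "data.frame"),
            reference_area_um2 = sum(rmask) * px_area,
            threshold = thr, label_image = labels, mask = mask)
}

#' Field-level summary of a particle table
#'
#' Density is particle count per reference area; sum intensity per area is
#' the summed per-particle integrated densities divided by the reference
#' area (total protein estimate normalized for imaged tissue size). With a
#' control mean, each summary is also expressed as percent of control
#' (control group = 100%).
#'
#' @param table a `particle_table` from [segment_particles()].
#' @param reference_area reference area in µm² (default: the ROI area stored
#'   on the table).
#' @param control_mean optional named numeric vector of control means for
#'   any of the summary fields, e.g. `c(density = ..., sum_intensity_per_area = ...)`.
#' @return a one-row data.frame: `n_particles`, `reference_area_um2`,
#'   `density_per_um2`, `sum_intensity_per_area`, `mean_particle_area_um2`,
#'   `mean_intensity`; percent-of-control columns (`*_pct`) when a control
#'   mean is supplied.
#' @export
summarize_field <- function(table, reference_area = NULL, control_mean = NULL) {
  if (is.null(reference_area)) reference_area <- attr(table, "reference_area_um2")
  if (is.null(reference_area) || reference_area <= 0)
    stop("reference_area must be positive")
  out <- data.frame(
    n_particles = nrow(table),
    reference_area_um2 = reference_area,
    density_per_um2 = nrow(table) / reference_area,
    sum_intensity_per_area = sum(table$integrated_density) / reference_area,
    mean_particle_area_um2 = if (nrow(table)) mean(table$area_um2) else NA_real_,
    mean_intensity = if (nrow(table)) mean(table$mean_intensity) else NA_real_)
  if (!is.null(control_mean)) {
    for (nm in names(control_mean)) {
      if (control_mean[[nm]] == 0) stop("control mean for ", nm, " is zero")
      if (!nm %in% names(out)) stop("unknown summary field: ", nm)
      out[[paste0(nm, "_pct")]] <- 100 * out[[nm]] / control_mean[[nm]]
    }
  }
  out
}

#' Equivalent ring diameter from area
#'
#' Diameter of the circle with the given area: `d = 2 * sqrt(A / pi)`.
#' Used to express an active-zone ring ROI area as a diameter.
#'
#' @param area area(s) in µm².
#' @return diameter(s) in µm.
#' @export
ring_diameter <- function(area) {
  if (any(area < 0)) stop("area must be non-negative")
  2 * sqrt(area / pi)
}

#' Mean cytoplasmic intensity of a bouton excluding active zones
#'
#' Blurs a copy of the image (sigma 2.0 px by default), thresholds it
#' (default 30 AU) to find the bright active-zone regions inside the bouton
#' ROI, subtracts those regions from the ROI, and returns the mean original
#' intensity over the remaining (cytoplasmic) pixels.
#'
#' @param img 2D [cal_image()].
#' @param bouton_roi polygon [roi()] outlining the bouton.
#' @param blur_sigma Gaussian blur sigma, px.
#' @param az_threshold threshold on the blurred image, AU.
#' @return list: `mean_intensity` (AU, original image over cytoplasm),
#'   `excluded_fraction` (fraction of bouton area removed as active zone),
#'   `n_pixels` used.
#' @export
cytoplasmic_intensity <- function(img, bouton_roi, blur_sigma = 2.0,
                                  az_threshold = 30) {
  stopifnot(inherits(img, "cal_image"))
  m <- img$data
  rmask <- roi_mask(bouton_roi, dim(m))
  if (!any(rmask)) stop("bouton ROI is empty")
  blurred <- blur_if(m, blur_sigma)
  az <- blurred > az_threshold & rmask
  cyto <- rmask & !az
  if (!any(cyto)) stop("no cytoplasmic pixels: active zones cover the bouton")
  list(mean_intensity = mean(m[cyto]),
       excluded_fraction = sum(az) / sum(rmask),
       n_pixels = sum(cyto))
}
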