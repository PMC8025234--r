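#' Moment-ellipse shape measurements of labeled 2D regions
#'
#' Fits an ellipse to each labeled region from its second central moments
#' and reports the long and short diameters (major/minor ellipse axes) and
#' the elongation (long/short ratio, always >= 1). The moment ellipse is
#' robust to pixelation compared with Feret calipers; a caliper (Feret)
#' alternative is available via `method = "feret"`.
#'
#' @param label_image integer matrix of region labels (0 = background).
#' @param pixel_size physical pixel size (nm/px).
#' @param method `"moments"` (default) or `"feret"`.
#' @return data.frame with one row per label: `label`, `area_nm2`,
#'   `long_diameter_nm`, `short_diameter_nm`, `elongation`. Regions of
#'   fewer than 4 pixels are dropped with a warning.
#' @export
fit_shape <- function(label_image, pixel_size = 1,
                      method = c("moments", "feret")) {
  method <- match.arg(method)
  labs <- setdiff(sort(unique(as.vector(label_image))), 0L)
  ny <- nrow(label_image)
  out <- list()
  dropped <- 0L
  for (id in labs) {
    lin <- which(label_image == id)
    if (length(lin) < 4) { dropped <- dropped + 1L; next }
    xs <- (lin - 1L) %/% ny
    ys <- (lin - 1L) %% ny
    if (method == "moments") {
      mx <- mean(xs); my <- mean(ys)
      # + 1/12: variance of the uniform pixel footprint
      cxx <- mean((xs - mx)^2) + 1 / 12
      cyy <- mean((ys - my)^2) + 1 / 12
      cxy <- mean((xs - mx) * (ys - my))
      tr <- cxx + cyy
      det_ <- cxx * cyy - cxy^2
      l1 <- tr / 2 + sqrt(pmax(tr^2 / 4 - det_, 0))
      l2 <- tr / 2 - sqrt(pmax(tr^2 / 4 - det_, 0))
      long_d <- 4 * sqrt(l1) * pixel_size
      short_d <- 4 * sqrt(pmax(l2, 0)) * pixel_size
    } else {
      # Feret: extreme caliper distances over rotations
      angs <- seq(0, pi, length.out = 181)[-181]
      wids <- vapply(angs, function(a) {
        p <- xs * cos(a) + ys * sin(a)
        diff(range(p)) + 1
      }, numeric(1))
      long_d <- max(wids) * pixel_size
      short_d <- min(wids) * pixel_size
    }
    out[[length(out) + 1]] <- data.frame(
      label = id, area_nm2 = length(lin) * pixel_size^2,
      long_diameter_nm = long_d, short_diameter_nm = short_d,
      elongation = long_d / short_d)
  }
  if (dropped > 0) warning(dropped, " region(s) of < 4 px rejected")
  if (length(out)) do.call(rbind, out)
  else data.frame(label = integer(0), area_nm2 = numeric(0),
                  long_diameter_nm = numeric(0), short_diameter_nm = numeric(0),
                  elongation = numeric(0))
}

#' Stereological volume fraction (Delesse principle)
#'
#' The areal fraction of labeled objects within a reference region on a
#' random section is an unbiased estimator of the objects' volume fraction.
#'
#' @param label_image integer label matrix (0 = background).
#' @param region_mask logical matrix delimiting the reference region;
#'   default: the whole image.
#' @param pixel_size physical pixel size (nm/px).
#' @return list with `volume_fraction`, `reference_area_nm2`,
#'   `object_area_sum_nm2`.
#' @export
volume_fraction <- function(label_image, region_mask = NULL, pixel_size = 1) {
  if (is.null(region_mask))
    region_mask <- matrix(TRUE, nrow(label_image), ncol(label_image))
  if (!any(region_mask)) stop("empty reference region")
  nref <- sum(region_mask)
  nobj <- sum(label_image > 0 & region_mask)
  list(volume_fraction = nobj / nref,
       reference_area_nm2 = nref * pixel_size^2,
       object_area_sum_nm2 = nobj * pixel_size^2)
}

#' Volume and surface area of labeled 3D objects
#'
#' Volume is the voxel count times the voxel volume. Surface area is
#' estimated from the isosurface of each label: the binary indicator is
#' mollified with a small Gaussian (sigma 1 voxel) and the surface obtained
#' as the integral of the gradient magnitude (coarea formula), which is
#' accurate to about 1% for smooth convex shapes at the voxel sizes used
#' here. Labels touching the volume boundary are flagged `clipped`.
#'
#' @param label_volume integer 3D array of labels (0 = background).
#' @param voxel_size isotropic voxel edge length (nm).
#' @return data.frame per label: `label`, `volume_nm3`, `surface_area_nm2`,
#'   `clipped`.
#' @export
volume_surface_3d <- function(label_volume, voxel_size = 1) {
  stopifnot(length(dim(label_volume)) == 3)
  labs <- setdiff(sort(unique(as.vector(label_volume))), 0L)
  d <- dim(label_volume)
  out <- lapply(labs, function(id) {
    sel <- label_volume == id
    idx <- which(sel, arr.ind = TRUE)
    clipped <- any(idx == 1) || any(sweep(idx, 2, d, `==`))
    # crop with margin for the mollified gradient
    lo <- pmax(apply(idx, 2, min) - 5L, 1L)
    hi <- pmin(apply(idx, 2, max) + 5L, d)
    sub <- array(0, hi - lo + 1L)
    sub[cbind(idx[, 1] - lo[1] + 1L, idx[, 2] - lo[2] + 1L, idx[, 3] - lo[3] + 1L)] <- 1
    f <- gauss_smooth_3d(sub, sigma = 1)
    n <- dim(f)
    gx <- (f[c(2:n[1], n[1]), , ] - f[c(1, 1:(n[1] - 1)), , ]) / 2
    gy <- (f[, c(2:n[2], n[2]), ] - f[, c(1, 1:(n[2] - 1)), ]) / 2
    gz <- (f[, , c(2:n[3], n[3])] - f[, , c(1, 1:(n[3] - 1))]) / 2
    surf <- sum(sqrt(gx^2 + gy^2 + gz^2)) * voxel_size^2
    data.frame(label = id, volume_nm3 = sum(sel) * voxel_size^3,
               surface_area_nm2 = surf, clipped = clipped)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Separable 3D Gaussian smoothing with border replication.
gauss_smooth_3d <- function(a, sigma = 1) {
  half <- ceiling(3 * sigma)
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  conv_axis <- function(a, axis) {
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
    ap <- aperm(a, perm)
    dd <- dim(ap)
    m <- matrix(ap, nrow = dd[1])
    mp <- rbind(m[rep(1, half), , drop = FALSE], m,
                m[rep(dd[1], half), , drop = FALSE])
    out <- apply(mp, 2, function(col) stats::filter(col, k, sides = 2))
    out <- out[(half + 1):(half + dd[1]), , drop = FALSE]
    aperm(array(out, dd), perm)
  }
  conv_axis(conv_axis(conv_axis(a, 1), 2), 3)
}

#' T-bar geometry from manual annotations
#'
#' Converts a roof polyline, a pedestal polyline and an area polygon
#' (pixel coordinates) to physical lengths and area. The roof length is
#' the length of the straight/segmented line connecting the furthest
#' extent of the dense material; the area uses the shoelace formula.
#'
#' @param roof_line,pedestal_line [roi()] polylines or point matrices (px);
#'   either may be `NULL`.
#' @param area_roi [roi()] polygon or vertex matrix (px), or `NULL`.
#' @param pixel_size nm per pixel.
#' @return list with `roof_length_nm`, `pedestal_length_nm`, `area_nm2`
#'   (NA for missing annotations).
#' @export
tbar_metrics <- function(roof_line = NULL, pedestal_line = NULL,
                         area_roi = NULL, pixel_size = 1) {
  list(
    roof_length_nm = if (is.null(roof_line)) NA_real_
                     else polyline_length(roof_line, pixel_size),
    pedestal_length_nm = if (is.null(pedestal_line)) NA_real_
                         else polyline_length(pedestal_line, pixel_size),
    area_nm2 = if (is.null(area_roi)) NA_real_
               else polygon_area(area_roi, pixel_size))
}
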