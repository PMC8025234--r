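#' Regions of interest
#'
#' ROIs are polygons (closed), lines or segmented polylines with an optional
#' width, in 0-based pixel coordinates (pixel centers at integers). They are
#' interchanged as small JSON documents with fields `type`, `points`
#' (list of `[x, y]` pairs) and optional `width`.
#'
#' @param type one of `"polygon"`, `"line"`, `"polyline"`.
#' @param points numeric matrix or data.frame with columns x, y (px).
#' @param width line width in pixels (line/polyline only).
#' @return an object of class `roi`.
#' @export
roi <- function(type = c("polygon", "line", "polyline"), points, width = 1) {
  type <- match.arg(type)
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("points must be an n x 2 matrix of (x, y)")
  if (type == "polygon" && nrow(points) < 3) stop("polygon needs >= 3 points")
  if (type != "polygon" && nrow(points) < 2) stop("line needs >= 2 points")
  colnames(points) <- c("x", "y")
  structure(list(type = type, points = points, width = width), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat("<roi> ", x$type, ", ", nrow(x$points), " points", sep = "")
  if (x$type != "polygon") cat(", width ", x$width, " px", sep = "")
  cat("\n")
  invisible(x)
}

#' Read / write an ROI JSON file
#' @param path JSON file path.
#' @return [read_roi()] returns an `roi`; [write_roi()] returns `path`.
#' @export
read_roi <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi(j$type, matrix(unlist(j$points), ncol = 2, byrow = !is.matrix(j$points)),
      width = if (!is.null(j$width)) j$width else 1)
}

#' @rdname read_roi
#' @param x an `roi` object.
#' @export
write_roi <- function(x, path) {
  stopifnot(inherits(x, "roi"))
  jsonlite::write_json(list(type = x$type,
                            points = unname(apply(x$points, 1, as.numeric, simplify = FALSE)),
                            width = x$width),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize a polygon ROI to a logical pixel mask
#'
#' A pixel belongs to the mask when its center (integer coordinates, 0-based)
#' lies inside the polygon by the even-odd rule. Points exactly on an edge
#' are treated as inside.
#'
#' @param x an `roi` of type `"polygon"`, or an n x 2 vertex matrix.
#' @param dim image dimensions `c(ny, nx)` (matrix rows are y).
#' @return logical matrix of size `dim`.
#' @export
roi_mask <- function(x, dim) {
  pts <- if (inherits(x, "roi")) {
    if (x$type != "polygon") stop("roi_mask needs a polygon ROI")
    x$points
  } else as.matrix(x)
  ny <- dim[1]; nx <- dim[2]
  xs <- rep(0:(nx - 1), each = ny)
  ys <- rep(0:(ny - 1), times = nx)
  inside <- point_in_polygon(xs, ys, pts[, 1], pts[, 2])
  matrix(inside, ny, nx)
}

# Vectorized even-odd point-in-polygon with on-edge points counted inside.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  onedge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    # on-segment test
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      tt <- pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2))
      d2 <- (xi + tt * dx - px)^2 + (yi + tt * dy - py)^2
      onedge <- onedge | d2 < 1e-18
    } else {
      onedge <- onedge | ((px - xi)^2 + (py - yi)^2 < 1e-18)
    }
    j <- i
  }
  inside | onedge
}

#' Length of a polyline in physical units
#'
#' @param x an `roi` of type line/polyline, or an n x 2 point matrix (px).
#' @param pixel_size physical size of a pixel (any unit).
#' @return total path length in `pixel_size` units.
#' @export
polyline_length <- function(x, pixel_size = 1) {
  pts <- if (inherits(x, "roi")) x$points else as.matrix(x)
  segs <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  sum(segs) * pixel_size
}

#' Area of a simple polygon (shoelace formula)
#'
#' @param x an `roi` polygon or vertex matrix (px).
#' @param pixel_size physical pixel size; area is scaled by `pixel_size^2`.
#' @return polygon area in squared `pixel_size` units.
#' @export
polygon_area <- function(x, pixel_size = 1) {
  pts <- if (inherits(x, "roi")) x$points else as.matrix(x)
  if (polygon_self_intersects(pts)) stop("self-intersecting polygon")
  xs <- pts[, 1]; ys <- pts[, 2]
  n <- nrow(pts)
  j <- c(2:n, 1)
  abs(sum(xs * ys[j] - xs[j] * ys)) / 2 * pixel_size^2
}

# Checks non-adjacent edge pairs for proper intersection.
polygon_self_intersects <- function(pts) {
  n <- nrow(pts)
  if (n < 4) return(FALSE)
  seg <- cbind(pts, pts[c(2:n, 1), ])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(i - j) <= 1 || (i == 1 && j == n)) next
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross(p[1], p[2], p[3], p[4], q[1], q[2])
      d2 <- cross(p[1], p[2], p[3], p[4], q[3], q[4])
      d3 <- cross(q[1], q[2], q[3], q[4], p[1], p[2])
      d4 <- cross(q[1], q[2], q[3], q[4], p[3], p[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}
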