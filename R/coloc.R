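#' Thresholded Pearson correlation with a flipped-channel control
#'
#' Computes the Pearson correlation of two channels over ROI pixels where at
#' least one channel exceeds its threshold ("Pearson's R above threshold"),
#' and repeats the measurement after mirroring the second channel
#' left-right within the ROI bounding box. The flipped value estimates the
#' chance (stochastic) colocalization level for structures of this size and
#' density; specific colocalization shows as `r_data` well above
#' `r_flipped`.
#'
#' @param ch1,ch2 2D [cal_image()]s or numeric matrices of equal size.
#' @param roi polygon [roi()], or `NULL` for the full frame.
#' @param thr1,thr2 per-channel thresholds (AU); default per-channel Otsu
#'   inside the ROI.
#' @param qualifying `"and"` (default; a pixel is used when both channels
#'   exceed their thresholds) or `"or"`. The AND rule keeps the correlation
#'   centered on zero for spatially independent channels; the OR rule admits
#'   bright-in-one/background-in-the-other pixels and biases the null
#'   negative for sparse high-contrast structures.
#' @return a `coloc_result`: list with `r_data`, `r_flipped`,
#'   `n_pixels_used`, `n_pixels_flipped`, `thr1`, `thr2`.
#' @export
pearson_above_threshold <- function(ch1, ch2, roi = NULL, thr1 = NULL,
                                    thr2 = NULL, qualifying = c("and", "or")) {
  qualifying <- match.arg(qualifying)
  m1 <- if (inherits(ch1, "cal_image")) ch1$data else as.matrix(ch1)
  m2 <- if (inherits(ch2, "cal_image")) ch2$data else as.matrix(ch2)
  if (!identical(dim(m1), dim(m2))) stop("channels must have the same shape")
  rmask <- if (is.null(roi)) matrix(TRUE, nrow(m1), ncol(m1))
           else roi_mask(roi, dim(m1))
  if (!any(rmask)) stop("ROI is empty")
  if (is.null(thr1)) thr1 <- otsu_threshold(m1[rmask])
  if (is.null(thr2)) thr2 <- otsu_threshold(m2[rmask])
  r_of <- function(a, b, valid) {
    qual <- if (qualifying == "or") (a > thr1 | b > thr2) else (a > thr1 & b > thr2)
    use <- valid & qual
    if (sum(use) < 2) stop("undefined correlation: fewer than 2 qualifying pixels")
    x <- a[use]; y <- b[use]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("undefined correlation: zero variance above threshold")
    stats::cor(x, y)
  }
  r_data <- r_of(m1, m2, rmask)
  # flip ch2 (and the roi membership it carries) horizontally in the roi bbox
  cols <- range(which(colSums(rmask) > 0))
  flip <- function(m) { m[, cols[1]:cols[2]] <- m[, cols[2]:cols[1]]; m }
  m2f <- flip(m2)
  rmaskf <- flip(rmask)
  n_used <- function(a, b, valid) {
    qual <- if (qualifying == "or") (a > thr1 | b > thr2) else (a > thr1 & b > thr2)
    sum(valid & qual)
  }
  r_flipped <- r_of(m1, m2f, rmask & rmaskf)
  structure(list(r_data = r_data, r_flipped = r_flipped,
                 n_pixels_used = n_used(m1, m2, rmask),
                 n_pixels_flipped = n_used(m1, m2f, rmask & rmaskf),
                 thr1 = thr1, thr2 = thr2),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> r = %.4f (flipped control %.4f), %d px used\n",
              x$r_data, x$r_flipped, x$n_pixels_used))
  invisible(x)
}

#' Area overlap between two binary masks
#'
#' The intersection (logical AND of the two masks) expressed as a percent of
#' each mask, plus the percent of mask B outside A (the "only"-positive
#' area, obtained by subtracting the copositive area from B's total area).
#'
#' @param maskA,maskB logical matrices of equal size.
#' @return list with `pct_A_overlap` (= 100 |A∩B|/|A|), `pct_B_overlap`
#'   (= 100 |A∩B|/|B|) and `pct_B_only` (= 100 |B∖A|/|B|).
#' @export
area_overlap <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB))) stop("masks must have the same shape")
  a <- sum(maskA); b <- sum(maskB)
  if (a == 0 || b == 0) stop("empty mask in denominator")
  ab <- sum(maskA & maskB)
  list(pct_A_overlap = 100 * ab / a,
       pct_B_overlap = 100 * ab / b,
       pct_B_only = 100 * (b - ab) / b)
}
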