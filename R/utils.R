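# Internal numerical helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded from `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Otsu threshold on a numeric vector (256-bin histogram between data range).
otsu_threshold <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(nbins, 1L + floor((v - rng[1]) / diff(rng) * nbins)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  rng[1] + k / nbins * diff(rng)
}

# Bilinear interpolation of matrix `m` (rows = y) at 0-based continuous
# pixel coordinates. Out-of-range coordinates are clamped to the border.
bilinear <- function(m, x, y) {
  ny <- nrow(m); nx <- ncol(m)
  x <- pmin(pmax(x, 0), nx - 1)
  y <- pmin(pmax(y, 0), ny - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, nx - 1); y1 <- pmin(y0 + 1, ny - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + 1 + x0 * ny; i10 <- y1 + 1 + x0 * ny
  i01 <- y0 + 1 + x1 * ny; i11 <- y1 + 1 + x1 * ny
  m[i00] * (1 - fx) * (1 - fy) + m[i10] * (1 - fx) * fy +
    m[i01] * fx * (1 - fy) + m[i11] * fx * fy
}

# Gaussian blur that tolerates sigma = 0 (identity).
blur_if <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

#' Local maxima with prominence (noise tolerance)
#'
#' Detects local intensity maxima whose topographic prominence is at least
#' `prominence`, the same notion as the noise tolerance of the classical
#' "find maxima" operation: a peak survives if one must descend by at least
#' `prominence` below its height before reaching any higher pixel. Peaks are
#' found by a descending flood with union-find; the highest peak of each
#' connected region is always kept. 8-connectivity.
#'
#' @param img numeric matrix.
#' @param prominence minimum prominence (image intensity units).
#' @param mask optional logical matrix restricting the search domain.
#' @return integer matrix of seed labels (0 = background), one label per
#'   accepted maximum, positioned at the peak pixel; attribute `"peaks"`
#'   holds a data.frame of peak coordinates (0-based x, y) and heights.
#' @export
find_maxima <- function(img, prominence, mask = NULL) {
  ny <- nrow(img); nx <- ncol(img)
  if (is.null(mask)) mask <- matrix(TRUE, ny, nx)
  idx <- which(mask)
  out <- matrix(0L, ny, nx)
  if (length(idx) == 0) {
    attr(out, "peaks") <- data.frame(x = numeric(0), y = numeric(0), height = numeric(0))
    return(out)
  }
  ord <- idx[order(img[idx], decreasing = TRUE)]
  # union-find over mask pixels; each basin tracks its peak pixel
  parent <- integer(ny * nx)      # 0 = unassigned
  peak_of <- integer(ny * nx)     # root -> peak linear index
  alive <- logical(ny * nx)       # peak not yet merged away
  inmask <- logical(ny * nx); inmask[idx] <- TRUE
  accepted <- integer(length(idx)); n_acc <- 0L
  for (p in ord) {
    parent[p] <- p; peak_of[p] <- p; alive[p] <- TRUE
    y <- (p - 1L) %% ny   # 0-based row
    up_ok <- y > 0L; dn_ok <- y < ny - 1L
    for (q in c(if (up_ok) p - 1L, if (dn_ok) p + 1L,
                p - ny, p + ny,
                if (up_ok) c(p - ny - 1L, p + ny - 1L),
                if (dn_ok) c(p - ny + 1L, p + ny + 1L))) {
      if (q < 1L || q > ny * nx) next
      if (parent[q] == 0L || !inmask[q]) next
      rp <- p
      while (parent[rp] != rp) { parent[rp] <- parent[parent[rp]]; rp <- parent[rp] }
      rq <- q
      while (parent[rq] != rq) { parent[rq] <- parent[parent[rq]]; rq <- parent[rq] }
      if (rp == rq) next
      # merge: the lower of the two basin peaks dies at the current level
      pk_p <- peak_of[rp]; pk_q <- peak_of[rq]
      hi <- if (img[pk_p] >= img[pk_q]) pk_p else pk_q
      lo <- if (img[pk_p] >= img[pk_q]) pk_q else pk_p
      if (alive[lo]) {
        if (img[lo] - img[p] >= prominence && lo != hi) {
          n_acc <- n_acc + 1L
          accepted[n_acc] <- lo
        }
        alive[lo] <- FALSE
      }
      parent[rq] <- rp
      peak_of[rp] <- hi
    }
  }
  # surviving basin peaks (one per connected component) are always accepted
  roots <- idx
  repeat {
    nxt <- parent[roots]
    if (all(nxt == roots)) break
    roots <- nxt
  }
  accepted <- unique(c(accepted[seq_len(n_acc)], peak_of[unique(roots)]))
  accepted <- accepted[accepted > 0]
  out[accepted] <- seq_along(accepted)
  attr(out, "peaks") <- data.frame(
    x = ((accepted - 1L) %/% ny),
    y = ((accepted - 1L) %% ny),
    height = img[accepted])
  out
}

# trapezoidal integral of y over x
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

local_maxima_1d <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}
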