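# Internal array helpers shared across the pipeline. All image data are plain
# R matrices indexed [row, col], 1-based, pixel centers at integer coordinates.

# Shift a matrix by (dr, dc); vacated cells are filled with `fill` or, when
# fill = "edge", with replicated border values.
shift_mat <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- seq_len(nr) - dr
  ci <- seq_len(nc) - dc
  if (identical(fill, "edge")) {
    ri <- pmin(pmax(ri, 1L), nr)
    ci <- pmin(pmax(ci, 1L), nc)
    return(m[ri, ci, drop = FALSE])
  }
  out <- matrix(fill, nr, nc)
  rok <- ri >= 1L & ri <= nr
  cok <- ci >= 1L & ci <= nc
  out[rok, cok] <- m[ri[rok], ci[cok], drop = FALSE]
  out
}

gaussian_kernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing with replicated (clamped) borders.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  acc <- matrix(0, nrow(m), ncol(m))
  for (s in seq(-r, r)) acc <- acc + k[s + r + 1L] * shift_mat(m, s, 0, fill = "edge")
  out <- matrix(0, nrow(m), ncol(m))
  for (s in seq(-r, r)) out <- out + k[s + r + 1L] * shift_mat(acc, 0, s, fill = "edge")
  out
}

# Mean over each pixel's in-domain 3x3 patch (pixel itself included).
# `domain` is a logical matrix; out-of-domain pixels contribute nothing.
local_mean3 <- function(m, domain = NULL) {
  if (is.null(domain)) domain <- matrix(TRUE, nrow(m), ncol(m))
  vals <- m
  vals[!domain] <- 0
  num <- matrix(0, nrow(m), ncol(m))
  den <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) {
    for (dc in -1:1) {
      num <- num + shift_mat(vals, dr, dc, fill = 0)
      den <- den + shift_mat(domain * 1, dr, dc, fill = 0)
    }
  }
  out <- num / pmax(den, 1)
  out[den == 0] <- NA_real_
  out
}

# Even-odd (ray casting) point-in-polygon test, vectorized over query points.
# poly: matrix with columns (row, col) of polygon vertices in order.
points_in_polygon <- function(pr, pc, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    crosses <- ((yi > pr) != (yj > pr)) &
      (pc < (xj - xi) * (pr - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Fill the convex hull of a set of pixels (given as logical matrix) on the
# same grid; returns logical matrix.
fill_convex_hull <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3L) return(mask)
  h <- grDevices::chull(idx[, 2], idx[, 1])   # chull takes (x, y)
  poly <- idx[h, , drop = FALSE]
  cand <- which(!mask, arr.ind = TRUE)
  if (nrow(cand) > 0L) {
    inside <- points_in_polygon(cand[, 1], cand[, 2], poly)
    mask[cand[inside, , drop = FALSE]] <- TRUE
  }
  mask
}

round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
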