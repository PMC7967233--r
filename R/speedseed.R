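# Construction of the fast-marching inputs: edge-preserving denoising,
# pleural padding, smoothed gradient magnitude, the exponential speed image
# F = exp(tau * |grad|), and the gradient-filtered seed grid.

#' Edge-preserving denoising (Perona-Malik anisotropic diffusion)
#'
#' Smooths homogeneous regions while leaving strong edges in place, using
#' the exponential conductance g(|grad|) = exp(-(|grad|/kappa)^2). Intended
#' for normalized intensities in \[0, 1\].
#'
#' @param img a [nodule_image] or a plain numeric matrix in \[0, 1\].
#' @param kappa conductance scale in normalized-intensity units; gradients
#'   well above `kappa` are treated as edges and diffuse slowly. Default 0.05.
#' @param iters number of explicit diffusion steps (default 10).
#' @param dt time step; must be <= 0.25 for stability of the 4-neighbor
#'   explicit scheme. Default 0.15.
#' @return A numeric matrix of the same shape.
#' @export
denoise <- function(img, kappa = 0.05, iters = 10, dt = 0.15) {
  u <- if (inherits(img, "nodule_image")) img$intensity else as.matrix(img)
  for (it in seq_len(iters)) {
    dN <- shift_mat(u, -1, 0, fill = "edge") - u
    dS <- shift_mat(u, 1, 0, fill = "edge") - u
    dW <- shift_mat(u, 0, -1, fill = "edge") - u
    dE <- shift_mat(u, 0, 1, fill = "edge") - u
    g <- function(d) exp(-(d / kappa)^2)
    u <- u + dt * (g(dN) * dN + g(dS) * dS + g(dW) * dW + g(dE) * dE)
  }
  u
}

#' Null the pleural boundary before gradient computation
#'
#' Lung segmentation removes the chest wall, which would otherwise leave a
#' sharp artificial step at the mask boundary and a spurious ridge in the
#' gradient (fatal for juxtapleural nodules). Every pixel outside the lung
#' mask is replaced by the value of its nearest inside pixel, so the mask
#' boundary contributes (near-)zero gradient while lung content is untouched.
#'
#' @param arr numeric matrix (typically the denoised crop).
#' @param mask logical lung mask; `NULL` means no pleura was removed and the
#'   input is returned unchanged.
#' @return Numeric matrix of the same shape.
#' @export
pad_pleura <- function(arr, mask = NULL) {
  arr <- as.matrix(arr)
  if (is.null(mask)) return(arr)
  mask <- matrix(as.logical(mask), nrow(arr), ncol(arr))
  if (!any(mask)) stop("no lung region: the lung mask is empty", call. = FALSE)
  filled <- mask
  out <- arr
  out[!mask] <- NA_real_
  # grassfire fill: each pass copies values one 8-connected shell outward;
  # earlier offsets in the list win, making the fill deterministic
  offsets <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                  c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  while (!all(filled)) {
    newly <- matrix(FALSE, nrow(arr), ncol(arr))
    vals <- matrix(NA_real_, nrow(arr), ncol(arr))
    for (o in offsets) {
      src_ok <- shift_mat(filled, o[1], o[2], fill = FALSE)
      take <- !filled & !newly & src_ok
      if (any(take)) {
        vals[take] <- shift_mat(out, o[1], o[2], fill = NA)[take]
        newly <- newly | take
      }
    }
    if (!any(newly)) break
    out[newly] <- vals[newly]
    filled <- filled | newly
  }
  out
}

#' Gaussian-smoothed gradient magnitude
#'
#' Convolves with a Gaussian of standard deviation `sigma` and takes the
#' central-difference gradient magnitude. The mean of the magnitude over the
#' valid domain (the lung mask when present, otherwise the whole image) is
#' the `total_grad_mean` used by the seed-grid rules.
#'
#' @param arr numeric matrix.
#' @param sigma Gaussian standard deviation in px (> 0, default 1).
#' @param mask optional logical domain for `total_grad_mean`.
#' @return An object of class `gradient_field`: list with `G` (magnitude
#'   matrix), `total_grad_mean`, and the `mask` used.
#' @export
gradient_magnitude <- function(arr, sigma = 1, mask = NULL) {
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  sm <- gaussian_blur(as.matrix(arr), sigma)
  gr <- pracma::gradient(sm)   # $X: d/dcol, $Y: d/drow (central differences)
  G <- sqrt(gr$X^2 + gr$Y^2)
  dom <- if (is.null(mask)) rep(TRUE, length(G)) else as.logical(mask)
  structure(list(G = G, total_grad_mean = mean(G[dom]), mask = mask),
            class = "gradient_field")
}

#' Exponential speed image
#'
#' F = exp(tau * G) with tau < 0, renormalized by its maximum so the fastest
#' pixel has speed exactly 1. Speeds are near zero across strong boundaries
#' and near one inside homogeneous tissue, which is what makes the front
#' stall at object borders.
#'
#' @param grad a `gradient_field` from [gradient_magnitude()], or a plain
#'   non-negative matrix of gradient magnitudes.
#' @param tau negative exponent (default -2).
#' @return An object of class `speed_image`: list with matrix `F` in (0, 1].
#' @export
speed_from_gradient <- function(grad, tau = -2) {
  if (tau >= 0) stop("`tau` must be negative", call. = FALSE)
  G <- if (inherits(grad, "gradient_field")) grad$G else as.matrix(grad)
  F <- exp(tau * G)
  F <- F / max(F)
  structure(list(F = F, tau = tau), class = "speed_image")
}

# Mean of the gradient over the in-domain 3x3 patch around each pixel.
local_grad_means <- function(G, domain) local_mean3(G, domain)

#' Generate the filtered seed grid
#'
#' Starts from an equidistant lattice with pitch `seed_distance` restricted
#' to the lung mask and filters each seed by the mean gradient over its
#' in-domain 3x3 neighborhood (`local`), compared against the image-wide
#' mean (`total`):
#' \itemize{
#'   \item delete when `local > beta * total` (seed sits on an edge);
#'   \item shift when `alpha * total <= local <= beta * total`: the seed
#'     moves to the 3x3 candidate (diagonals included) with the smallest
#'     local mean, the seed itself winning ties, then raster order;
#'   \item keep when `local < alpha * total` (area already uniform).
#' }
#' Shifted seeds may coincide; duplicates are removed and the final set is
#' returned in raster order.
#'
#' @param grad a `gradient_field`.
#' @param mask optional logical lung mask; lattice points outside it are
#'   skipped and shifts may not leave it.
#' @param seed_distance lattice pitch in px (>= 3, default 3: the densest
#'   grid whose 3x3 local areas do not overlap seeds).
#' @param alpha,beta rule thresholds (defaults 1 and 2, `alpha <= beta`).
#' @return An object of class `seed_grid`: list with integer matrix `seeds`
#'   (columns row, col), and the parameters used.
#' @export
generate_seed_grid <- function(grad, mask = NULL, seed_distance = 3,
                               alpha = 1, beta = 2) {
  stopifnot(inherits(grad, "gradient_field"))
  if (seed_distance < 3) stop("`seed_distance` must be >= 3", call. = FALSE)
  if (alpha > beta) stop("`alpha` must be <= `beta`", call. = FALSE)
  G <- grad$G
  nr <- nrow(G); nc <- ncol(G)
  domain <- if (is.null(mask)) matrix(TRUE, nr, nc) else
    matrix(as.logical(mask), nr, nc)
  total <- grad$total_grad_mean
  loc <- local_grad_means(G, domain)

  sd_ <- as.integer(seed_distance)
  start <- (sd_ + 1L) %/% 2L          # centers the lattice pitch
  rows <- seq.int(start, nr, by = sd_)
  cols <- seq.int(start, nc, by = sd_)
  lattice <- as.matrix(expand.grid(row = rows, col = cols))
  lattice <- lattice[order(lattice[, 1], lattice[, 2]), , drop = FALSE]
  keep_pt <- domain[lattice]
  lattice <- lattice[keep_pt, , drop = FALSE]

  out <- matrix(integer(0), 0, 2)
  for (i in seq_len(nrow(lattice))) {
    r <- lattice[i, 1]; c <- lattice[i, 2]
    lg <- loc[r, c]
    if (is.na(lg) || lg > beta * total) next            # rule 1: delete
    if (lg < alpha * total) {                           # rule 3: keep
      out <- rbind(out, c(r, c))
      next
    }
    # rule 2: shift to the in-domain 3x3 candidate with minimum local mean;
    # candidates in raster order with the seed itself first (tie winner)
    nb <- as.matrix(expand.grid(cc = (c - 1):(c + 1), rr = (r - 1):(r + 1)))
    cand <- rbind(c(r, c), nb[, c("rr", "cc")])        # self first, then raster
    cand <- cand[!(duplicated(cand)), , drop = FALSE]
    ok <- cand[, 1] >= 1 & cand[, 1] <= nr & cand[, 2] >= 1 & cand[, 2] <= nc
    cand <- cand[ok, , drop = FALSE]
    cand <- cand[domain[cand], , drop = FALSE]
    lvals <- loc[cand]
    best <- cand[which.min(lvals), ]                    # first minimum wins
    out <- rbind(out, best)
  }
  if (nrow(out) == 0L)
    stop("no uniform region for seeding: every lattice seed was deleted",
         call. = FALSE)
  out <- out[!duplicated(out), , drop = FALSE]
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  dimnames(out) <- list(NULL, c("row", "col"))
  structure(list(seeds = out, seed_distance = sd_, alpha = alpha, beta = beta),
            class = "seed_grid")
}
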