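# R surface of the multi-label fast marching solver. The marching loop
# itself is compiled (src/fmm.cpp); this file exposes the closed-form
# trial-time update, initialization, and the full partition with per-region
# statistics.

#' Upwind trial-time update
#'
#' Solves the first-order Godunov discretization of |grad T| F = 1 at one
#' pixel, given the smaller known arrival time on each grid axis. With
#' `a = min(T_left, T_right)` and `b = min(T_up, T_down)`: when
#' `|a - b| >= h/F` the quadratic has no causal 2D root and the 1D update
#' `min(a, b) + h/F` applies; otherwise the larger root of
#' `(T - a)^2 + (T - b)^2 = (h/F)^2` is returned.
#'
#' @param a,b smaller neighbor arrival time along the horizontal and
#'   vertical axis; `Inf` when no known neighbor exists on that axis. At
#'   least one must be finite.
#' @param f front speed at the pixel, > 0.
#' @param h grid step (default 1 pixel).
#' @return The trial arrival time (always >= the neighbor times used).
#' @export
solve_trial_time <- function(a, b, f, h = 1) {
  if (!is.finite(f) || f <= 0) stop("speed must be strictly positive", call. = FALSE)
  lo <- min(a, b); hi <- max(a, b)
  if (!is.finite(lo)) stop("at least one neighbor time must be finite", call. = FALSE)
  hf <- h / f
  if (!is.finite(hi) || hi - lo >= hf) return(lo + hf)
  ((a + b) + sqrt(2 * hf^2 - (a - b)^2)) / 2
}

check_speed_seeds <- function(speed, seeds, domain) {
  F <- if (inherits(speed, "speed_image")) speed$F else as.matrix(speed)
  S <- if (inherits(seeds, "seed_grid")) seeds$seeds else
    matrix(as.integer(seeds), ncol = 2)
  if (nrow(S) == 0L) stop("at least one seed is required", call. = FALSE)
  if (is.null(domain)) domain <- matrix(TRUE, nrow(F), ncol(F))
  storage.mode(S) <- "integer"
  list(F = F, S = S, domain = matrix(as.logical(domain), nrow(F), ncol(F)))
}

#' Initialize the fast-marching state
#'
#' Seeds become KNOWN with arrival time 0 and their own label (the seed's
#' index in raster order); their in-domain 4-neighbors enter the narrow band
#' with trial time 1/F and the adjacent seed's label (the smaller time wins
#' when several seeds touch the same pixel; exact ties go to the lower seed
#' index). Everything else is FAR with infinite time and no label.
#'
#' @param speed a `speed_image` (or matrix of positive speeds).
#' @param seeds a `seed_grid` (or 2-column integer matrix of (row, col)).
#' @param domain optional logical matrix; pixels outside it are excluded
#'   from marching entirely.
#' @return A list with `T`, `R` (0 = unassigned), and `status`
#'   (0 FAR, 1 narrow band, 2 KNOWN).
#' @export
fmm_initialize <- function(speed, seeds, domain = NULL) {
  z <- check_speed_seeds(speed, seeds, domain)
  out <- fmm_march_cpp(z$F, z$S, z$domain, init_only = TRUE)
  out[c("T", "R", "status")]
}

#' Multi-label fast marching partition
#'
#' Propagates a front from every seed simultaneously over the speed image.
#' Each pixel is frozen with the arrival time of the first front to reach
#' it and that front's label, so the domain is partitioned into one region
#' per seed. Pixels outside `domain` are never visited; in-domain pixels
#' isolated by the mask keep the sentinel label 0 (with a warning).
#'
#' @inheritParams fmm_initialize
#' @param img optional [nodule_image] (or matrix); when given, per-region
#'   mean intensities are computed for the merging stage.
#' @return An object of class `fmm_partition`: list with `T` (arrival
#'   times), `labels` (region matrix), `pops` (the frozen arrival times in
#'   pop order; non-decreasing), `seeds`, and `region_stats` (data frame
#'   with seed coordinates, pixel counts and mean intensities).
#' @export
fmm_partition <- function(speed, seeds, domain = NULL, img = NULL) {
  z <- check_speed_seeds(speed, seeds, domain)
  out <- fmm_march_cpp(z$F, z$S, z$domain, init_only = FALSE)
  if (out$unreached > 0L)
    warning(sprintf("%d in-domain pixel(s) unreachable from any seed; left unlabeled",
                    out$unreached))
  labs <- out$R
  nlab <- nrow(z$S)
  stats <- data.frame(label = seq_len(nlab),
                      seed_row = z$S[, 1], seed_col = z$S[, 2],
                      pixel_count = tabulate(labs[labs > 0L], nbins = nlab))
  if (!is.null(img)) {
    intens <- if (inherits(img, "nodule_image")) img$intensity else as.matrix(img)
    sums <- rep(0, nlab)
    sel <- labs > 0L
    agg <- rowsum(as.vector(intens[sel]), group = as.vector(labs[sel]))
    sums[as.integer(rownames(agg))] <- agg[, 1]
    stats$mean_intensity <- ifelse(stats$pixel_count > 0,
                                   sums / stats$pixel_count, NA_real_)
  }
  structure(list(T = out$T, labels = labs, pops = out$pops,
                 seeds = z$S, domain = z$domain, region_stats = stats),
            class = "fmm_partition")
}

#' @export
print.fmm_partition <- function(x, ...) {
  cat(sprintf("<fmm_partition> %d x %d px, %d regions\n",
              nrow(x$labels), ncol(x$labels), nrow(x$seeds)))
  invisible(x)
}
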