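# Objective segmentation evaluation: Dice overlap, long/short-axis diameter
# measurement following the Fleischner manual-measurement convention, and
# per-category report tables.

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)` for two binary masks of identical shape. By
#' convention two empty masks score 1 (perfect agreement on "nothing").
#'
#' @param A,B logical matrices of the same shape.
#' @return A value in \[0, 1\].
#' @export
dice <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop("mask shapes differ", call. = FALSE)
  A <- as.logical(A); B <- as.logical(B)
  denom <- sum(A) + sum(B)
  if (denom == 0L) return(1.0)
  2 * sum(A & B) / denom
}

mask_border <- function(m) {
  outside <- !m
  nb <- shift_mat(outside, -1, 0, fill = TRUE) | shift_mat(outside, 1, 0, fill = TRUE) |
    shift_mat(outside, 0, -1, fill = TRUE) | shift_mat(outside, 0, 1, fill = TRUE)
  m & nb
}

largest_component <- function(m) {
  lab <- EBImage::bwlabel(m * 1)
  ids <- setdiff(unique(as.vector(lab)), 0)
  if (length(ids) <= 1L) return(m)
  sizes <- vapply(ids, function(i) sum(lab == i), numeric(1))
  lab == ids[which.max(sizes)]
}

#' Long- and short-axis diameters of a mask
#'
#' Measures the largest connected component, following the manual convention
#' for nodule size: the long axis is the maximal center-to-center distance
#' between two border pixels (border = mask pixels with a 4-neighbor
#' outside), and the short axis is the longest chord through the mask
#' perpendicular to the long axis (mask pixels are binned by their
#' projection onto the long-axis direction, 1 px bins; the short axis is
#' the maximal perpendicular extent within a bin). A single-pixel-wide
#' structure therefore has short axis 0. Reported values are rounded to the
#' nearest whole millimeter; unrounded values are also returned.
#'
#' @param mask non-empty logical matrix.
#' @param spacing pixel spacing in mm/px.
#' @return List with `long_mm`, `short_mm` (nearest whole mm) and
#'   `long_raw`, `short_raw` (unrounded mm).
#' @export
measure_diameters <- function(mask, spacing = 1) {
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (!any(mask)) stop("nothing to measure: the mask is empty", call. = FALSE)
  mask <- largest_component(mask)
  b <- which(mask_border(mask), arr.ind = TRUE)
  if (nrow(b) == 1L) {
    return(list(long_mm = 0, short_mm = 0, long_raw = 0, short_raw = 0))
  }
  D <- as.matrix(stats::dist(b))
  long_px <- max(D)
  ij <- which(D == long_px, arr.ind = TRUE)[1, ]
  u <- b[ij[2], ] - b[ij[1], ]
  u <- u / sqrt(sum(u^2))
  v <- c(-u[2], u[1])
  # short axis: longest chord perpendicular to u. Discretized as the max
  # perpendicular extent over all pixel pairs whose separation along u is
  # at most half a pixel (sliding window over the sorted u-projections).
  pix <- which(mask, arr.ind = TRUE)
  proj_u <- as.vector(pix %*% u)
  proj_v <- as.vector(pix %*% v)
  ord <- order(proj_u)
  us <- proj_u[ord]; vs <- proj_v[ord]
  hi <- findInterval(us + 0.5 + 1e-9, us)
  short_px <- max(vapply(seq_along(us), function(i) {
    w <- vs[i:hi[i]]
    max(w) - min(w)
  }, numeric(1)))
  list(long_mm = round_half_up(long_px * spacing),
       short_mm = round_half_up(short_px * spacing),
       long_raw = long_px * spacing,
       short_raw = short_px * spacing)
}

#' Relative measurement error
#'
#' `|ms - mgt| / mgt * 100`, in percent.
#'
#' @param ms measurement on the segmentation.
#' @param mgt measurement on the ground truth; must be > 0.
#' @return Percentage error (>= 0).
#' @export
relative_error <- function(ms, mgt) {
  if (any(mgt <= 0)) stop("ground-truth measurement must be > 0", call. = FALSE)
  abs(ms - mgt) / mgt * 100
}

#' Evaluate segmentations against ground truth
#'
#' Computes per-case Dice and long/short-axis diameter errors (diameters
#' rounded to the nearest whole mm before the error, matching the reporting
#' convention), then per-category aggregates (mean and sample standard
#' deviation; sd is 0 with `n = 1`).
#'
#' @param masks list of logical segmentation masks.
#' @param cases list of `synth_case` objects (or any list whose elements
#'   have `ground_truth`, `image$spacing` and `config$category` /
#'   `config$subcategory`).
#' @return An object of class `eval_report`: `per_case` and `per_category`
#'   data frames.
#' @export
evaluate_dataset <- function(masks, cases) {
  stopifnot(length(masks) == length(cases))
  rows <- lapply(seq_along(masks), function(i) {
    cs <- cases[[i]]
    sp <- cs$image$spacing
    dgt <- measure_diameters(cs$ground_truth, sp)
    ds <- if (any(masks[[i]])) measure_diameters(masks[[i]], sp) else
      list(long_mm = 0, short_mm = 0)
    data.frame(case_id = i,
               category = cs$config$category,
               subcategory = cs$config$subcategory,
               dice = dice(masks[[i]], cs$ground_truth),
               long_mm = ds$long_mm, short_mm = ds$short_mm,
               long_gt_mm = dgt$long_mm, short_gt_mm = dgt$short_mm,
               e_long_pct = relative_error(ds$long_mm, dgt$long_mm),
               e_short_pct = if (dgt$short_mm > 0)
                 relative_error(ds$short_mm, dgt$short_mm) else NA_real_)
  })
  per_case <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE) else 0)
  cats <- unique(per_case$category)
  per_category <- do.call(rbind, lapply(cats, function(cat) {
    sub <- per_case[per_case$category == cat, ]
    data.frame(category = cat, n = nrow(sub),
               dice_mean = mean(sub$dice), dice_sd = agg(sub$dice)["sd"],
               e_long_mean = mean(sub$e_long_pct),
               e_long_sd = agg(sub$e_long_pct)["sd"],
               e_short_mean = mean(sub$e_short_pct, na.rm = TRUE),
               e_short_sd = agg(sub$e_short_pct)["sd"],
               row.names = NULL)
  }))
  structure(list(per_case = per_case, per_category = per_category),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$per_category, digits = 3)
  invisible(x)
}
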