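# CT preprocessing: resampling, lung segmentation, HU normalization and
# nodule-centered cropping. The output of this stage is a `nodule_image`:
# a normalized, isotropic, square crop centered on the annotated nodule.

#' CT volume container
#'
#' A minimal in-memory representation of a CT scan: a 3D array of Hounsfield
#' units plus the physical voxel spacing. Axis order is (z, y, x) so that
#' `voxels[k, , ]` is one axial slice indexed (row, col).
#'
#' @param voxels 3D numeric array of Hounsfield units, dimensions (z, y, x).
#' @param spacing numeric length-3, mm per voxel along (z, y, x); all > 0.
#' @param origin numeric length-3 physical offset in mm (default zeros).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L || any(dim(voxels) == 0L))
    stop("`voxels` must be a non-empty 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (z, y, x)", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = as.numeric(origin)),
            class = "ct_volume")
}

#' Nodule annotation
#'
#' Centroid and approximate diameter of a nodule, as produced by a detection
#' stage or a manual annotation. The centroid may be given in voxel indices
#' (1-based, (z, y, x)) or in physical millimeters relative to the volume
#' origin; the `coords` flag says which.
#'
#' @param centroid numeric length-3 (z, y, x).
#' @param diameter_mm nodule diameter in millimeters, > 0.
#' @param coords either "voxel" or "mm".
#' @return An object of class `nodule_annotation`.
#' @export
nodule_annotation <- function(centroid, diameter_mm, coords = c("voxel", "mm")) {
  coords <- match.arg(coords)
  if (!is.numeric(diameter_mm) || diameter_mm <= 0)
    stop("`diameter_mm` must be > 0", call. = FALSE)
  structure(list(centroid = as.numeric(centroid), diameter_mm = diameter_mm,
                 coords = coords),
            class = "nodule_annotation")
}

#' Normalized nodule crop
#'
#' @param intensity 2D numeric matrix with values in \[0, 1\]; must be square.
#' @param spacing isotropic pixel spacing in mm/px.
#' @param lung_mask optional logical matrix of the same shape, TRUE = lung
#'   interior. When present, segmentation is restricted to this domain.
#' @param provenance free-text record of source and crop window.
#' @return An object of class `nodule_image`.
#' @export
nodule_image <- function(intensity, spacing, lung_mask = NULL, provenance = "") {
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != ncol(intensity))
    stop("nodule crops must be square", call. = FALSE)
  if (anyNA(intensity) || min(intensity) < 0 || max(intensity) > 1)
    stop("`intensity` must lie in [0, 1]", call. = FALSE)
  if (!is.null(lung_mask)) {
    if (!all(dim(as.matrix(lung_mask)) == dim(intensity)))
      stop("`lung_mask` must match the intensity shape", call. = FALSE)
    lung_mask <- matrix(as.logical(lung_mask), nrow(intensity), ncol(intensity))
  }
  structure(list(intensity = intensity, spacing = as.numeric(spacing),
                 lung_mask = lung_mask, provenance = provenance),
            class = "nodule_image")
}

#' @export
print.nodule_image <- function(x, ...) {
  cat(sprintf("<nodule_image> %d x %d px, %.3g mm/px%s\n",
              nrow(x$intensity), ncol(x$intensity), x$spacing,
              if (is.null(x$lung_mask)) "" else ", with lung mask"))
  invisible(x)
}

# Cubic-spline resampling of one axis of a matrix (applied to each row/col).
resample_axis <- function(m, old_n, new_n, along) {
  old_pos <- seq_len(old_n)
  # new grid covers the same physical extent; positions in old-index units
  new_pos <- seq(1, old_n, length.out = new_n)
  if (along == 1L) {
    apply(m, 2, function(v) stats::spline(old_pos, v, xout = new_pos, method = "fmm")$y)
  } else {
    t(apply(m, 1, function(v) stats::spline(old_pos, v, xout = new_pos, method = "fmm")$y))
  }
}

#' Resample a CT volume to a target in-plane spacing
#'
#' Resamples every axial slice to isotropic in-plane spacing with cubic
#' spline interpolation; the z axis is left untouched (segmentation operates
#' on single slices). The new in-plane dimension is
#' `round(old_n * old_spacing / target_spacing)` with round-half-up.
#'
#' @param vol a [ct_volume].
#' @param target_spacing target in-plane spacing in mm/px (default 0.5).
#' @return A resampled [ct_volume].
#' @export
resample_volume <- function(vol, target_spacing = 0.5) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!is.numeric(target_spacing) || target_spacing <= 0)
    stop("`target_spacing` must be > 0", call. = FALSE)
  d <- dim(vol$voxels)
  new_y <- as.integer(round_half_up(d[2] * vol$spacing[2] / target_spacing))
  new_x <- as.integer(round_half_up(d[3] * vol$spacing[3] / target_spacing))
  out <- array(0, dim = c(d[1], new_y, new_x))
  for (k in seq_len(d[1])) {
    sl <- vol$voxels[k, , ]
    sl <- resample_axis(sl, d[2], new_y, along = 1L)
    sl <- resample_axis(sl, d[3], new_x, along = 2L)
    out[k, , ] <- sl
  }
  ct_volume(out, c(vol$spacing[1], target_spacing, target_spacing), vol$origin)
}

#' Segment the lungs on a single axial slice
#'
#' Thresholds air-like voxels, keeps the dominant interior connected
#' components (candidate lungs), applies morphological closing and then a
#' per-lung convex hull. The hull recovers wall-attached (juxtapleural)
#' nodules that thresholding alone would exclude from the lung field.
#'
#' @param slice2d 2D numeric matrix in Hounsfield units.
#' @param threshold_hu air/tissue threshold; voxels below it are lung
#'   candidates. Default -320 HU.
#' @param closing_radius radius (px) of the disc used for morphological
#'   closing before hulling; default 5 (tuned for 0.5 mm/px crops).
#' @return Logical matrix, TRUE = lung interior. All-FALSE (with a warning)
#'   when no voxel lies below the threshold.
#' @export
segment_lungs <- function(slice2d, threshold_hu = -320, closing_radius = 5) {
  slice2d <- as.matrix(slice2d)
  air <- slice2d < threshold_hu
  if (!any(air)) {
    warning("no voxels below the air threshold; returning an empty lung mask")
    return(matrix(FALSE, nrow(slice2d), ncol(slice2d)))
  }
  lab <- EBImage::bwlabel(air * 1)
  ids <- setdiff(unique(as.vector(lab)), 0)
  # drop components touching the image border (ambient air around the body)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  interior <- setdiff(ids, border)
  if (length(interior) == 0L) interior <- ids  # slice fully inside the lungs
  sizes <- vapply(interior, function(i) sum(lab == i), numeric(1))
  keep <- interior[order(sizes, decreasing = TRUE)][seq_len(min(2L, length(interior)))]
  out <- matrix(FALSE, nrow(slice2d), ncol(slice2d))
  for (i in keep) {
    comp <- lab == i
    if (closing_radius > 0) {
      kern <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, shape = "disc")
      comp <- EBImage::closing(comp * 1, kern) > 0.5
    }
    out <- out | fill_convex_hull(comp)
  }
  out
}

#' Normalize Hounsfield units to \[0, 1\]
#'
#' Linear map from the diagnostic window -1000 HU (air) to +400 HU (dense
#' soft tissue); values outside are clipped to the bounds. Denser material
#' (bone, metal) carries no information for nodule segmentation.
#'
#' @param slice2d 2D numeric matrix (or any numeric array) in HU.
#' @return Array of the same shape with values in \[0, 1\].
#' @export
normalize_hu <- function(slice2d) {
  pmin(pmax((slice2d + 1000) / 1400, 0), 1)
}

#' Crop a nodule-centered square window
#'
#' Extracts a square crop of side `round(2 * diameter / spacing)` pixels
#' (round-half-up) centered on the annotated centroid, so the window is
#' twice the nodule diameter in each direction. Parts of the window falling
#' outside the slice are zero-padded and recorded in the provenance.
#'
#' @param slice2d normalized 2D matrix (values in \[0, 1\]).
#' @param ann a [nodule_annotation]; its in-plane centroid (y, x) is used.
#'   Millimeter coordinates are converted using `spacing`.
#' @param spacing isotropic pixel spacing of `slice2d` in mm/px.
#' @param mask optional logical lung mask, cropped identically.
#' @return A [nodule_image].
#' @export
crop_nodule <- function(slice2d, ann, spacing, mask = NULL) {
  stopifnot(inherits(ann, "nodule_annotation"))
  slice2d <- as.matrix(slice2d)
  ctr <- ann$centroid[2:3]              # (row, col) in-plane
  if (ann$coords == "mm") ctr <- ctr / spacing + 1
  cr <- as.integer(round_half_up(ctr[1]))
  cc <- as.integer(round_half_up(ctr[2]))
  if (cr < 1L || cr > nrow(slice2d) || cc < 1L || cc > ncol(slice2d))
    stop("annotated centroid lies outside the slice", call. = FALSE)
  side <- as.integer(round_half_up(2 * ann$diameter_mm / spacing))
  half_lo <- (side - 1L) %/% 2L
  rows <- (cr - half_lo):(cr - half_lo + side - 1L)
  cols <- (cc - half_lo):(cc - half_lo + side - 1L)
  pad_window <- function(m, fill) {
    out <- matrix(fill, side, side)
    rok <- rows >= 1L & rows <= nrow(m)
    cok <- cols >= 1L & cols <= ncol(m)
    out[rok, cok] <- m[rows[rok], cols[cok], drop = FALSE]
    out
  }
  padded <- !(all(rows >= 1L & rows <= nrow(slice2d)) &&
                all(cols >= 1L & cols <= ncol(slice2d)))
  crop <- pad_window(slice2d, 0)
  mcrop <- if (!is.null(mask)) pad_window(mask, FALSE) else NULL
  prov <- sprintf("crop rows %d..%d cols %d..%d of %dx%d slice%s",
                  rows[1], rows[side], cols[1], cols[side],
                  nrow(slice2d), ncol(slice2d),
                  if (padded) " (zero-padded outside slice)" else "")
  nodule_image(crop, spacing, lung_mask = mcrop, provenance = prov)
}
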