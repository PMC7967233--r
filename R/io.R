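# Disk I/O for crops, masks and reports. Crops travel as a PNG (intensity)
# plus a JSON sidecar (spacing, provenance, optional run-length-encoded
# lung mask); binary masks as 8-bit PNG (0/255).

#' Write a segmentation mask as PNG
#'
#' @param mask logical matrix.
#' @param path output file (8-bit grayscale PNG, 0/255).
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask from PNG
#'
#' @param path PNG file; any channel value > 0.5 is TRUE.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

#' Write a nodule crop to disk
#'
#' Stores the intensity as a grayscale PNG and a JSON sidecar
#' (`<path>.json`) with the spacing, provenance and lung mask.
#'
#' @param img a [nodule_image].
#' @param path output PNG path.
#' @export
write_crop <- function(img, path) {
  stopifnot(inherits(img, "nodule_image"))
  png::writePNG(img$intensity, path)
  side <- list(spacing = img$spacing, provenance = img$provenance,
               shape = dim(img$intensity))
  if (!is.null(img$lung_mask))
    side$lung_mask = as.integer(img$lung_mask)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a nodule crop written by [write_crop()]
#'
#' @param path PNG path (expects `<path>.json` alongside).
#' @return A [nodule_image].
#' @export
read_crop <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mask <- NULL
  if (!is.null(side$lung_mask))
    mask <- matrix(as.logical(side$lung_mask), nrow(m), ncol(m))
  nodule_image(m, side$spacing, lung_mask = mask,
               provenance = side$provenance %||% "")
}
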