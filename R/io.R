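# Image and mask persistence: 16-bit grayscale PNG for pixels (with a sidecar
# JSON carrying the HU rescale and pixel spacing) and 8-bit 0/255 PNG masks.
# The pixel grid is row-major with the origin at the top-left corner.

#' Write an ROI image as 16-bit PNG with sidecar JSON
#'
#' Pixels are affine-mapped to the 16-bit range; the sidecar JSON stores
#' `hu_slope`, `hu_intercept` (so `HU = slope * raw + intercept`) and
#' `spacing_mm`.  The mask is written as an 8-bit 0/255 PNG.  Quantization
#' limits the round trip to about `(max - min) / 65535` HU.
#'
#' @param image an [roi_image()].
#' @param path path of the image PNG; the sidecar is `<path>.json` and the
#'   mask `<path stem>_mask.png`.
#' @return Invisibly, the three file paths.
#' @export
write_roi_png <- function(image, path) {
  stopifnot_roi(image)
  px <- image$pixels
  lo <- min(px); hi <- max(px)
  slope <- if (hi > lo) (hi - lo) / 65535 else 1
  raw <- round((px - lo) / slope)
  write_png16_cpp(matrix(as.integer(raw), nrow(raw), ncol(raw)), path)
  side <- sub("\\.png$", "", path)
  jsonlite::write_json(
    list(hu_slope = slope, hu_intercept = lo,
         spacing_mm = image$spacing_mm),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  mask_path <- paste0(side, "_mask.png")
  png::writePNG(ifelse(image$mask, 1, 0), mask_path)
  invisible(c(image = path, sidecar = paste0(path, ".json"),
              mask = mask_path))
}

#' Read an ROI image from 16-bit PNG plus sidecar JSON
#'
#' @param path path of the image PNG written by [write_roi_png()] (the
#'   sidecar `<path>.json` must exist).
#' @param mask_path path of the mask PNG; defaults to `<path stem>_mask.png`.
#' @return An [roi_image()] on the HU scale.
#' @export
read_roi_png <- function(path, mask_path = NULL) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  side_file <- paste0(path, ".json")
  if (!file.exists(side_file)) {
    stop("sidecar JSON not found: ", side_file, call. = FALSE)
  }
  side <- jsonlite::read_json(side_file, simplifyVector = TRUE)
  if (is.null(mask_path)) {
    mask_path <- paste0(sub("\\.png$", "", path), "_mask.png")
  }
  if (!file.exists(mask_path)) {
    stop("mask PNG not found: ", mask_path, call. = FALSE)
  }
  mk <- png::readPNG(mask_path)
  if (length(dim(mk)) == 3L) mk <- mk[, , 1L]
  px <- raw * 65535 * side$hu_slope + side$hu_intercept
  roi_image(px, mk > 0.5, spacing_mm = side$spacing_mm)
}
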