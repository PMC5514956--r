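#' Tumor region-of-interest image
#'
#' Container for a single-slice grayscale tumor image on a Hounsfield-unit
#' (HU) attenuation scale, together with a binary tumor mask and the pixel
#' spacing.  This is the unit of input for pre-filtration and texture feature
#' extraction.
#'
#' @param pixels numeric matrix of attenuation values (HU).
#' @param mask logical (or 0/1) matrix of the same shape; `TRUE` marks tumor.
#' @param spacing_mm positive pixel edge length in millimetres.
#' @return An object of class `roi_image` with elements `pixels`, `mask`
#'   (logical) and `spacing_mm`.
#' @examples
#' img <- roi_image(matrix(rnorm(64 * 64, 70, 20), 64),
#'                  mask = matrix(TRUE, 64, 64))
#' dim(img$pixels)
#' @export
roi_image <- function(pixels, mask, spacing_mm = 0.7) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  mask <- as.matrix(mask)
  if (!identical(dim(pixels), dim(mask))) {
    stop("`pixels` and `mask` must have identical dimensions", call. = FALSE)
  }
  mask <- matrix(as.logical(mask), nrow(pixels), ncol(pixels))
  if (anyNA(mask)) stop("`mask` must be binary without NA", call. = FALSE)
  if (sum(mask) < 64L) {
    stop("mask must contain at least 64 foreground pixels", call. = FALSE)
  }
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0) {
    stop("`spacing_mm` must be a positive scalar", call. = FALSE)
  }
  structure(list(pixels = pixels, mask = mask, spacing_mm = spacing_mm),
            class = "roi_image")
}

#' @export
print.roi_image <- function(x, ...) {
  cat(sprintf("<roi_image> %d x %d px, %.3g mm/px, %d mask px (%.1f%%)\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_mm, sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' @noRd
stopifnot_roi <- function(image) {
  if (!inherits(image, "roi_image")) {
    stop("expected an `roi_image` object", call. = FALSE)
  }
  invisible(image)
}
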