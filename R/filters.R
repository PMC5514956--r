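# Pre-filtration: the three "band-width responses" applied to each ROI image
# before texture feature extraction.  Filter "0" is the identity; filters
# "1.0" and "1.5" are Laplacian-of-Gaussian (LoG) band-pass responses at
# sigma = 1.0 and 1.5 pixels.

FILTER_IDS <- c("0", "1.0", "1.5")

#' Pre-filter specification
#'
#' The feature pipeline pre-filters every ROI image at three band widths
#' before texture extraction: no filtration (`"0"`) and Laplacian-of-Gaussian
#' band-pass at sigma 1.0 and 1.5 pixels.  Sigma is expressed in pixels; with
#' a single acquisition protocol the pixel/millimetre distinction is a
#' constant factor.
#'
#' @param filter_id one of `"0"`, `"1.0"`, `"1.5"`.
#' @param sigma_px non-negative LoG scale in pixels.  Defaults to the numeric
#'   value of `filter_id` (0 for `"0"`).
#' @return An object of class `filter_spec` with `filter_id` and `sigma_px`.
#' @examples
#' filter_spec("1.0")
#' @export
filter_spec <- function(filter_id, sigma_px = NULL) {
  filter_id <- as.character(filter_id)
  if (!filter_id %in% FILTER_IDS) {
    stop("`filter_id` must be one of \"0\", \"1.0\", \"1.5\"", call. = FALSE)
  }
  if (is.null(sigma_px)) sigma_px <- as.numeric(filter_id)
  if (!is.numeric(sigma_px) || length(sigma_px) != 1L || sigma_px < 0) {
    stop("`sigma_px` must be a non-negative scalar", call. = FALSE)
  }
  if ((filter_id == "0") != (sigma_px == 0)) {
    stop("filter_id \"0\" requires sigma_px = 0 and vice versa", call. = FALSE)
  }
  structure(list(filter_id = filter_id, sigma_px = sigma_px),
            class = "filter_spec")
}

#' The default three-filter set
#'
#' @return List of three [filter_spec()] objects: identity, LoG sigma 1.0,
#'   LoG sigma 1.5.
#' @export
default_filters <- function() {
  lapply(FILTER_IDS, filter_spec)
}

# sampled analytic LoG kernel, support +/- 6 sigma.  `zero_mean = TRUE`
# subtracts the (tiny) residual mean so constant images map exactly to zero.
#' @noRd
log_kernel <- function(sigma, zero_mean = TRUE) {
  k <- ceiling(6 * sigma)
  u <- (-k):k
  r2 <- outer(u^2, u^2, "+")
  kern <- (r2 - 2 * sigma^2) / (2 * pi * sigma^6) * exp(-r2 / (2 * sigma^2))
  if (zero_mean) kern <- kern - mean(kern)
  kern
}

# separable pieces of the LoG: LoG(x, y) = c0 * (gpp(x) g(y) + g(x) gpp(y)),
# used by the batched fast path; identical on samples to log_kernel().
#' @noRd
log_sep_parts <- function(sigma) {
  k <- ceiling(6 * sigma)
  u <- (-k):k
  g <- exp(-u^2 / (2 * sigma^2))
  gpp <- (u^2 - sigma^2) / sigma^4 * g
  kern <- outer(gpp, g) + outer(g, gpp)
  list(g = g, gpp = gpp, c0 = 1 / (2 * pi * sigma^2),
       mean_adjust = mean(kern) / (2 * pi * sigma^2), k = k)
}

#' Apply a band-pass pre-filter to an ROI image
#'
#' Filter `"0"` returns the image unchanged.  The LoG filters convolve the
#' pixel grid with the sampled analytic Laplacian-of-Gaussian kernel
#' (support ±6 sigma, adjusted to exact zero mean) using symmetric (mirror)
#' boundary padding.  The mask and spacing pass through unchanged.
#'
#' @param image an [roi_image()].
#' @param spec a [filter_spec()].
#' @return A filtered [roi_image()].
#' @examples
#' img <- roi_image(matrix(rnorm(64^2, 70, 20), 64), matrix(TRUE, 64, 64))
#' flt <- apply_prefilter(img, filter_spec("1.0"))
#' @export
apply_prefilter <- function(image, spec) {
  stopifnot_roi(image)
  if (!inherits(spec, "filter_spec")) {
    stop("`spec` must be a `filter_spec`", call. = FALSE)
  }
  if (spec$filter_id == "0") return(image)
  parts <- log_sep_parts(spec$sigma_px)
  px <- image$pixels
  out <- parts$c0 * (sepconv2_mirror(px, parts$gpp, parts$g) +
                     sepconv2_mirror(px, parts$g, parts$gpp)) -
    parts$mean_adjust * box_sum(px, parts$k)
  roi_image(out, image$mask, image$spacing_mm)
}

# local sum over a (2k+1)^2 window, mirror padding (separable with ones)
#' @noRd
box_sum <- function(x, k) {
  ones <- rep(1, 2L * k + 1L)
  sepconv2_mirror(x, ones, ones)
}

# batched LoG: x3 (n, n, B) -> filtered (n, n, B)
#' @noRd
log_filter_batch <- function(x3, sigma) {
  parts <- log_sep_parts(sigma)
  ones <- rep(1, 2L * parts$k + 1L)
  parts$c0 * (sepconv2_batch(x3, parts$gpp, parts$g) +
              sepconv2_batch(x3, parts$g, parts$gpp)) -
    parts$mean_adjust * sepconv2_batch(x3, ones, ones)
}
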