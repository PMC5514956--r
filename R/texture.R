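# Texture feature extraction: 12 Gabor features (3 scales x 4 orientations)
# and 9 wavelet features (3 levels x 3 detail bands) per pre-filter, 63 per
# patient over the three-filter set.

#' Gabor filter-bank specification
#'
#' The bank holds three centre spatial frequencies (scale indices 1..3, high
#' to low frequency) and four orientations.  The Gaussian envelope of each
#' kernel is set by the half-response spatial-frequency bandwidth in octaves:
#' `sigma = lambda/pi * sqrt(log(2)/2) * (2^b + 1)/(2^b - 1)` with
#' `lambda = 1/frequency`.  Orientations are degrees counter-clockwise from
#' the +x (column) axis and denote the modulation (wave-vector) direction.
#'
#' @param scales strictly decreasing centre frequencies in cycles/pixel,
#'   indexed 1..3.
#' @param orientations_deg exactly four orientations in `[0, 180)`.
#' @param bandwidth_octaves positive half-response bandwidth (octaves).
#' @return An object of class `gabor_bank_spec`.
#' @examples
#' gabor_bank_spec()
#' @export
gabor_bank_spec <- function(scales = c(1 / 4, 1 / 8, 1 / 16),
                            orientations_deg = c(0, 45, 90, 135),
                            bandwidth_octaves = 1) {
  if (length(scales) != 3L || any(diff(scales) >= 0) || any(scales <= 0)) {
    stop("`scales` must be 3 strictly decreasing positive frequencies",
         call. = FALSE)
  }
  if (length(orientations_deg) != 4L) {
    stop("exactly 4 orientations are required", call. = FALSE)
  }
  if (bandwidth_octaves <= 0) stop("bandwidth must be positive", call. = FALSE)
  structure(list(scales = scales,
                 orientations_deg = as.numeric(orientations_deg),
                 bandwidth_octaves = bandwidth_octaves),
            class = "gabor_bank_spec")
}

#' Wavelet decomposition specification
#'
#' @param family wavelet family; only the orthonormal Haar wavelet is
#'   implemented (its orthonormality underpins the Parseval check used to
#'   validate the transform).
#' @param levels decomposition depth (>= 1).
#' @return An object of class `wavelet_spec`.
#' @examples
#' wavelet_spec()
#' @export
wavelet_spec <- function(family = "haar", levels = 3L) {
  family <- tolower(family)
  if (!identical(family, "haar")) {
    stop("only the Haar family is implemented", call. = FALSE)
  }
  levels <- as.integer(levels)
  if (levels < 1L) stop("`levels` must be >= 1", call. = FALSE)
  structure(list(family = family, levels = levels,
                 bands = c("H", "V", "D")),
            class = "wavelet_spec")
}

# envelope sigma in pixels for a centre frequency
#' @noRd
gabor_sigma <- function(freq, bandwidth) {
  lambda <- 1 / freq
  lambda / pi * sqrt(log(2) / 2) * (2^bandwidth + 1) / (2^bandwidth - 1)
}

# 1-D complex factors and DC constant of one bank kernel.
# Coordinates: x = column offset, y = -row offset (counter-clockwise
# orientation convention); truncation at +/- 3 sigma.
#' @noRd
gabor_parts <- function(scale_idx, orientation_deg, bank) {
  freq <- bank$scales[scale_idx]
  sigma <- gabor_sigma(freq, bank$bandwidth_octaves)
  k <- ceiling(3 * sigma)
  u <- (-k):k
  g <- exp(-u^2 / (2 * sigma^2))
  th <- orientation_deg * pi / 180
  wx <- 2 * pi * freq * cos(th)
  wy <- 2 * pi * freq * sin(th)
  vx <- g * exp(1i * wx * u)        # along columns
  vy <- g * exp(-1i * wy * u)       # along rows (y points up)
  dc <- (sum(vy) * sum(vx)) / sum(g)^2
  list(g = g, vx = vx, vy = vy, dc = dc, k = k,
       wx = wx, wy = wy, norm = 1 / (2 * pi * sigma^2))
}

#' Zero-mean complex Gabor kernel
#'
#' Returns the sampled complex Gabor kernel used by the bank: an isotropic
#' Gaussian envelope modulated along the stated orientation, truncated at
#' ±3 sigma, normalised by `1/(2 pi sigma^2)`, and made exactly zero-mean by
#' subtracting a scaled copy of the envelope (so constant image regions give
#' a response of exactly zero).
#'
#' @param scale_idx scale index 1..3.
#' @param orientation_deg one of the bank orientations.
#' @param bank a [gabor_bank_spec()].
#' @return A complex matrix of odd dimensions.
#' @examples
#' k <- gabor_kernel(1, 90)
#' abs(sum(k)) < 1e-12
#' @export
gabor_kernel <- function(scale_idx, orientation_deg,
                         bank = gabor_bank_spec()) {
  p <- gabor_parts(scale_idx, orientation_deg, bank)
  env <- outer(p$g, p$g)
  p$norm * (outer(p$vy, p$vx) - p$dc * env)
}

#' Single Gabor texture feature
#'
#' Mean magnitude of the zero-mean complex Gabor response over the mask
#' pixels, computed with symmetric (mirror) boundary padding.  Strictly
#' non-negative; exactly zero on constant images.
#'
#' @param image an [roi_image()] (already pre-filtered upstream if desired).
#' @param scale_idx scale index 1..3 (high to low frequency).
#' @param orientation_deg orientation in degrees, one of the bank's four.
#' @param bank a [gabor_bank_spec()].
#' @return A single non-negative number.
#' @examples
#' img <- roi_image(matrix(rnorm(64^2), 64), matrix(TRUE, 64, 64))
#' gabor_feature(img, 1, 90)
#' @export
gabor_feature <- function(image, scale_idx, orientation_deg,
                          bank = gabor_bank_spec()) {
  stopifnot_roi(image)
  scale_idx <- as.integer(scale_idx)
  if (is.na(scale_idx) || scale_idx < 1L || scale_idx > 3L) {
    stop("`scale_idx` must be 1, 2 or 3", call. = FALSE)
  }
  if (!orientation_deg %in% bank$orientations_deg) {
    stop("`orientation_deg` must be one of the bank orientations",
         call. = FALSE)
  }
  if (!any(image$mask)) stop("degenerate ROI", call. = FALSE)
  p <- gabor_parts(scale_idx, orientation_deg, bank)
  px <- image$pixels
  resp <- sepconv2_mirror(px, p$vy, p$vx) -
    p$dc * sepconv2_mirror(px, p$g, p$g)
  mean(Mod(p$norm * resp)[image$mask])
}

# ---- batched Gabor engine ---------------------------------------------------
# Computes bank features for a batch of same-sized images.  The complex
# separable kernel is factored as diagonal phase terms around real Gaussian
# band matrices (v[u] = g[u] e^{iwu} = e^{iw(i+u)} g[u] e^{-iwi}), so each
# pass is a real dgemm on shared data: orientations 45 and 135 share a row
# pass, orientation 0 shares its (real) row pass with the DC-correction
# blur.  Exactly equivalent to gabor_feature() up to floating-point rounding.

# one scale, all four orientations; returns nb x 4 matrix of mask-mean
# magnitudes.  maskmat_t: (m*n) x nb matrix of the TRANSPOSED masks.
#' @noRd
gabor_scale_batch <- function(imgs3, maskmat_t, msums, bank, s) {
  parts <- lapply(bank$orientations_deg, function(o)
    gabor_parts(s, o, bank))
  gabor_scale_cpp(imgs3, maskmat_t, msums, parts[[1L]]$g,
                  vapply(parts, function(p) p$wx, 0),
                  vapply(parts, function(p) p$wy, 0),
                  vapply(parts, function(p) Re(p$dc), 0),
                  vapply(parts, function(p) Im(p$dc), 0),
                  parts[[1L]]$norm)
}

# imgs3: (n, m, B) real array; mask3: logical array same shape.
# Returns B x 12 matrix, columns ordered scale-major then orientation.
#' @noRd
gabor_bank_batch <- function(imgs3, mask3, bank, scales = 1:3) {
  d <- dim(imgs3)
  n <- d[1L]; m <- d[2L]; nb <- d[3L]
  maskmat_t <- matrix(as.numeric(aperm(mask3, c(2L, 1L, 3L))), m * n, nb)
  msums <- colSums(maskmat_t)
  if (any(msums == 0)) stop("degenerate ROI", call. = FALSE)
  do.call(cbind, lapply(scales, function(s)
    gabor_scale_batch(imgs3, maskmat_t, msums, bank, s)))
}

# ---- Haar wavelet -----------------------------------------------------------

#' Orthonormal 2-D Haar decomposition
#'
#' Separable orthonormal Haar analysis to the requested depth.  Both image
#' dimensions must be divisible by `2^levels`.  Being orthonormal, the
#' transform conserves energy: the squared coefficients over the final
#' approximation plus all detail sub-bands sum to the squared pixels.
#'
#' @param x numeric matrix.
#' @param levels decomposition depth.
#' @return A list with `approx` (final approximation) and `detail`, a list of
#'   per-level lists with matrices `H` (detail along x: vertical structure),
#'   `V` (detail along y: horizontal structure) and `D` (diagonal).
#' @examples
#' dec <- haar_decompose(matrix(rnorm(64^2), 64), 3)
#' names(dec$detail[[2]])
#' @export
haar_decompose <- function(x, levels = 3L) {
  levels <- as.integer(levels)
  if (any(dim(x) %% 2^levels != 0)) {
    stop("matrix dimensions must be divisible by 2^levels", call. = FALSE)
  }
  detail <- vector("list", levels)
  a <- x
  s2 <- sqrt(2)
  for (l in seq_len(levels)) {
    odd_c <- a[, seq(1L, ncol(a), 2L), drop = FALSE]
    evn_c <- a[, seq(2L, ncol(a), 2L), drop = FALSE]
    lx <- (odd_c + evn_c) / s2
    hx <- (odd_c - evn_c) / s2
    odd_r <- function(z) z[seq(1L, nrow(z), 2L), , drop = FALSE]
    evn_r <- function(z) z[seq(2L, nrow(z), 2L), , drop = FALSE]
    ll <- (odd_r(lx) + evn_r(lx)) / s2
    hl <- (odd_r(hx) + evn_r(hx)) / s2   # highpass x, lowpass y
    lh <- (odd_r(lx) - evn_r(lx)) / s2   # lowpass x, highpass y
    hh <- (odd_r(hx) - evn_r(hx)) / s2
    detail[[l]] <- list(H = hl, V = lh, D = hh)
    a <- ll
  }
  list(approx = a, detail = detail)
}

#' Wavelet sub-band texture features
#'
#' Crops the image to the mask bounding box, replaces out-of-mask pixels by
#' the in-mask mean, extends the crop symmetrically to a dyadic size, and
#' performs an orthonormal Haar decomposition.  The feature for each
#' (level, band) is the mean absolute detail coefficient over coefficients
#' whose spatial support overlaps the mask by more than half (falling back to
#' any overlap if no coefficient reaches a majority).
#'
#' @param image an [roi_image()].
#' @param spec a [wavelet_spec()].
#' @return Named numeric vector of length `3 * levels`, names
#'   `wavelet-<level>-<band>` with bands `H`, `V`, `D`.
#' @examples
#' img <- roi_image(matrix(rnorm(64^2), 64), matrix(TRUE, 64, 64))
#' wavelet_features(img)
#' @export
wavelet_features <- function(image, spec = wavelet_spec()) {
  stopifnot_roi(image)
  rows <- range(which(rowSums(image$mask) > 0))
  cols <- range(which(colSums(image$mask) > 0))
  crop <- image$pixels[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  mcrop <- image$mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  blk <- 2L^spec$levels
  if (min(dim(crop)) < blk) {
    stop("ROI too small for decomposition depth", call. = FALSE)
  }
  crop[!mcrop] <- mean(crop[mcrop])
  # symmetric extension to the next dyadic multiple; extension pixels carry
  # mask weight zero
  ext <- function(n) {
    tgt <- ceiling(n / blk) * blk
    if (tgt == n) seq_len(n) else c(seq_len(n), n:(n - (tgt - n) + 1L))
  }
  ri <- ext(nrow(crop)); ci <- ext(ncol(crop))
  xp <- crop[ri, ci, drop = FALSE]
  mw <- matrix(0, length(ri), length(ci))
  mw[seq_len(nrow(crop)), seq_len(ncol(crop))] <- mcrop
  dec <- haar_decompose(xp, spec$levels)
  out <- numeric(0)
  frac <- mw
  for (l in seq_len(spec$levels)) {
    # mask fraction of each 2^l x 2^l coefficient support via 2x2 pooling
    frac <- (frac[seq(1, nrow(frac), 2), seq(1, ncol(frac), 2)] +
             frac[seq(2, nrow(frac), 2), seq(1, ncol(frac), 2)] +
             frac[seq(1, nrow(frac), 2), seq(2, ncol(frac), 2)] +
             frac[seq(2, nrow(frac), 2), seq(2, ncol(frac), 2)]) / 4
    sel <- frac > 0.5
    if (!any(sel)) sel <- frac > 0
    for (band in spec$bands) {
      val <- mean(abs(dec$detail[[l]][[band]][sel]))
      out <- c(out, val)
    }
  }
  names(out) <- as.vector(t(outer(seq_len(spec$levels), spec$bands,
                                  function(l, b) paste0("wavelet-", l, "-", b))))
  out
}

# batched wavelet features when all images in the batch share one mask;
# identical (to rounding) to per-image wavelet_features()
#' @noRd
wavelet_features_batch <- function(imgs3, mask, spec) {
  nb <- dim(imgs3)[3L]
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  crop3 <- imgs3[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
  mcrop <- mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  blk <- 2L^spec$levels
  if (min(dim(mcrop)) < blk) {
    stop("ROI too small for decomposition depth", call. = FALSE)
  }
  npx <- length(mcrop)
  cm <- matrix(crop3, npx, nb)
  mv <- as.vector(mcrop)
  mu <- colMeans(cm[mv, , drop = FALSE])
  if (any(!mv)) cm[!mv, ] <- rep(mu, each = sum(!mv))
  ext <- function(n) {
    tgt <- ceiling(n / blk) * blk
    if (tgt == n) seq_len(n) else c(seq_len(n), n:(n - (tgt - n) + 1L))
  }
  ri <- ext(nrow(mcrop)); ci <- ext(ncol(mcrop))
  dim(cm) <- c(dim(mcrop), nb)
  a <- cm[ri, ci, , drop = FALSE]
  mw <- matrix(0, length(ri), length(ci))
  mw[seq_len(nrow(mcrop)), seq_len(ncol(mcrop))] <- mcrop
  s2 <- sqrt(2)
  frac <- mw
  out <- matrix(NA_real_, nb, 3L * spec$levels)
  nm <- character(3L * spec$levels)
  j <- 0L
  for (l in seq_len(spec$levels)) {
    oc <- seq(1L, dim(a)[2L], 2L); ec <- seq(2L, dim(a)[2L], 2L)
    lx <- (a[, oc, , drop = FALSE] + a[, ec, , drop = FALSE]) / s2
    hx <- (a[, oc, , drop = FALSE] - a[, ec, , drop = FALSE]) / s2
    or <- seq(1L, dim(a)[1L], 2L); er <- seq(2L, dim(a)[1L], 2L)
    bands <- list(
      H = (hx[or, , , drop = FALSE] + hx[er, , , drop = FALSE]) / s2,
      V = (lx[or, , , drop = FALSE] - lx[er, , , drop = FALSE]) / s2,
      D = (hx[or, , , drop = FALSE] - hx[er, , , drop = FALSE]) / s2)
    a <- (lx[or, , , drop = FALSE] + lx[er, , , drop = FALSE]) / s2
    frac <- (frac[seq(1, nrow(frac), 2), seq(1, ncol(frac), 2)] +
             frac[seq(2, nrow(frac), 2), seq(1, ncol(frac), 2)] +
             frac[seq(1, nrow(frac), 2), seq(2, ncol(frac), 2)] +
             frac[seq(2, nrow(frac), 2), seq(2, ncol(frac), 2)]) / 4
    sel <- frac > 0.5
    if (!any(sel)) sel <- frac > 0
    for (band in spec$bands) {
      bb <- abs(bands[[band]])
      dim(bb) <- c(length(sel), nb)
      j <- j + 1L
      out[, j] <- colMeans(bb[as.vector(sel), , drop = FALSE])
      nm[j] <- sprintf("wavelet-%d-%s", l, band)
    }
  }
  colnames(out) <- nm
  out
}

# ---- feature table ----------------------------------------------------------

#' Canonical texture feature names
#'
#' @param bank a [gabor_bank_spec()].
#' @param wspec a [wavelet_spec()].
#' @param filters list of three [filter_spec()] objects.
#' @return Character vector of 63 feature names,
#'   `gabor-<scale>-<deg>@<filter>` and `wavelet-<level>-<band>@<filter>`.
#' @export
canonical_feature_names <- function(bank = gabor_bank_spec(),
                                    wspec = wavelet_spec(),
                                    filters = default_filters()) {
  unlist(lapply(filters, function(f) {
    gab <- as.vector(t(outer(1:3, bank$orientations_deg, function(s, o)
      sprintf("gabor-%d-%d@%s", s, o, f$filter_id))))
    wav <- as.vector(t(outer(seq_len(wspec$levels), wspec$bands,
      function(l, b) sprintf("wavelet-%s-%s@%s", l, b, f$filter_id))))
    c(gab, wav)
  }))
}

#' Extract the per-patient texture feature table
#'
#' For each image and each of the three pre-filters, computes the 12 Gabor
#' and 9 wavelet features (21 per filter, 63 per patient).  Images sharing
#' dimensions are processed in BLAS-batched groups; results are identical to
#' calling [apply_prefilter()], [gabor_feature()] and [wavelet_features()]
#' image by image.
#'
#' @param images list of [roi_image()] objects.
#' @param ids character/numeric patient identifiers, one per image, unique.
#' @param bank a [gabor_bank_spec()].
#' @param wspec a [wavelet_spec()].
#' @param filters list of exactly three [filter_spec()] objects.
#' @return A `data.frame` of class `feature_table`: column `patient_id`
#'   followed by the 63 canonical feature columns.
#' @examples
#' imgs <- lapply(1:3, function(i)
#'   generate_roi_image(texture_params(seed = i)))
#' ft <- extract_feature_table(imgs, ids = paste0("P", 1:3))
#' dim(ft)
#' @export
extract_feature_table <- function(images, ids,
                                  bank = gabor_bank_spec(),
                                  wspec = wavelet_spec(),
                                  filters = default_filters()) {
  if (length(filters) != 3L ||
      !all(vapply(filters, inherits, TRUE, "filter_spec"))) {
    stop("exactly 3 filter_spec objects are required", call. = FALSE)
  }
  if (length(images) != length(ids)) {
    stop("one id per image is required", call. = FALSE)
  }
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate ids", call. = FALSE)
  lapply(images, stopifnot_roi)
  nimg <- length(images)
  fnames <- canonical_feature_names(bank, wspec, filters)
  res <- matrix(NA_real_, nimg, length(fnames),
                dimnames = list(NULL, fnames))

  dims <- vapply(images, function(im) paste(dim(im$pixels), collapse = "x"), "")
  for (grp in split(seq_len(nimg), dims)) {
    sub <- images[grp]
    n <- nrow(sub[[1]]$pixels); m <- ncol(sub[[1]]$pixels)
    # chunk to bound memory in the batched engine
    chunk <- max(1L, min(64L, floor(6e7 / (8 * (n + 60)^2 * 8))))
    for (ck in split(seq_along(sub), ceiling(seq_along(sub) / chunk))) {
      imgs3 <- array(unlist(lapply(sub[ck], function(im) im$pixels)),
                     c(n, m, length(ck)))
      mask3 <- array(unlist(lapply(sub[ck], function(im) im$mask)),
                     c(n, m, length(ck)))
      for (f in filters) {
        f3 <- if (f$filter_id == "0") imgs3 else
          log_filter_batch(imgs3, f$sigma_px)
        gcols <- sprintf("gabor-%d-%d@%s",
                         rep(1:3, each = 4L),
                         rep(bank$orientations_deg, 3L), f$filter_id)
        res[grp[ck], gcols] <- gabor_bank_batch(f3, mask3, bank)
        same_mask <- length(ck) == 1L ||
          all(mask3 == as.vector(mask3[, , 1L]))
        if (same_mask) {
          wf <- wavelet_features_batch(f3, mask3[, , 1L], wspec)
          res[grp[ck], paste0(colnames(wf), "@", f$filter_id)] <- wf
        } else {
          for (jj in seq_along(ck)) {
            im <- roi_image(f3[, , jj], mask3[, , jj],
                            sub[[ck[jj]]]$spacing_mm)
            wf <- wavelet_features(im, wspec)
            res[grp[ck[jj]], paste0(names(wf), "@", f$filter_id)] <- wf
          }
        }
      }
    }
  }
  if (anyNA(res) || any(!is.finite(res))) {
    bad <- which(!is.finite(res), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite feature %s for patient %s",
                 colnames(res)[bad[2L]], ids[bad[1L]]), call. = FALSE)
  }
  out <- data.frame(patient_id = ids, res, check.names = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Write / read a feature table as CSV
#'
#' Values are serialized with 15 significant digits so that a write/read
#' round trip is lossless well beyond 12 significant digits.
#'
#' @param x a `feature_table`.
#' @param path file path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a `feature_table`.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  y <- x
  for (j in seq(2L, ncol(y))) y[[j]] <- sprintf("%.15g", y[[j]])
  utils::write.csv(y, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param path file path.
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE,
                         colClasses = c(patient_id = "character"))
  class(out) <- c("feature_table", "data.frame")
  out
}
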