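# Gabor and wavelet texture features.

test_that("constant images give zero Gabor and wavelet features", {
  img <- flat_image(64, 100)
  for (s in 1:3) for (o in c(0, 45, 90, 135)) {
    expect_lt(gabor_feature(img, s, o), 1e-9)
  }
  expect_lt(max(wavelet_features(img)), 1e-9)
})

test_that("gabor kernels are exactly zero-mean", {
  for (s in 1:3) for (o in c(0, 45, 90, 135)) {
    expect_lt(abs(sum(gabor_kernel(s, o))), 1e-12)
  }
})

test_that("a grating is detected at its own orientation and scale", {
  n <- 64
  xx <- outer(rep(1, n), 1:n)
  grating <- roi_image(50 * cos(2 * pi * xx / 4), matrix(TRUE, n, n))
  # brute-force direct convolution oracle over the four orientations
  bank <- gabor_bank_spec()
  oracle <- vapply(c(0, 45, 90, 135), function(o) {
    k <- gabor_kernel(1, o, bank)
    mean(Mod(oracle_conv2(grating$pixels, k)))
  }, 0)
  feats <- vapply(c(0, 45, 90, 135), function(o)
    gabor_feature(grating, 1, o, bank), 0)
  expect_equal(feats, oracle, tolerance = 1e-10)
  # the grating varies along x: wave vector at 0 degrees
  expect_equal(which.max(feats), 1L)
})

test_that("gabor features are 90-degree equivariant", {
  img <- generate_roi_image(texture_params(
    size_px = 64, correlation_length_px = 4, anisotropy_ratio = 3,
    anisotropy_angle_deg = 0, seed = 21))
  sym_mask <- matrix(FALSE, 64, 64)
  cx <- (64 + 1) / 2
  rr <- sqrt(outer(((1:64) - cx)^2, ((1:64) - cx)^2, "+"))
  sym_mask[rr <= 24] <- TRUE
  a <- roi_image(img$pixels, sym_mask)
  rot <- function(m) t(m)[, nrow(m):1]
  b <- roi_image(rot(img$pixels), sym_mask)
  for (s in 1:2) for (o in c(0, 45)) {
    f_rot <- gabor_feature(b, s, o)
    f_orig <- gabor_feature(a, s, (o + 90) %% 180)
    expect_lt(abs(f_rot - f_orig) / f_orig, 0.01)
  }
})

test_that("the batched engine equals the modular per-image path", {
  img <- generate_roi_image(texture_params(
    correlation_length_px = 3.5, anisotropy_ratio = 2,
    anisotropy_angle_deg = 30, seed = 5))
  ft <- extract_feature_table(list(img), "P1")
  for (fid in c("0", "1.0", "1.5")) {
    flt <- apply_prefilter(img, filter_spec(fid))
    for (s in 1:3) for (o in c(0, 45, 90, 135)) {
      expect_equal(ft[[sprintf("gabor-%d-%d@%s", s, o, fid)]],
                   gabor_feature(flt, s, o), tolerance = 1e-12)
    }
    wf <- wavelet_features(flt)
    expect_equal(unlist(ft[1, paste0(names(wf), "@", fid)]),
                 wf, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("haar decomposition is orthonormal (Parseval identity)", {
  set.seed(4)
  x <- matrix(rnorm(64 * 64, 70, 25), 64)
  dec <- haar_decompose(x, 3)
  energy <- sum(dec$approx^2) +
    sum(vapply(dec$detail, function(l)
      sum(l$H^2) + sum(l$V^2) + sum(l$D^2), 0))
  expect_lt(abs(energy - sum(x^2)) / sum(x^2), 1e-6)
})

test_that("period-2 horizontal stripes load on the vertical-detail band", {
  n <- 32
  stripes <- matrix(rep(c(10, -10), length.out = n), n, n)  # varies by row
  img <- roi_image(stripes + 100, matrix(TRUE, n, n))
  wf <- wavelet_features(img)
  expect_gt(wf["wavelet-1-V"], wf["wavelet-1-H"] * 10)
  expect_gt(wf["wavelet-1-V"], wf["wavelet-1-D"] * 10)
  # hand Haar oracle: column lowpass doubles the +/-10 pattern to
  # +/-10*sqrt(2); the row highpass then gives (10*sqrt(2) + 10*sqrt(2)) /
  # sqrt(2) = 20 for every level-1 V coefficient
  expect_equal(unname(wf["wavelet-1-V"]), 20, tolerance = 1e-9)
})

test_that("feature table has the canonical 63-column structure", {
  imgs <- lapply(1:5, function(i)
    generate_roi_image(texture_params(size_px = 48, seed = i)))
  ft <- extract_feature_table(imgs, paste0("P", 1:5))
  expect_s3_class(ft, "feature_table")
  expect_equal(dim(ft), c(5L, 64L))
  expect_identical(names(ft)[1], "patient_id")
  expect_identical(names(ft)[-1], canonical_feature_names())
  expect_equal(sum(grepl("^gabor-", names(ft))), 36L)
  expect_equal(sum(grepl("^wavelet-", names(ft))), 27L)
  expect_true(all(is.finite(as.matrix(ft[, -1]))))
})

test_that("feature extraction is order-invariant and rejects duplicates", {
  imgs <- lapply(1:4, function(i)
    generate_roi_image(texture_params(size_px = 48, seed = i + 10)))
  ids <- paste0("P", 1:4)
  a <- extract_feature_table(imgs, ids)
  perm <- c(3, 1, 4, 2)
  b <- extract_feature_table(imgs[perm], ids[perm])
  b <- b[match(a$patient_id, b$patient_id), ]
  expect_equal(as.matrix(a[, -1]), as.matrix(b[, -1]),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(extract_feature_table(imgs, rep("P1", 4)), "duplicate")
  expect_error(extract_feature_table(imgs, ids,
                                     filters = default_filters()[1:2]),
               "3 filter")
})

test_that("features are shift-invariant and scale covariant", {
  img <- generate_roi_image(texture_params(size_px = 48, seed = 33))
  ft <- extract_feature_table(list(img), "A")
  shifted <- roi_image(img$pixels + 500, img$mask)
  ft_s <- extract_feature_table(list(shifted), "A")
  expect_lt(max(abs(as.matrix(ft[, -1]) - as.matrix(ft_s[, -1]))), 1e-6)
  scaled <- roi_image(img$pixels * 3.7, img$mask)
  ft_c <- extract_feature_table(list(scaled), "A")
  expect_equal(as.matrix(ft_c[, -1]), 3.7 * as.matrix(ft[, -1]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("features separate planted texture classes", {
  imgs_lo <- lapply(1:20, function(i) generate_roi_image(
    texture_params(size_px = 48, correlation_length_px = 2, seed = i)))
  imgs_hi <- lapply(1:20, function(i) generate_roi_image(
    texture_params(size_px = 48, correlation_length_px = 6, seed = 100 + i)))
  ft <- extract_feature_table(c(imgs_lo, imgs_hi), paste0("P", 1:40))
  v <- ft[["gabor-1-90@0"]]
  p <- stats::wilcox.test(v[1:20], v[21:40], exact = TRUE)$p.value
  expect_lt(p, 0.01)
})

test_that("degenerate ROIs are rejected", {
  img <- noise_image(32, seed = 2)
  expect_error(wavelet_spec(levels = 0), ">= 1")
  small_mask <- matrix(FALSE, 32, 32)
  small_mask[1:9, 1:9] <- TRUE
  roi <- roi_image(img$pixels, small_mask)
  # 9-px crop cannot host a 3-level (block 8) decomposition after cropping
  expect_silent(wavelet_features(roi))
  tiny <- matrix(FALSE, 32, 32)
  tiny[1:16, 1:4] <- TRUE
  expect_error(wavelet_features(roi_image(img$pixels, tiny)),
               "too small")
})

test_that("feature table CSV round trip is lossless to 12 digits", {
  imgs <- lapply(1:2, function(i)
    generate_roi_image(texture_params(size_px = 48, seed = i)))
  ft <- extract_feature_table(imgs, c("a", "b"))
  path <- tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_identical(names(back), names(ft))
  expect_equal(as.matrix(back[, -1]), as.matrix(ft[, -1]),
               tolerance = 1e-12, ignore_attr = TRUE)
})
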