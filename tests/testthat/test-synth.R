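# Synthetic texture and cohort generator.

test_that("texture parameters validate invariants", {
  expect_error(texture_params(size_px = 16), ">= 32")
  expect_error(texture_params(correlation_length_px = 0), "positive")
  expect_error(texture_params(anisotropy_ratio = 0.5), ">= 1")
  expect_error(texture_params(sd_hu = -1), "non-negative")
  expect_error(texture_params(anisotropy_angle_deg = 180), "180")
})

test_that("sd_hu = 0 gives a constant image at mean_hu", {
  img <- generate_roi_image(texture_params(sd_hu = 0, mean_hu = 55))
  expect_true(all(img$pixels == 55))
})

test_that("image generation is bit-identical under a fixed seed", {
  p <- texture_params(correlation_length_px = 4, seed = 99)
  a <- generate_roi_image(p)
  b <- generate_roi_image(p)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$mask, b$mask)
  c <- generate_roi_image(texture_params(correlation_length_px = 4,
                                         seed = 100))
  expect_false(identical(a$pixels, c$pixels))
})

test_that("the mask covers at least half the pixels", {
  img <- generate_roi_image(texture_params(size_px = 48, seed = 1))
  expect_gte(mean(img$mask), 0.5)
})

test_that("images match the requested HU mean and spread", {
  img <- generate_roi_image(texture_params(mean_hu = 70, sd_hu = 20,
                                           seed = 2))
  expect_equal(mean(img$pixels), 70, tolerance = 1e-9)
  expect_equal(sd(img$pixels), 20, tolerance = 1e-9)
})

test_that("anisotropy angle rotates the autocorrelation major axis by 90", {
  # brute-force sample autocorrelation, orientation from its second moments
  acf_angle <- function(px) {
    px <- px - mean(px)
    lags <- -6:6
    cc <- matrix(0, 13, 13)
    n <- nrow(px)
    for (a in lags) for (b in lags) {
      i <- max(1, 1 - a):min(n, n - a)
      j <- max(1, 1 - b):min(n, n - b)
      cc[a + 7, b + 7] <- mean(px[i, j] * px[i + a, j + b])
    }
    cc <- pmax(cc / cc[7, 7], 0)
    dx <- outer(rep(1, 13), lags)   # column offset = x
    dy <- outer(-lags, rep(1, 13))  # y points up
    0.5 * atan2(2 * sum(cc * dx * dy), sum(cc * (dx^2 - dy^2))) * 180 / pi
  }
  mk <- function(angle) generate_roi_image(texture_params(
    size_px = 96, correlation_length_px = 4, anisotropy_ratio = 4,
    anisotropy_angle_deg = angle, seed = 7))
  a0 <- acf_angle(mk(0)$pixels)
  a90 <- acf_angle(mk(90)$pixels)
  delta <- abs(a0 - a90) %% 180
  expect_lt(abs(delta - 90), 5)
  expect_lt(abs(a0 %% 180), 5)
})

test_that("cohort parameters validate invariants", {
  expect_error(cohort_params(n_tace = -1), ">= 0")
  expect_error(cohort_params(baseline_rate = 0), "positive")
  expect_error(cohort_params(censor_rate = -1), "positive")
})

test_that("cohorts are reproducible and carry ground truth", {
  cp <- cohort_params(n_tace = 25, n_combo = 20, seed = 5)
  a <- generate_cohort(cohort = cp)
  b <- generate_cohort(cohort = cp)
  expect_identical(a$records, b$records)
  expect_identical(a$images[[7]]$pixels, b$images[[7]]$pixels)
  expect_identical(a$truth$z, b$truth$z)
  expect_equal(nrow(a$records), 45L)
  expect_setequal(unique(a$records$arm), c("TACE", "TACE_S"))
  expect_true(all(a$records$ttp_time > 0))
  expect_true(all(a$records$ttp_event %in% 0:1))
  # progression never observed after death
  obs <- a$records$ttp_event == 1 & a$records$os_event == 1
  expect_true(all(a$records$ttp_time[obs] <= a$records$os_time[obs]))
})

test_that("vanishing censoring yields events for everyone", {
  cc <- generate_cohort(cohort = cohort_params(
    n_tace = 25, n_combo = 20, censor_rate = 1e-9, seed = 3))
  expect_true(all(cc$records$ttp_event == 1))
  expect_true(all(cc$records$os_event == 1))
})

test_that("event fraction grows with the baseline rate", {
  tex <- texture_params(size_px = 32, correlation_length_px = 2)
  texh <- texture_params(size_px = 32, correlation_length_px = 4)
  frac <- vapply(c(0.03, 0.115, 0.5), function(rate) {
    mean(vapply(1:100, function(i) {
      cc <- generate_cohort(tex, texh, cohort_params(
        n_tace = 20, n_combo = 20, baseline_rate = rate,
        censor_rate = 0.115, seed = 7000 + i))
      mean(cc$records$ttp_event)
    }, 0))
  }, 0)
  expect_true(all(diff(frac) > 0))
})

test_that("with beta = 0 the designated feature and event time are independent", {
  cc <- generate_cohort(
    texture_params(size_px = 48, correlation_length_px = 2),
    texture_params(size_px = 48, correlation_length_px = 6,
                   anisotropy_ratio = 2.5),
    cohort_params(n_tace = 1000, n_combo = 0, beta_ttp = 0, beta_os = 0,
                  combo_hr = 1, censor_rate = 1e-9, seed = 12))
  tau <- stats::cor(cc$truth$z, cc$records$ttp_time, method = "kendall")
  se <- sqrt(2 * (2 * 1000 + 5) / (9 * 1000 * 999))
  expect_lt(abs(tau), 3 * se)
})

test_that("null arms reject at the nominal log-rank rate", {
  rej <- vapply(1:200, function(i) {
    cc <- generate_cohort(
      texture_params(size_px = 32, correlation_length_px = 2),
      texture_params(size_px = 32, correlation_length_px = 4),
      cohort_params(n_tace = 25, n_combo = 25, beta_ttp = 0, beta_os = 0,
                    combo_hr = 1, seed = 4000 + i))
    lr <- logrank_test(cc$records$ttp_time, cc$records$ttp_event,
                       cc$records$arm)
    lr$p < 0.05
  }, TRUE)
  # 2 SE binomial band around 5%
  expect_lt(abs(mean(rej) - 0.05), 2 * sqrt(0.05 * 0.95 / 200) + 1e-9)
})

test_that("cohort CSV round trip preserves the records", {
  cc <- generate_cohort(cohort = cohort_params(n_tace = 20, n_combo = 20,
                                               seed = 9))
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(cc$records, path)
  back <- read_cohort_csv(path)
  expect_equal(back$ttp_time, cc$records$ttp_time, tolerance = 1e-12)
  expect_identical(back$arm, cc$records$arm)
  expect_identical(back$lesion_n, cc$records$lesion_n)
})
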