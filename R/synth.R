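# Synthetic study data: stationary Gaussian random-field tumor textures on a
# Hounsfield-unit scale, and a two-arm survival cohort whose hazard depends
# log-linearly on a designated texture feature measured from each patient's
# generated image.

#' Texture generator parameters
#'
#' Describes one stationary Gaussian random-field texture: white noise
#' smoothed by an oriented Gaussian kernel with the stated correlation length
#' and anisotropy, then affine-mapped to the stated HU mean and spread.
#'
#' @param size_px square image side in pixels (>= 32).
#' @param correlation_length_px Gaussian smoothing sigma along the major axis
#'   (pixels).
#' @param anisotropy_angle_deg major-axis orientation, degrees in `[0, 180)`,
#'   counter-clockwise from the +x (column) axis.
#' @param anisotropy_ratio major/minor correlation-length ratio (>= 1);
#'   1 gives a statistically isotropic field.
#' @param mean_hu,sd_hu target sample mean and standard deviation on the
#'   Hounsfield scale; `sd_hu = 0` yields a constant image.
#' @param seed integer seed; identical parameters and seed reproduce the
#'   image bit for bit.
#' @return An object of class `texture_params`.
#' @examples
#' texture_params(correlation_length_px = 4, seed = 7)
#' @export
texture_params <- function(size_px = 64L, correlation_length_px = 3,
                           anisotropy_angle_deg = 0, anisotropy_ratio = 1,
                           mean_hu = 70, sd_hu = 20, seed = 1L) {
  size_px <- as.integer(size_px)
  if (is.na(size_px) || size_px < 32L) {
    stop("`size_px` must be an integer >= 32", call. = FALSE)
  }
  if (correlation_length_px <= 0) {
    stop("`correlation_length_px` must be positive", call. = FALSE)
  }
  if (anisotropy_angle_deg < 0 || anisotropy_angle_deg >= 180) {
    stop("`anisotropy_angle_deg` must be in [0, 180)", call. = FALSE)
  }
  if (anisotropy_ratio < 1) {
    stop("`anisotropy_ratio` must be >= 1", call. = FALSE)
  }
  if (sd_hu < 0) stop("`sd_hu` must be non-negative", call. = FALSE)
  structure(list(size_px = size_px,
                 correlation_length_px = correlation_length_px,
                 anisotropy_angle_deg = anisotropy_angle_deg,
                 anisotropy_ratio = anisotropy_ratio,
                 mean_hu = mean_hu, sd_hu = sd_hu,
                 seed = as.integer(seed)),
            class = "texture_params")
}

# elliptical mask covering >= 50% of a n x n grid
#' @noRd
ellipse_mask <- function(n) {
  cx <- (n + 1) / 2
  a <- 0.46 * n; b <- 0.40 * n
  xx <- outer(rep(1, n), seq_len(n)) - cx
  yy <- outer(seq_len(n), rep(1, n)) - cx
  (xx / a)^2 + (yy / b)^2 <= 1
}

# smooth white noise with an oriented Gaussian kernel (circular convolution
# on the torus via FFT -- the standard stationary Gaussian random-field
# construction), given an already-drawn white-noise matrix
#' @noRd
grf_from_noise <- function(noise, params) {
  n <- nrow(noise)
  s_maj <- params$correlation_length_px
  s_min <- s_maj / params$anisotropy_ratio
  th <- params$anisotropy_angle_deg * pi / 180
  # kernel on the torus, centred at (1,1); x = col, y = -row
  ix <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  xx <- outer(rep(1, n), ix)
  yy <- outer(-ix, rep(1, n))
  u <- xx * cos(th) + yy * sin(th)
  v <- -xx * sin(th) + yy * cos(th)
  kern <- exp(-0.5 * ((u / s_maj)^2 + (v / s_min)^2))
  field <- Re(fft(fft(noise) * fft(kern), inverse = TRUE)) / n^2
  field
}

#' Generate a synthetic tumor ROI image
#'
#' Draws a stationary Gaussian random field (white noise convolved with an
#' oriented Gaussian kernel), affine-maps it to the requested sample mean and
#' standard deviation in HU, and attaches an elliptical tumor mask covering
#' more than half of the pixels.
#'
#' @param params a [texture_params()].
#' @return An [roi_image()].
#' @examples
#' img <- generate_roi_image(texture_params(seed = 42))
#' mean(img$mask) > 0.5
#' @export
generate_roi_image <- function(params) {
  if (!inherits(params, "texture_params")) {
    stop("`params` must be a `texture_params`", call. = FALSE)
  }
  n <- params$size_px
  noise <- with_seed(params$seed, matrix(stats::rnorm(n * n), n, n))
  if (params$sd_hu == 0) {
    px <- matrix(params$mean_hu, n, n)
  } else {
    field <- grf_from_noise(noise, params)
    px <- params$mean_hu +
      params$sd_hu * (field - mean(field)) / stats::sd(field)
  }
  roi_image(px, ellipse_mask(n), spacing_mm = 0.7)
}

# run code under a temporary RNG state
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Survival cohort generator parameters
#'
#' Parameters of the simulated two-arm cohort.  Event times follow an
#' exponential model: the progression hazard is
#' `baseline_rate * exp(beta_ttp * z + log(combo_hr) * arm)`, where `z` is
#' the designated texture feature measured on each patient's generated image
#' and standardized to unit variance within the cohort, and `arm` is 1 for
#' TACE+sorafenib.  Overall survival is progression time plus a residual
#' exponential survival with hazard
#' `os_baseline_rate * exp(beta_os * z + log(combo_hr) * arm)` (keeping
#' progression no later than death).  Censoring is an independent shared
#' exponential follow-up time.
#'
#' Defaults encode the planted-effect validation scenario: a unit-SD texture
#' effect on progression (`beta_ttp = 1`), a combination-arm hazard factor
#' `combo_hr = 0.317` calibrated so the low-texture half of the TACE arm
#' matches the combination arm's marginal hazard
#' (`E[e^z | z < 0] / E[e^z]` under a standard normal `z`), and censoring
#' matched to the baseline rate so the progression indicator is balanced.
#'
#' @param n_tace,n_combo arm sizes (the study recruited 197 and 64).
#' @param beta_ttp log-hazard for progression per unit of the designated
#'   (standardized) texture feature.
#' @param beta_os log-hazard for the post-progression survival component.
#' @param combo_hr multiplicative hazard factor of the combination arm.
#' @param baseline_rate baseline progression hazard per month.
#' @param os_baseline_rate baseline post-progression death hazard per month.
#' @param censor_rate hazard of the independent censoring time.
#' @param prob_os_lost probability that a patient is lost to overall-survival
#'   follow-up after progression (excluded from OS analyses).
#' @param designated_feature canonical name of the texture feature that
#'   drives the hazard.
#' @param seed integer seed.
#' @return An object of class `cohort_params`.
#' @examples
#' cohort_params(n_tace = 40, n_combo = 20, seed = 3)
#' @export
cohort_params <- function(n_tace = 197L, n_combo = 64L,
                          beta_ttp = 1, beta_os = 1, combo_hr = 0.317,
                          baseline_rate = 0.115, os_baseline_rate = 0.09,
                          censor_rate = 0.115, prob_os_lost = 0.06,
                          designated_feature = "gabor-1-90@0",
                          seed = 1L) {
  n_tace <- as.integer(n_tace); n_combo <- as.integer(n_combo)
  if (n_tace < 0L || n_combo < 0L) stop("counts must be >= 0", call. = FALSE)
  if (baseline_rate <= 0 || os_baseline_rate <= 0 || censor_rate <= 0) {
    stop("rates must be positive", call. = FALSE)
  }
  if (combo_hr <= 0) stop("`combo_hr` must be positive", call. = FALSE)
  structure(list(n_tace = n_tace, n_combo = n_combo, beta_ttp = beta_ttp,
                 beta_os = beta_os, combo_hr = combo_hr,
                 baseline_rate = baseline_rate,
                 os_baseline_rate = os_baseline_rate,
                 censor_rate = censor_rate, prob_os_lost = prob_os_lost,
                 designated_feature = designated_feature,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

# draw clinical covariates emulating the study's baseline table
#' @noRd
draw_covariates <- function(n) {
  data.frame(
    age = pmin(pmax(round(stats::rnorm(n, 56, 12)), 20), 84),
    sex = sample(c("M", "F"), n, TRUE, prob = c(241, 20) / 261),
    md_mm = pmin(pmax(round(exp(stats::rnorm(n, log(75), 0.28))), 42), 187),
    lesion_n = sample(c("1", "2", "3", ">=4"), n, TRUE,
                      prob = c(113, 67, 13, 68) / 261),
    cirrhosis = stats::rbinom(n, 1, 196 / 261),
    bclc = sample(c("AB", "B", "C"), n, TRUE, prob = c(75, 101, 85) / 261),
    cp = sample(c("A", "B"), n, TRUE, prob = c(180, 81) / 261),
    vi_em = stats::rbinom(n, 1, 85 / 261),
    afp_cat = sample(c("<25", "25-400", ">400"), n, TRUE,
                     prob = c(69, 93, 99) / 261),
    hepatitis = sample(c("none", "B", "C"), n, TRUE,
                       prob = c(62, 195, 4) / 261),
    stringsAsFactors = FALSE
  )
}

# measure the designated feature from images (parses "gabor-s-deg@filter")
#' @noRd
measure_designated <- function(images, feature,
                               bank = gabor_bank_spec(),
                               wspec = wavelet_spec()) {
  parts <- strsplit(feature, "@", fixed = TRUE)[[1]]
  fspec <- filter_spec(parts[2])
  bits <- strsplit(parts[1], "-", fixed = TRUE)[[1]]
  n <- nrow(images[[1]]$pixels)
  imgs3 <- array(unlist(lapply(images, `[[`, "pixels")),
                 c(n, n, length(images)))
  mask3 <- array(unlist(lapply(images, `[[`, "mask")),
                 c(n, n, length(images)))
  f3 <- if (fspec$filter_id == "0") imgs3 else
    log_filter_batch(imgs3, fspec$sigma_px)
  if (bits[1] == "gabor") {
    s <- as.integer(bits[2]); o <- as.numeric(bits[3])
    feats <- gabor_bank_batch(f3, mask3, bank, scales = s)
    feats[, match(o, bank$orientations_deg)]
  } else {
    l <- as.integer(bits[2]); b <- bits[3]
    vapply(seq_along(images), function(j) {
      im <- roi_image(f3[, , j], mask3[, , j])
      wavelet_features(im, wspec)[sprintf("wavelet-%d-%s", l, b)]
    }, 0)
  }
}

#' Generate a two-arm synthetic cohort
#'
#' Generates one ROI image per patient (texture parameters interpolated
#' uniformly between `tex_low` and `tex_high`, per-patient sub-seeds), then
#' draws progression and death times from the exponential hazard model of
#' [cohort_params()] driven by the designated texture feature measured from
#' the images, with shared independent exponential censoring.  Clinical
#' covariates are drawn from categorical distributions emulating the study's
#' baseline table and have no effect on the hazards.
#'
#' @param tex_low,tex_high [texture_params()] for the two ends of the texture
#'   continuum (their seeds are ignored; per-patient sub-seeds are used).
#' @param cohort a [cohort_params()].
#' @return A list with `images` (list of [roi_image()]), `records` (a
#'   `data.frame` of patient records: arm, ttp/os times and event flags,
#'   os_lost flag, clinical covariates) and `truth` (a list recording the
#'   designated feature values, their standardization, interpolation weights
#'   and the true effect parameters; never consumed by pipeline stages).
#' @examples
#' cc <- generate_cohort(cohort = cohort_params(n_tace = 25, n_combo = 25,
#'                                              seed = 11))
#' table(cc$records$arm)
#' @export
generate_cohort <- function(tex_low = texture_params(correlation_length_px = 2),
                            tex_high = texture_params(correlation_length_px = 6,
                                                      anisotropy_ratio = 2.5),
                            cohort = cohort_params()) {
  if (!inherits(cohort, "cohort_params")) {
    stop("`cohort` must be a `cohort_params`", call. = FALSE)
  }
  n <- cohort$n_tace + cohort$n_combo
  if (n < 1L) stop("empty cohort", call. = FALSE)
  arm <- rep(c("TACE", "TACE_S"), c(cohort$n_tace, cohort$n_combo))

  draws <- with_seed(cohort$seed, {
    # independent interpolation weight per texture parameter: patients
    # occupy a box, not a line, in texture space, so features are not
    # artificially collinear
    u <- matrix(stats::runif(n * 5L), n, 5L,
                dimnames = list(NULL, c("correlation_length_px",
                                        "anisotropy_angle_deg",
                                        "anisotropy_ratio", "mean_hu",
                                        "sd_hu")))
    covs <- draw_covariates(n)
    img_seeds <- sample.int(2^30, n)
    e_ttp <- stats::rexp(n)
    e_os <- stats::rexp(n)
    cens <- stats::rexp(n, cohort$censor_rate)
    lost <- stats::rbinom(n, 1, cohort$prob_os_lost)
    list(u = u, covs = covs, img_seeds = img_seeds, e_ttp = e_ttp,
         e_os = e_os, cens = cens, lost = lost)
  })

  lerp <- function(fld, i) {
    tex_low[[fld]] + (tex_high[[fld]] - tex_low[[fld]]) * draws$u[i, fld]
  }
  images <- lapply(seq_len(n), function(i) {
    tp <- texture_params(
      size_px = tex_low$size_px,
      correlation_length_px = lerp("correlation_length_px", i),
      anisotropy_angle_deg = lerp("anisotropy_angle_deg", i),
      anisotropy_ratio = lerp("anisotropy_ratio", i),
      mean_hu = lerp("mean_hu", i),
      sd_hu = lerp("sd_hu", i),
      seed = draws$img_seeds[i])
    generate_roi_image(tp)
  })

  raw <- measure_designated(images, cohort$designated_feature)
  z <- if (stats::sd(raw) > 0) (raw - mean(raw)) / stats::sd(raw) else raw * 0

  arm01 <- as.integer(arm == "TACE_S")
  h_ttp <- cohort$baseline_rate *
    exp(cohort$beta_ttp * z + log(cohort$combo_hr) * arm01)
  t_prog <- draws$e_ttp / h_ttp
  h_os <- cohort$os_baseline_rate *
    exp(cohort$beta_os * z + log(cohort$combo_hr) * arm01)
  t_death <- t_prog + draws$e_os / h_os

  ttp_time <- pmin(t_prog, draws$cens)
  ttp_event <- as.integer(t_prog <= draws$cens)
  os_time <- pmin(t_death, draws$cens)
  os_event <- as.integer(t_death <= draws$cens)
  os_lost <- as.integer(draws$lost == 1L & ttp_event == 1L)

  records <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    arm = arm,
    ttp_time = ttp_time, ttp_event = ttp_event,
    os_time = os_time, os_event = os_event,
    os_lost = os_lost,
    draws$covs,
    stringsAsFactors = FALSE
  )
  truth <- list(designated_feature = cohort$designated_feature,
                raw_feature = raw, z = z, u = draws$u,
                beta_ttp = cohort$beta_ttp, beta_os = cohort$beta_os,
                combo_hr = cohort$combo_hr)
  list(images = images, records = records, truth = truth)
}

#' Write / read cohort records as CSV
#'
#' @param records a cohort records `data.frame` (see [generate_cohort()]).
#' @param path file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the records `data.frame`.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  colClasses = c(patient_id = "character",
                                 lesion_n = "character"))
}
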