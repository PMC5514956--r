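# End-to-end selection logic: screen texture features for prognostic value in
# the TACE arm, dichotomize the TACE arm at ROC/Youden thresholds, compare the
# resulting subgroups with the combination arm, adjudicate the best feature
# per endpoint, and validate consistency between endpoints.

CLINICAL_CANDIDATES <- c("age", "sex", "md_mm", "lesion_n", "cirrhosis",
                         "bclc", "cp", "vi_em", "afp_cat", "hepatitis")

#' Join patient records with a feature table
#'
#' @param records cohort records (see [generate_cohort()]).
#' @param feature_table a `feature_table` from [extract_feature_table()].
#' @return A merged `data.frame`, one row per patient record; patients
#'   without extracted features carry `NA` feature values (feature-based
#'   stages only consume the TACE arm, so combination-arm features are
#'   optional).
#' @export
join_features <- function(records, feature_table) {
  merge(records, as.data.frame(feature_table), by = "patient_id",
        sort = FALSE, all.x = TRUE)
}

# rows eligible for an endpoint (OS drops patients lost after progression)
#' @noRd
endpoint_rows <- function(records, endpoint) {
  if (toupper(endpoint) == "OS" && "os_lost" %in% names(records)) {
    records$os_lost != 1L
  } else rep(TRUE, nrow(records))
}

#' Survival-driven texture feature screening
#'
#' Mirrors the study's two-stage screen within the TACE arm: a univariate Cox
#' screen (Wald P < `alpha`) over all 63 texture features and the candidate
#' clinical factors, followed by one forward likelihood-ratio multivariate
#' Cox model per (transform family x pre-filter) block -- up to six models --
#' each offered the screened clinical factors alongside the block's screened
#' texture features.  A block with no screened texture feature is skipped.
#'
#' @param feature_table a `feature_table`.
#' @param records cohort records.
#' @param endpoint `"TTP"` or `"OS"`.
#' @param alpha univariate screening threshold.
#' @return A list with `screen` (the univariate screen table), `block_fits`
#'   (named list of [cox_fit()] per block) and `winners` (texture features
#'   retained in any block model).
#' @export
run_feature_selection <- function(feature_table, records, endpoint,
                                  alpha = 0.10) {
  joined <- join_features(records, feature_table)
  joined <- joined[joined$arm == "TACE" & endpoint_rows(joined, endpoint), ,
                   drop = FALSE]
  cols <- endpoint_cols(endpoint)
  if (nrow(joined) == 0L || sum(joined[[cols["event"]]]) == 0L) {
    stop("no events for endpoint", call. = FALSE)
  }
  feats <- setdiff(names(feature_table), "patient_id")
  clin <- intersect(CLINICAL_CANDIDATES, names(joined))
  clin <- clin[vapply(clin, function(v)
    length(unique(joined[[v]])) > 1L, TRUE)]
  screen <- univariate_screen(joined, endpoint, c(feats, clin), alpha)
  kept <- screen$variable[screen$retained]
  kept_clin <- intersect(kept, clin)
  block_fits <- list()
  winners <- character(0)
  for (fam in c("gabor", "wavelet")) {
    for (fid in FILTER_IDS) {
      blk <- grep(sprintf("^%s-.*@%s$", fam, fid), feats, value = TRUE)
      blk_kept <- intersect(kept, blk)
      if (length(blk_kept) == 0L) next
      fit <- forward_lr_select(joined, endpoint, c(blk_kept, kept_clin))
      key <- sprintf("%s@%s", fam, fid)
      block_fits[[key]] <- fit
      winners <- c(winners, intersect(fit$variables, blk))
    }
  }
  list(screen = screen, block_fits = block_fits,
       winners = unique(winners))
}

#' Dichotomize the TACE arm at a threshold and compare three groups
#'
#' Splits TACE patients at the feature threshold (`<= threshold` is the low
#' group), keeps the combination arm whole, and runs the three-group log-rank
#' test with all pairwise comparisons, plus the two-group Kaplan-Meier /
#' log-rank comparison within the TACE arm.  A degenerate split (one empty
#' TACE subgroup) is flagged and compared as two groups.
#'
#' @param feature canonical feature name (must be a column of `records`, i.e.
#'   records already joined with the feature table).
#' @param threshold dichotomization cut (from [roc_threshold()] on the TACE
#'   arm).
#' @param records joined records (see [join_features()]).
#' @param endpoint `"TTP"` or `"OS"`.
#' @return A list with `assignments` (patient_id, endpoint, feature,
#'   threshold, label in `TACE_low`/`TACE_high`/`COMBO`), `logrank` (the
#'   three-group test, with `pairwise`), `km` (per-label [km_estimate()]
#'   fits), `tace_logrank` (two-group test within TACE, `NULL` if degenerate)
#'   and `degenerate`.
#' @export
dichotomize_and_compare <- function(feature, threshold, records, endpoint) {
  if (!feature %in% names(records)) {
    stop("feature column not found: ", feature, call. = FALSE)
  }
  records <- records[endpoint_rows(records, endpoint), , drop = FALSE]
  cols <- endpoint_cols(endpoint)
  label <- ifelse(records$arm == "TACE_S", "COMBO",
                  ifelse(records[[feature]] <= threshold,
                         "TACE_low", "TACE_high"))
  assignments <- data.frame(patient_id = records$patient_id,
                            endpoint = toupper(endpoint), feature = feature,
                            threshold = threshold, label = label,
                            stringsAsFactors = FALSE)
  present <- unique(label)
  degenerate <- !all(c("TACE_low", "TACE_high") %in% present)
  lr <- logrank_test(records[[cols["time"]]], records[[cols["event"]]],
                     label)
  km <- lapply(split(seq_len(nrow(records)), label), function(idx) {
    km_estimate(records[[cols["time"]]][idx], records[[cols["event"]]][idx])
  })
  tace_lr <- NULL
  if (!degenerate) {
    sel <- label != "COMBO"
    tace_lr <- logrank_test(records[[cols["time"]]][sel],
                            records[[cols["event"]]][sel], label[sel])
  }
  list(assignments = assignments, logrank = lr, km = km,
       tace_logrank = tace_lr, degenerate = degenerate)
}

#' Multivariate Cox over all patients with the three-level subgrouping
#'
#' Fits a Cox model on the full cohort with the subgroup factor (reference
#' `COMBO`) plus any clinical candidate passing a univariate screen at
#' P < 0.10, and reports the likelihood-ratio test of the subgrouping term.
#'
#' @param records joined records.
#' @param assignments assignment `data.frame` from
#'   [dichotomize_and_compare()] (or any data.frame with `patient_id` and
#'   `label`).
#' @param endpoint `"TTP"` or `"OS"`.
#' @return A list with `fit` (a [cox_fit()]; terms `subgroupTACE_low` and
#'   `subgroupTACE_high` are the HRs versus the combination arm) and
#'   `subgroup_lr_p`.
#' @export
all_patient_cox <- function(records, assignments, endpoint) {
  dat <- merge(records, assignments[, c("patient_id", "label")],
               by = "patient_id", sort = FALSE)
  dat <- dat[endpoint_rows(dat, endpoint), , drop = FALSE]
  if (length(unique(dat$label)) < 2L) {
    stop("subgrouping must have at least 2 levels", call. = FALSE)
  }
  dat$subgroup <- stats::relevel(factor(dat$label), ref = "COMBO")
  clin <- intersect(CLINICAL_CANDIDATES, names(dat))
  clin <- clin[vapply(clin, function(v)
    length(unique(dat[[v]])) > 1L, TRUE)]
  screen <- univariate_screen(dat, endpoint, clin, alpha = 0.10)
  keep_clin <- screen$variable[screen$retained]
  fit <- suppressWarnings(cox_fit(dat, endpoint, c("subgroup", keep_clin)))
  red <- suppressWarnings(cox_fit(dat, endpoint,
                                  if (length(keep_clin)) keep_clin else
                                    character(0)))
  ddf <- nrow(fit$terms) - nrow(red$terms)
  lr_p <- stats::pchisq(2 * (fit$loglik - red$loglik), ddf,
                        lower.tail = FALSE)
  list(fit = fit, subgroup_lr_p = lr_p, clinical = keep_clin)
}

#' Consistency of the TTP feature across OS-defined subgroups
#'
#' Compares the TTP-selected feature between the two OS-defined TACE
#' subgroups, routing through normality/homogeneity checks to a t-test or
#' Mann-Whitney U test, and reports group means, SDs and the direction.
#'
#' @param ttp_feature_values numeric feature values for TACE patients.
#' @param os_subgroup_labels two-level labels (low/high OS subgroup) aligned
#'   with `ttp_feature_values`.
#' @return A list with `statistic`, `p`, `method`, `direction`
#'   (`"lower_in_low"` or `"higher_in_low"`), `means` and `sds`.
#' @export
consistency_check <- function(ttp_feature_values, os_subgroup_labels) {
  lab <- as.character(os_subgroup_labels)
  lv <- sort(unique(lab))
  if (length(lv) != 2L) {
    stop("exactly two OS subgroups are required", call. = FALSE)
  }
  a <- ttp_feature_values[lab == lv[1L]]
  b <- ttp_feature_values[lab == lv[2L]]
  if (min(length(a), length(b)) < 3L) {
    stop("insufficient subgroup size", call. = FALSE)
  }
  dc <- distribution_checks(a, b)
  normal <- dc$shapiro_p > 0.05 && dc$shapiro_p2 > 0.05 &&
    !is.na(dc$levene_p) && dc$levene_p > 0.05
  cmp <- group_compare(a, b, if (normal) "t" else "mann_whitney")
  list(statistic = cmp$statistic, p = cmp$p, method = cmp$method,
       direction = if (mean(a) < mean(b)) "lower_in_low" else
         "higher_in_low",
       groups = lv,
       means = c(mean(a), mean(b)), sds = c(stats::sd(a), stats::sd(b)))
}

#' Demographic and baseline summary with between-arm tests
#'
#' Continuous variables are summarised as median (range) per arm with a
#' t-test or Mann-Whitney P (routed by Shapiro-Wilk and Levene checks);
#' categorical variables as counts with percentages (one decimal) and a
#' chi-square P (Fisher's exact for 2x2 tables with small expected counts).
#'
#' @param records cohort records.
#' @return A `data.frame` with one row per variable level: `variable`,
#'   `level`, `all`, `tace`, `combo` and `p` (on the variable's first row).
#' @export
demographic_table <- function(records) {
  arms <- split(seq_len(nrow(records)), records$arm)
  if (!all(c("TACE", "TACE_S") %in% names(arms))) {
    stop("empty group", call. = FALSE)
  }
  ia <- arms$TACE; ib <- arms$TACE_S
  rows <- list()
  cont <- intersect(c("age", "md_mm"), names(records))
  cats <- intersect(c("sex", "lesion_n", "cirrhosis", "bclc", "cp",
                      "vi_em", "afp_cat", "hepatitis"), names(records))
  med_rng <- function(x) sprintf("%g (%g-%g)", stats::median(x), min(x),
                                 max(x))
  for (v in cont) {
    a <- records[[v]][ia]; b <- records[[v]][ib]
    dc <- distribution_checks(a, b)
    normal <- dc$shapiro_p > 0.05 && dc$shapiro_p2 > 0.05 &&
      !is.na(dc$levene_p) && dc$levene_p > 0.05
    cmp <- group_compare(a, b, if (normal) "t" else "mann_whitney")
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, level = "", all = med_rng(records[[v]]),
      tace = med_rng(a), combo = med_rng(b), p = cmp$p,
      stringsAsFactors = FALSE)
  }
  for (v in cats) {
    x <- factor(records[[v]])
    tab <- table(x, records$arm)
    use_fisher <- nrow(tab) == 2L &&
      any(suppressWarnings(stats::chisq.test(tab))$expected < 5)
    cmp <- group_compare(tab, kind = if (use_fisher) "fisher" else
      "chi_square")
    for (k in seq_len(nrow(tab))) {
      cnt <- function(idx) sum(x[idx] == rownames(tab)[k])
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = rownames(tab)[k],
        all = sprintf("%d (%s)", sum(x == rownames(tab)[k]),
                      fmt_pct(sum(x == rownames(tab)[k]), length(x))),
        tace = sprintf("%d (%s)", cnt(ia), fmt_pct(cnt(ia), length(ia))),
        combo = sprintf("%d (%s)", cnt(ib), fmt_pct(cnt(ib), length(ib))),
        p = if (k == 1L) cmp$p else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Select the best stratifying feature for one endpoint
#'
#' For each texture feature retained by [run_feature_selection()], finds the
#' ROC/Youden threshold on the TACE arm (against the endpoint's event
#' indicator), dichotomizes and compares the three groups, and fits the
#' all-patient Cox model with the three-level subgrouping.  A candidate is
#' demoted if its low-value TACE subgroup still differs from the combination
#' arm at P < 0.05 (some suitable patients would remain unidentified); among
#' the remainder, candidates whose subgrouping term is significant in the
#' all-patient Cox model are preferred, with ties broken by the smaller
#' three-group log-rank P.
#'
#' @param feature_table a `feature_table`.
#' @param records cohort records.
#' @param endpoint `"TTP"` or `"OS"`.
#' @return A list with `selection` (output of [run_feature_selection()]),
#'   `candidates` (per-feature list: threshold, comparison, all-patient Cox),
#'   and `best` (the winning feature name, or `NA` if none).
#' @export
select_best_feature <- function(feature_table, records, endpoint) {
  sel <- run_feature_selection(feature_table, records, endpoint)
  joined <- join_features(records, feature_table)
  cols <- endpoint_cols(endpoint)
  cands <- list()
  for (feat in sel$winners) {
    tace <- joined[joined$arm == "TACE" & endpoint_rows(joined, endpoint), ,
                   drop = FALSE]
    thr <- tryCatch(
      roc_threshold(tace[[feat]], tace[[cols["event"]]], feature = feat),
      error = function(e) NULL)
    if (is.null(thr)) next
    cmpr <- dichotomize_and_compare(feat, thr$cut_value, joined, endpoint)
    apc <- tryCatch(all_patient_cox(joined, cmpr$assignments, endpoint),
                    error = function(e) NULL)
    pw <- cmpr$logrank$pairwise
    p_low <- if (!is.null(pw)) {
      pw$p[(pw$group1 == "COMBO" & pw$group2 == "TACE_low") |
             (pw$group1 == "TACE_low" & pw$group2 == "COMBO")]
    } else NA_real_
    p_high <- if (!is.null(pw)) {
      pw$p[(pw$group1 == "COMBO" & pw$group2 == "TACE_high") |
             (pw$group1 == "TACE_high" & pw$group2 == "COMBO")]
    } else NA_real_
    cands[[feat]] <- list(
      feature = feat, threshold = thr,
      comparison = cmpr, all_patient = apc,
      p_low_vs_combo = if (length(p_low)) p_low else NA_real_,
      p_high_vs_combo = if (length(p_high)) p_high else NA_real_,
      demoted = isTRUE(!is.na(p_low) && length(p_low) > 0 &&
                         p_low < 0.05))
  }
  surv <- Filter(function(cc) !cc$demoted, cands)
  best <- NA_character_
  if (length(surv)) {
    sig <- Filter(function(cc) !is.null(cc$all_patient) &&
                    !is.na(cc$all_patient$subgroup_lr_p) &&
                    cc$all_patient$subgroup_lr_p < 0.05, surv)
    pool <- if (length(sig)) sig else surv
    lrp <- vapply(pool, function(cc) cc$comparison$logrank$p, 0)
    best <- names(pool)[which.min(lrp)]
  }
  list(selection = sel, candidates = cands, best = best)
}

#' Full two-endpoint selection report
#'
#' Runs [select_best_feature()] for TTP and OS, and when both endpoints
#' produce a winner, checks their consistency: the TTP feature is compared
#' between the OS-defined TACE subgroups via [consistency_check()].
#'
#' @param feature_table a `feature_table`.
#' @param records cohort records.
#' @return An object of class `selection_report`: per-endpoint results,
#'   `consistency`, and a short `recommendation` naming the selected
#'   features and thresholds.
#' @export
selection_report <- function(feature_table, records) {
  ttp <- select_best_feature(feature_table, records, "TTP")
  os <- tryCatch(select_best_feature(feature_table, records, "OS"),
                 error = function(e) NULL)
  consistency <- NULL
  if (!is.na(ttp$best) && !is.null(os) && !is.na(os$best)) {
    joined <- join_features(records, feature_table)
    tace <- joined[joined$arm == "TACE" & endpoint_rows(joined, "OS"), ,
                   drop = FALSE]
    os_thr <- os$candidates[[os$best]]$threshold$cut_value
    lab <- ifelse(tace[[os$best]] <= os_thr, "OS_low", "OS_high")
    consistency <- tryCatch(consistency_check(tace[[ttp$best]], lab),
                            error = function(e) NULL)
  }
  rec <- if (is.na(ttp$best)) {
    "No texture feature met the selection criteria for TTP."
  } else {
    sprintf(paste(
      "Patients with %s above %.4f are predicted to progress earlier under",
      "TACE alone and are candidates for TACE plus sorafenib."),
      ttp$best, ttp$candidates[[ttp$best]]$threshold$cut_value)
  }
  out <- list(ttp = ttp, os = os, consistency = consistency,
              recommendation = rec)
  class(out) <- "selection_report"
  out
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  cat("  TTP winner:", x$ttp$best, "\n")
  if (!is.null(x$os)) cat("  OS winner: ", x$os$best, "\n")
  if (!is.null(x$consistency)) {
    cat(sprintf("  consistency: P = %.3f (%s)\n", x$consistency$p,
                x$consistency$method))
  }
  cat("  ", x$recommendation, "\n")
  invisible(x)
}

#' Run the full pipeline from a configuration file
#'
#' The configuration is a JSON object.  In demo mode (`"mode": "demo"`) a
#' synthetic cohort is generated with the packaged defaults (`n_tace`,
#' `n_combo` and `seed` configurable); in data mode, `image_dir`, `mask_dir`
#' and `cohort_csv` point to 16-bit PNG images (`<patient_id>.png` plus
#' sidecar JSON), 8-bit mask PNGs (`<patient_id>_mask.png`) and the cohort
#' CSV.  `filters` (optional) must list exactly three pre-filter ids.
#' Outputs written to `outdir`: `features.csv`, `fits.json`,
#' `thresholds.json`, `assignments.csv`, `report.json` and `run.log`.
#'
#' @param config_path path to the JSON configuration.
#' @param seed overrides the configured seed.
#' @param outdir overrides the configured output directory.
#' @return The [selection_report()] (invisibly).
#' @export
cli_run <- function(config_path, seed = NULL, outdir = NULL) {
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  mode <- if (is.null(cfg$mode)) "demo" else cfg$mode
  if (!is.null(cfg$filters)) {
    if (length(cfg$filters) != 3L) {
      stop("`filters` must list exactly 3 pre-filters", call. = FALSE)
    }
    filters <- lapply(as.character(cfg$filters), filter_spec)
  } else filters <- default_filters()
  if (is.null(seed)) seed <- if (is.null(cfg$seed)) 1L else cfg$seed
  if (is.null(outdir)) {
    outdir <- if (is.null(cfg$outdir)) stop("`outdir` is required",
                                            call. = FALSE) else cfg$outdir
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  if (identical(mode, "demo")) {
    cp <- cohort_params(
      n_tace = if (is.null(cfg$n_tace)) 80L else cfg$n_tace,
      n_combo = if (is.null(cfg$n_combo)) 40L else cfg$n_combo,
      seed = seed)
    cohort <- generate_cohort(cohort = cp)
    images <- cohort$images
    records <- cohort$records
  } else {
    records <- read_cohort_csv(cfg$cohort_csv)
    img_files <- file.path(cfg$image_dir,
                           paste0(records$patient_id, ".png"))
    mask_files <- file.path(cfg$mask_dir,
                            paste0(records$patient_id, "_mask.png"))
    missing_mask <- records$patient_id[!file.exists(mask_files)]
    if (length(missing_mask)) {
      stop("missing mask for patients: ",
           paste(missing_mask, collapse = ", "), call. = FALSE)
    }
    missing_img <- records$patient_id[!file.exists(img_files)]
    if (length(missing_img)) {
      stop("missing image for patients: ",
           paste(missing_img, collapse = ", "), call. = FALSE)
    }
    images <- Map(read_roi_png, img_files, mask_files)
  }

  ft <- extract_feature_table(images, records$patient_id, filters = filters)
  write_feature_table(ft, file.path(outdir, "features.csv"))
  rep <- selection_report(ft, records)

  fit_json <- function(sbf) {
    if (is.null(sbf)) return(NULL)
    list(winners = sbf$selection$winners, best = sbf$best,
         blocks = lapply(sbf$selection$block_fits, function(f) f$terms))
  }
  jsonlite::write_json(list(TTP = fit_json(rep$ttp), OS = fit_json(rep$os)),
                       file.path(outdir, "fits.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  thr <- lapply(c(rep$ttp$candidates,
                  if (!is.null(rep$os)) rep$os$candidates), function(cc) {
    t <- cc$threshold
    list(feature = t$feature, cut_value = t$cut_value,
         sensitivity = t$sensitivity, specificity = t$specificity,
         youden_j = t$youden_j, auc = t$auc)
  })
  jsonlite::write_json(thr, file.path(outdir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA)
  asg <- do.call(rbind, lapply(
    Filter(Negate(is.null), list(
      if (!is.na(rep$ttp$best)) rep$ttp$candidates[[rep$ttp$best]] else NULL,
      if (!is.null(rep$os) && !is.na(rep$os$best))
        rep$os$candidates[[rep$os$best]] else NULL)),
    function(cc) cc$comparison$assignments))
  if (!is.null(asg)) {
    utils::write.csv(asg, file.path(outdir, "assignments.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(ttp_best = rep$ttp$best,
         os_best = if (is.null(rep$os)) NA else rep$os$best,
         recommendation = rep$recommendation,
         consistency_p = if (is.null(rep$consistency)) NA else
           rep$consistency$p),
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
  writeLines(c(
    sprintf("texstrat %s | R %s", as.character(utils::packageVersion("texstrat")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("config: %s", normalizePath(config_path)),
    sprintf("mode: %s | seed: %s | outdir: %s", mode, seed, outdir),
    sprintf("filters: %s",
            paste(vapply(filters, function(f) f$filter_id, ""),
                  collapse = ", ")),
    sprintf("patients: %d | features: %d", nrow(records), ncol(ft) - 1L),
    sprintf("finished: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
    file.path(outdir, "run.log"))
  invisible(rep)
}
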