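# One seeded end-to-end planted-effect run: generate a two-arm cohort whose
# progression hazard is driven by gabor-1-90@0 (unit-SD effect beta = 1),
# extract the full 63-feature table for the TACE arm, run the
# screen -> forward-LR -> ROC -> three-group comparison chain, and summarise
# what the planted-effect recovery properties need.  48 x 48 images keep the
# 100-run suite within its time budget (the hazard is coupled to the measured
# feature, so the coupling is exact at any image size).
planted_chain_run <- function(seed, n_tace = 400, n_combo = 100) {
  cc <- generate_cohort(
    texture_params(size_px = 48, correlation_length_px = 2),
    texture_params(size_px = 48, correlation_length_px = 6,
                   anisotropy_ratio = 2.5),
    cohort_params(n_tace = n_tace, n_combo = n_combo, seed = seed))
  tace_ids <- cc$records$patient_id[cc$records$arm == "TACE"]
  ft <- extract_feature_table(cc$images[cc$records$arm == "TACE"], tace_ids)
  res <- select_best_feature(ft, cc$records, "TTP")
  joined <- join_features(cc$records, ft)
  tace <- joined[joined$arm == "TACE", ]
  thr <- roc_threshold(tace[["gabor-1-90@0"]], tace$ttp_event)
  cmp <- dichotomize_and_compare("gabor-1-90@0", thr$cut_value, joined,
                                 "TTP")
  pw <- cmp$logrank$pairwise
  pair_p <- function(g) {
    pw$p[(pw$group1 == "COMBO" & pw$group2 == g) |
           (pw$group1 == g & pw$group2 == "COMBO")]
  }
  vals <- tace[["gabor-1-90@0"]]
  list(best = res$best,
       winners = res$selection$winners,
       planted_retained = "gabor-1-90@0" %in% res$selection$winners,
       p_high = pair_p("TACE_high"),
       p_low = pair_p("TACE_low"),
       cut_z = (thr$cut_value - stats::median(vals)) / stats::sd(vals))
}
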