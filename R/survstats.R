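# Inferential primitives: Kaplan-Meier, log-rank, Cox regression (univariate
# screening and forward likelihood-ratio model building), ROC/Youden
# cut-points, two-group comparisons and distribution checks.

#' Endpoint column lookup
#' @noRd
endpoint_cols <- function(endpoint) {
  endpoint <- toupper(endpoint)
  switch(endpoint,
         TTP = c(time = "ttp_time", event = "ttp_event"),
         OS = c(time = "os_time", event = "os_event"),
         stop("`endpoint` must be \"TTP\" or \"OS\"", call. = FALSE))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators.
#' @return An object of class `km_fit` with `time`, `n_risk`, `n_event`,
#'   `surv` (the product-limit estimate after each distinct event time) and
#'   `surv_at(t)`, a right-continuous step-function evaluator starting at 1.
#' @examples
#' km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
#' km$surv_at(2.5)
#' @export
km_estimate <- function(times, events) {
  check_surv(times, events)
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- list(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
              surv = sf$surv)
  out$surv_at <- function(t) {
    vapply(t, function(tt) {
      idx <- which(out$time <= tt)
      if (length(idx) == 0L) 1 else out$surv[max(idx)]
    }, 0)
  }
  class(out) <- "km_fit"
  out
}

#' @noRd
check_surv <- function(times, events) {
  if (length(times) != length(events) || length(times) == 0L) {
    stop("`times` and `events` must be equal-length and non-empty",
         call. = FALSE)
  }
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  if (!all(events %in% c(0, 1))) {
    stop("events must be binary 0/1", call. = FALSE)
  }
  invisible(NULL)
}

#' Log-rank test (two or more groups, with pairwise tests for three)
#'
#' Standard observed-minus-expected log-rank statistic with `k - 1` degrees
#' of freedom.  With three groups, all pairwise two-group log-rank tests are
#' returned without multiplicity adjustment.
#'
#' @param times,events survival data as in [km_estimate()].
#' @param groups group labels (>= 2 non-empty groups).
#' @return A list with `chi2`, `df`, `p`, and for three groups `pairwise`,
#'   a data.frame of group pairs with their chi-square and P-values.
#' @examples
#' logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("a", "a", "b", "b"))
#' @export
logrank_test <- function(times, events, groups) {
  check_surv(times, events)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) < 2L) stop("at least 2 groups are required", call. = FALSE)
  # identical survival experience in all groups: survdiff errors on a
  # zero-variance statistic only in degenerate cases; handle chi2 = 0 cleanly
  sd0 <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(lv) - 1L
  out <- list(chi2 = unname(sd0$chisq), df = df,
              p = stats::pchisq(unname(sd0$chisq), df, lower.tail = FALSE))
  if (length(lv) == 3L) {
    pw <- t(utils::combn(lv, 2L))
    res <- apply(pw, 1L, function(pair) {
      sel <- groups %in% pair
      s <- survival::survdiff(
        survival::Surv(times[sel], events[sel]) ~ groups[sel])
      c(chi2 = unname(s$chisq),
        p = stats::pchisq(unname(s$chisq), 1L, lower.tail = FALSE))
    })
    out$pairwise <- data.frame(group1 = pw[, 1L], group2 = pw[, 2L],
                               chi2 = res["chi2", ], p = res["p", ],
                               stringsAsFactors = FALSE)
  }
  out
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood with Efron tie handling.  Monotone
#' likelihood (perfect separation) is flagged as non-convergence and the
#' coefficients are still reported, with a warning.
#'
#' @param records a patient records `data.frame` (see [generate_cohort()]),
#'   possibly joined with texture feature columns.
#' @param endpoint `"TTP"` or `"OS"`.
#' @param covariates character vector of column names (numeric or
#'   categorical) to include.
#' @return An object of class `cox_fit`: a list with `terms` (a `data.frame`
#'   of coefficient, HR, 95% CI, Wald P per estimated coefficient),
#'   `variables`, `loglik` (null and final log partial likelihood),
#'   `converged`, `n`, `n_event` and `wald_p` (per-variable overall Wald P).
#' @examples
#' cc <- generate_cohort(cohort = cohort_params(n_tace = 40, n_combo = 20,
#'                                              seed = 2))
#' fit <- cox_fit(cc$records, "TTP", "age")
#' fit$terms
#' @export
cox_fit <- function(records, endpoint, covariates) {
  cols <- endpoint_cols(endpoint)
  times <- records[[cols["time"]]]
  events <- records[[cols["event"]]]
  check_surv(times, events)
  if (sum(events) < 1L) stop("no events for endpoint", call. = FALSE)
  covariates <- as.character(covariates)
  if (length(covariates) == 0L) {
    null_ll <- survival::coxph(survival::Surv(times, events) ~ 1)$loglik
    out <- list(terms = data.frame(term = character(), coef = numeric(),
                                   hr = numeric(), ci_low = numeric(),
                                   ci_high = numeric(), p = numeric(),
                                   stringsAsFactors = FALSE),
                variables = character(), loglik_null = null_ll,
                loglik = null_ll, converged = TRUE,
                n = length(times), n_event = sum(events),
                wald_p = stats::setNames(numeric(0), character(0)))
    class(out) <- "cox_fit"
    return(out)
  }
  miss <- setdiff(covariates, names(records))
  if (length(miss)) {
    stop("covariates not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (v in covariates) {
    x <- records[[v]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      stop("covariate constant across subjects: ", v, call. = FALSE)
    }
  }
  dat <- records[, covariates, drop = FALSE]
  for (v in covariates) if (is.character(dat[[v]])) {
    dat[[v]] <- factor(dat[[v]])
  }
  dat$.time <- times; dat$.event <- events
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w))) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    })
  if (!converged) {
    warning("monotone likelihood or singular fit; coefficients unreliable",
            call. = FALSE)
  }
  sm <- summary(fit)
  co <- stats::coef(fit)
  keep <- !is.na(co)
  se <- sqrt(diag(fit$var))[keep]
  co <- co[keep]
  terms <- data.frame(
    term = names(co),
    coef = unname(co),
    hr = unname(exp(co)),
    ci_low = unname(exp(co - stats::qnorm(0.975) * se)),
    ci_high = unname(exp(co + stats::qnorm(0.975) * se)),
    p = unname(2 * stats::pnorm(-abs(co / se))),
    stringsAsFactors = FALSE)
  asg <- fit$assign
  wald_p <- vapply(seq_along(asg), function(i) {
    idx <- asg[[i]]
    idx <- idx[!is.na(stats::coef(fit))[idx]]
    if (length(idx) == 0L) return(NA_real_)
    b <- stats::coef(fit)[idx]
    v <- fit$var[idx, idx, drop = FALSE]
    stat <- tryCatch(drop(t(b) %*% solve(v, b)), error = function(e) NA_real_)
    stats::pchisq(stat, length(idx), lower.tail = FALSE)
  }, 0)
  names(wald_p) <- names(asg)
  out <- list(terms = terms, variables = covariates,
              loglik_null = fit$loglik[1L], loglik = fit$loglik[2L],
              converged = converged, n = fit$n, n_event = fit$nevent,
              wald_p = wald_p)
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, loglik = %.3f%s\n",
              x$n, x$n_event, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  if (nrow(x$terms)) {
    tt <- x$terms
    tt$hr_ci <- sprintf("%.3f (%.3f-%.3f)", tt$hr, tt$ci_low, tt$ci_high)
    print(tt[, c("term", "coef", "hr_ci", "p")], row.names = FALSE)
  } else cat("  (no variables)\n")
  invisible(x)
}

#' Univariate Cox screening
#'
#' Fits one single-covariate Cox model per candidate and retains candidates
#' whose overall Wald P-value is below `alpha`, preserving the input order.
#'
#' @inheritParams cox_fit
#' @param candidates character vector of candidate column names.
#' @param alpha retention threshold on the Wald P-value.
#' @return A `data.frame` with `variable`, `p` and `retained`, ordered as the
#'   input candidates.
#' @export
univariate_screen <- function(records, endpoint, candidates, alpha = 0.10) {
  candidates <- as.character(candidates)
  cols <- endpoint_cols(endpoint)
  y <- survival::Surv(records[[cols["time"]]], records[[cols["event"]]])
  ctrl <- survival::coxph.control(eps = 1e-9, iter.max = 100)
  p <- vapply(candidates, function(v) {
    x <- records[[v]]
    if (is.numeric(x) && stats::sd(x) > 0) {
      # single numeric covariate: call the fitting engine directly (same
      # estimates as coxph, without the model-frame overhead)
      fit <- tryCatch(
        suppressWarnings(survival::coxph.fit(
          matrix(x, ncol = 1), y, strata = NULL, offset = NULL,
          init = 0, control = ctrl, weights = NULL, method = "efron",
          rownames = NULL)),
        error = function(e) NULL)
      if (is.null(fit) || is.na(fit$coefficients[1L])) return(NA_real_)
      stats::pchisq(fit$coefficients[1L]^2 / fit$var[1L, 1L], 1L,
                    lower.tail = FALSE)
    } else {
      fit <- tryCatch(suppressWarnings(cox_fit(records, endpoint, v)),
                      error = function(e) NULL)
      if (is.null(fit) || length(fit$wald_p) == 0L) NA_real_ else
        unname(fit$wald_p[1L])
    }
  }, 0)
  data.frame(variable = candidates, p = unname(p),
             retained = !is.na(p) & p < alpha,
             stringsAsFactors = FALSE)
}

#' @noRd
cox_loglik <- function(records, endpoint, covariates) {
  fit <- suppressWarnings(cox_fit(records, endpoint, covariates))
  # degrees of freedom: number of estimated coefficients
  list(ll = fit$loglik, df = nrow(fit$terms), fit = fit)
}

#' Forward stepwise Cox selection by likelihood-ratio tests
#'
#' Iteratively adds the candidate with the smallest likelihood-ratio P-value
#' below `p_enter`, then removes any included variable whose likelihood-ratio
#' P-value rises above `p_remove`, until a fixed point.  Ties are broken by
#' candidate order, so the procedure is deterministic.  Candidates that fail
#' to add estimable coefficients (e.g. collinear duplicates of an included
#' variable) are skipped.
#'
#' @inheritParams univariate_screen
#' @param p_enter entry threshold on the likelihood-ratio P-value.
#' @param p_remove removal threshold (must exceed `p_enter`).
#' @return A [cox_fit()] for the selected model; with no selected variables,
#'   a zero-variable fit (not an error).
#' @export
forward_lr_select <- function(records, endpoint, candidates,
                              p_enter = 0.05, p_remove = 0.10) {
  if (p_remove < p_enter) {
    stop("`p_remove` must be >= `p_enter`", call. = FALSE)
  }
  candidates <- as.character(candidates)
  included <- character(0)
  cur <- cox_loglik(records, endpoint, included)
  for (step in seq_len(50L)) {
    changed <- FALSE
    pool <- setdiff(candidates, included)
    if (length(pool)) {
      trial <- lapply(pool, function(v) {
        tryCatch(cox_loglik(records, endpoint, c(included, v)),
                 error = function(e) NULL)
      })
      pv <- vapply(seq_along(pool), function(i) {
        tr <- trial[[i]]
        if (is.null(tr)) return(NA_real_)
        ddf <- tr$df - cur$df
        if (ddf < 1L) return(NA_real_)
        stats::pchisq(2 * (tr$ll - cur$ll), ddf, lower.tail = FALSE)
      }, 0)
      ok <- which(!is.na(pv) & pv < p_enter)
      if (length(ok)) {
        best <- ok[which.min(pv[ok])]
        included <- c(included, pool[best])
        cur <- trial[[best]]
        changed <- TRUE
      }
    }
    # backward pass: drop any variable whose LR P exceeds p_remove
    repeat {
      if (length(included) == 0L) break
      drop_p <- vapply(included, function(v) {
        red <- cox_loglik(records, endpoint, setdiff(included, v))
        ddf <- cur$df - red$df
        if (ddf < 1L) return(0)
        stats::pchisq(2 * (cur$ll - red$ll), ddf, lower.tail = FALSE)
      }, 0)
      worst <- which.max(drop_p)
      if (drop_p[worst] > p_remove) {
        included <- setdiff(included, included[worst])
        cur <- cox_loglik(records, endpoint, included)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  cur$fit
}

#' ROC curve threshold by the Youden index
#'
#' Builds the empirical ROC of `values` against a binary outcome over all
#' midpoints between adjacent sorted unique values, assuming higher values
#' indicate the positive class, and returns the cut maximizing Youden's
#' J = sensitivity + specificity - 1 (ties broken toward the lower cut).
#' The low/high dichotomization used downstream is `value <= cut` versus
#' `value > cut`.
#'
#' @param values numeric marker values.
#' @param outcome binary 0/1 outcome; both classes must be present.
#' @param feature optional feature name carried into the result.
#' @return An object of class `threshold_result`: `feature`, `cut_value`,
#'   `sensitivity`, `specificity`, `youden_j` and `auc` (rank-based,
#'   ties counted half).
#' @examples
#' roc_threshold(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
roc_threshold <- function(values, outcome, feature = NA_character_) {
  if (length(values) != length(outcome)) {
    stop("`values` and `outcome` must have equal length", call. = FALSE)
  }
  if (!all(outcome %in% c(0, 1)) || length(unique(outcome)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  u <- sort(unique(values))
  if (length(u) < 2L) stop("values are constant", call. = FALSE)
  cuts <- (u[-1L] + u[-length(u)]) / 2
  case <- values[outcome == 1]
  ctrl <- values[outcome == 0]
  sens <- vapply(cuts, function(ct) mean(case > ct), 0)
  spec <- vapply(cuts, function(ct) mean(ctrl <= ct), 0)
  j <- sens + spec - 1
  best <- which(j == max(j))[1L]   # ties toward the lower cut
  r <- rank(values, ties.method = "average")
  n1 <- length(case); n0 <- length(ctrl)
  auc <- (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  out <- list(feature = feature, cut_value = cuts[best],
              sensitivity = sens[best], specificity = spec[best],
              youden_j = j[best], auc = auc)
  class(out) <- "threshold_result"
  out
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result> %s cut = %.4f (sens %.3f, spec %.3f, J %.3f, AUC %.3f)\n",
    if (is.na(x$feature)) "" else x$feature, x$cut_value, x$sensitivity,
    x$specificity, x$youden_j, x$auc))
  invisible(x)
}

#' Two-group comparison tests
#'
#' Two-sided comparisons used for demographics and subgroup validation.  The
#' t-test assumes equal variances when Levene's test (centered at the mean)
#' has P > 0.05 and uses the Welch correction otherwise.  `chi_square` and
#' `fisher` take a contingency table (matrix) as `a`, or two categorical
#' vectors to be cross-tabulated.
#'
#' @param a,b continuous samples, or for count tests a contingency matrix in
#'   `a` (with `b` omitted) / two categorical vectors.
#' @param kind one of `"t"`, `"mann_whitney"`, `"chi_square"`, `"fisher"`.
#' @return A list with `statistic`, `p` and `method`.
#' @examples
#' group_compare(rnorm(20), rnorm(20), "t")
#' group_compare(matrix(c(74, 123, 17, 47), 2, byrow = TRUE),
#'               kind = "fisher")
#' @export
group_compare <- function(a, b = NULL,
                          kind = c("t", "mann_whitney", "chi_square",
                                   "fisher")) {
  kind <- match.arg(kind)
  if (kind %in% c("t", "mann_whitney")) {
    if (is.null(b)) stop("two samples are required", call. = FALSE)
    if (kind == "t") {
      lev <- distribution_checks(a, b)$levene_p
      eq <- !is.na(lev) && lev > 0.05
      tt <- stats::t.test(a, b, var.equal = eq)
      return(list(statistic = unname(tt$statistic), p = tt$p.value,
                  method = if (eq) "t (pooled)" else "t (Welch)"))
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    return(list(statistic = unname(wt$statistic), p = wt$p.value,
                method = "Mann-Whitney U"))
  }
  tab <- if (is.matrix(a)) a else table(a, b)
  if (kind == "chi_square") {
    ct <- suppressWarnings(stats::chisq.test(tab))
    list(statistic = unname(ct$statistic), p = ct$p.value,
         method = "chi-square")
  } else {
    ft <- stats::fisher.test(tab)
    list(statistic = NA_real_, p = ft$p.value, method = "Fisher exact")
  }
}

#' Normality and variance-homogeneity checks
#'
#' Shapiro-Wilk normality P-value for one sample, and (given a second
#' sample) Levene's test for homogeneity of variance centered at the group
#' means.  Used to route [group_compare()] between the t-test and the
#' Mann-Whitney U test.
#'
#' @param x numeric sample (n >= 3).
#' @param y optional second sample.
#' @return A list with `shapiro_p` (and `shapiro_p2` for the second sample)
#'   and `levene_p` (`NA` without a second sample).
#' @export
distribution_checks <- function(x, y = NULL) {
  if (length(x) < 3L) stop("n >= 3 required", call. = FALSE)
  out <- list(shapiro_p = stats::shapiro.test(x)$p.value, levene_p = NA_real_)
  if (!is.null(y)) {
    if (length(y) < 3L) stop("n >= 3 required", call. = FALSE)
    out$shapiro_p2 <- stats::shapiro.test(y)$p.value
    dat <- data.frame(v = c(x, y),
                      g = factor(rep(c("a", "b"), c(length(x), length(y)))))
    lt <- car::leveneTest(v ~ g, data = dat, center = mean)
    out$levene_p <- lt[["Pr(>F)"]][1L]
  }
  out
}

#' Percentage formatting used in reports
#'
#' @param x numerator count.
#' @param n denominator count.
#' @param digits decimal places (reports use 1; whole-percent summaries 0).
#' @return Character scalar such as `"37.6%"`.
#' @examples
#' fmt_pct(74, 197)
#' @export
fmt_pct <- function(x, n, digits = 1) {
  sprintf("%.*f%%", digits, 100 * x / n)
}
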