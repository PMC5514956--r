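# Survival statistics: KM, log-rank, Cox, stepwise selection, ROC, group
# comparisons.

test_that("KM equals 1 - ECDF without censoring and hand product-limit", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv_at(2.5), 0.5)
  expect_equal(km$surv_at(0.5), 1)
  expect_equal(km$surv_at(4), 0)
  set.seed(1)
  t <- rexp(40)
  km2 <- km_estimate(t, rep(1, 40))
  for (q in quantile(t, c(0.2, 0.5, 0.9))) {
    expect_equal(km2$surv_at(q), 1 - mean(t <= q))
  }
  # all censored
  km3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km3$surv_at(100), 1)
  # one censored observation: oracle by explicit risk-set enumeration
  km4 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km4$surv_at(3), oracle_km(c(1, 2, 3), c(1, 0, 1), 3))
  expect_equal(km4$surv_at(2.5), 2 / 3)
  expect_equal(km4$surv_at(3), 0)
})

test_that("log-rank separates extremes and vanishes on identical groups", {
  t <- c(1:20 / 10, 5 + 1:20 / 10)
  g <- rep(c("a", "b"), each = 20)
  lr <- logrank_test(t, rep(1, 40), g)
  expect_lt(lr$p, 0.001)
  # two identical copies of one sample
  set.seed(2)
  s <- rexp(15); e <- rbinom(15, 1, 0.7); e[1] <- 1
  lr0 <- logrank_test(c(s, s), c(e, e), rep(c("a", "b"), each = 15))
  expect_lt(lr0$chi2, 1e-9)
  expect_error(logrank_test(s, e, rep("a", 15)), "2 groups")
})

test_that("log-rank is invariant under monotone time transforms", {
  set.seed(3)
  t <- rexp(60); e <- rbinom(60, 1, 0.8); g <- rep(c("a", "b"), 30)
  a <- logrank_test(t, e, g)
  b <- logrank_test(log1p(t) + 2, e, g)
  expect_equal(a$chi2, b$chi2, tolerance = 1e-12)
})

test_that("three-group log-rank reports unadjusted pairwise tests", {
  set.seed(4)
  t <- rexp(90); e <- rep(1, 90); g <- rep(c("a", "b", "c"), 30)
  lr <- logrank_test(t, e, g)
  expect_equal(lr$df, 2L)
  expect_equal(nrow(lr$pairwise), 3L)
  sel <- g %in% c("a", "b")
  two <- logrank_test(t[sel], e[sel], g[sel])
  row <- lr$pairwise[lr$pairwise$group1 %in% c("a", "b") &
                       lr$pairwise$group2 %in% c("a", "b"), ]
  expect_equal(row$chi2, two$chi2, tolerance = 1e-12)
})

test_that("cox_fit matches the brute-force partial-likelihood oracle", {
  fixtures <- list(
    list(t = c(2, 4, 1, 5, 3), e = c(1, 0, 1, 1, 1),
         x = c(0.5, -1, 2, 0, 1)),
    list(t = c(1, 2, 3, 4, 5, 6), e = c(1, 1, 0, 1, 1, 0),
         x = c(0.3, -0.2, 0.8, -1, 0.1, 0.5)),
    list(t = c(3, 1, 4, 2), e = c(1, 1, 1, 0), x = c(-1, 1, 0.5, 2)),
    list(t = c(1, 3, 2, 5, 4, 6), e = c(1, 1, 1, 1, 1, 1),
         x = c(0.2, 1.4, -0.7, 0.9, -1.1, 0.4)))
  for (fx in fixtures) {
    rec <- data.frame(ttp_time = fx$t, ttp_event = fx$e, x = fx$x)
    fit <- cox_fit(rec, "TTP", "x")
    bhat <- oracle_cox_grid(fx$t, fx$e, fx$x)
    expect_lt(abs(bhat), 4.9)   # interior maximum, grid is informative
    expect_lt(abs(fit$terms$coef - bhat), 1e-3)
    expect_equal(fit$terms$hr, exp(fit$terms$coef), tolerance = 1e-9)
    expect_true(fit$terms$ci_low <= fit$terms$ci_high)
  }
  # the 4-subject toy set with covariate (1,1,0,0) and all events has a
  # monotone partial likelihood: the enumerated log-likelihood increases all
  # the way to the grid edge and the fit reports non-convergence
  t4 <- c(1, 2, 3, 4); e4 <- rep(1, 4); x4 <- c(1, 1, 0, 0)
  ll <- vapply(c(4, 4.5, 5), oracle_cox_loglik, 0, times = t4, events = e4,
               x = x4)
  expect_true(all(diff(ll) > 0))
  expect_warning(fit4 <- cox_fit(data.frame(ttp_time = t4, ttp_event = e4,
                                            x = x4), "TTP", "x"))
  expect_false(fit4$converged)
})

test_that("cox_fit is reparameterization-consistent", {
  set.seed(5)
  rec <- data.frame(ttp_time = rexp(80), ttp_event = rbinom(80, 1, 0.8),
                    x = rnorm(80))
  rec$x10 <- rec$x * 10
  a <- cox_fit(rec, "TTP", "x")
  b <- cox_fit(rec, "TTP", "x10")
  expect_equal(b$terms$coef, a$terms$coef / 10, tolerance = 1e-8)
  expect_equal(a$loglik, b$loglik, tolerance = 1e-9)
})

test_that("cox_fit flags monotone likelihood and rejects degenerate input", {
  rec <- data.frame(ttp_time = c(1, 2, 3, 4, 5, 6),
                    ttp_event = rep(1, 6),
                    x = c(1, 1, 1, 0, 0, 0))
  expect_warning(fit <- cox_fit(rec, "TTP", "x"), "monotone|unreliable")
  expect_false(fit$converged)
  rec0 <- data.frame(ttp_time = 1:4, ttp_event = rep(1, 4), x = rep(2, 4))
  expect_error(cox_fit(rec0, "TTP", "x"), "constant")
  rec1 <- data.frame(ttp_time = 1:4, ttp_event = rep(0, 4), x = rnorm(4))
  expect_error(cox_fit(rec1, "TTP", "x"), "no events")
})

test_that("cox_fit on a null binary covariate is well calibrated", {
  cover <- vapply(1:100, function(i) {
    set.seed(600 + i)
    n <- 500
    x <- rbinom(n, 1, 0.5)
    rec <- data.frame(ttp_time = rexp(n), ttp_event = 1, x = x)
    fit <- cox_fit(rec, "TTP", "x")
    c(abs(fit$terms$coef) < 0.2,
      fit$terms$ci_low <= 1 && fit$terms$ci_high >= 1)
  }, c(TRUE, TRUE))
  expect_gte(sum(cover[2, ]), 90)
  expect_gte(mean(cover[1, ]), 0.9)
})

test_that("univariate screening retains by Wald P in input order", {
  set.seed(6)
  rec <- make_records(300, beta = 1)
  rec$noise1 <- rnorm(300); rec$noise2 <- rnorm(300)
  sc <- univariate_screen(rec, "TTP", c("noise1", "z", "noise2"),
                          alpha = 0.10)
  expect_identical(sc$variable, c("noise1", "z", "noise2"))
  expect_true(sc$retained[sc$variable == "z"])
  sc_all <- univariate_screen(rec, "TTP", c("noise1", "z"), alpha = 1)
  expect_true(all(sc_all$retained))
  # fast numeric path agrees with the generic path
  p_ref <- unname(cox_fit(rec, "TTP", "noise1")$wald_p[1])
  expect_equal(sc$p[1], p_ref, tolerance = 1e-12)
})

test_that("forward LR selection finds a planted effect among noise", {
  hits <- vapply(1:100, function(i) {
    set.seed(2500 + i)
    n <- 400
    rec <- make_records(n, beta = 0.8)
    noise <- as.data.frame(matrix(rnorm(n * 19), n))
    names(noise) <- paste0("f", 1:19)
    rec <- cbind(rec, noise)
    fit <- forward_lr_select(rec, "TTP", c(paste0("f", 1:19), "z"))
    "z" %in% fit$variables
  }, TRUE)
  expect_gte(sum(hits), 90)
})

test_that("forward LR selection stays near-empty on pure noise", {
  empty <- vapply(1:60, function(i) {
    set.seed(3500 + i)
    n <- 150
    rec <- make_records(n, beta = 0)
    noise <- as.data.frame(matrix(rnorm(n * 10), n))
    names(noise) <- paste0("f", 1:10)
    rec <- cbind(rec, noise)
    fit <- forward_lr_select(rec, "TTP", paste0("f", 1:10))
    length(fit$variables) == 0L
  }, TRUE)
  # roughly (1 - 0.05)^10 = 60%, wide tolerance
  expect_gt(mean(empty), 0.35)
})

test_that("a duplicated candidate is never double-selected", {
  set.seed(7)
  rec <- make_records(300, beta = 1)
  rec$z_copy <- rec$z
  fit <- forward_lr_select(rec, "TTP", c("z", "z_copy"))
  expect_lte(length(fit$variables), 1L)
  expect_equal(fit$variables, "z")
})

test_that("roc_threshold finds planted cuts and respects invariances", {
  r <- roc_threshold(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$cut_value, 2.5)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$youden_j, 1)
  expect_equal(r$auc, 1)

  vals <- 1:10
  out <- as.integer(vals > 7)
  r2 <- roc_threshold(vals, out)
  expect_gt(r2$cut_value, 7)
  expect_lt(r2$cut_value, 8)

  # Youden J invariant under strictly monotone transforms
  set.seed(8)
  v <- rnorm(60); o <- rbinom(60, 1, plogis(v))
  if (length(unique(o)) < 2) o[1:2] <- c(0, 1)
  a <- roc_threshold(v, o)
  b <- roc_threshold(exp(v), o)
  expect_equal(a$youden_j, b$youden_j, tolerance = 1e-12)
  expect_equal(a$auc, b$auc, tolerance = 1e-12)
  expect_error(roc_threshold(v, rep(1, 60)), "both outcome classes")
})

test_that("roc AUC is near 0.5 for uninformative markers", {
  set.seed(9)
  aucs <- vapply(1:500, function(i) {
    v <- rnorm(200); o <- rbinom(200, 1, 0.5)
    if (length(unique(o)) < 2) o[1:2] <- c(0, 1)
    roc_threshold(v, o)$auc
  }, 0)
  se <- sd(aucs) / sqrt(500)
  expect_lt(abs(mean(aucs) - 0.5), 2 * se + 0.005)
})

test_that("roc_threshold agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  v <- rnorm(80); o <- rbinom(80, 1, plogis(2 * v))
  if (length(unique(o)) < 2) o[1:2] <- c(0, 1)
  r <- roc_threshold(v, o)
  pr <- pROC::roc(o, v, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-9)
  best <- pROC::coords(pr, "best", best.method = "youden")
  expect_equal(r$youden_j,
               max(best$sensitivity + best$specificity - 1),
               tolerance = 1e-9)
})

test_that("group comparisons behave on canonical inputs", {
  x <- c(1.1, 2.3, 3.1, 4.9, 5.2)
  tt <- group_compare(x, x, "t")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p, 1)
  mw <- group_compare(rnorm(20), rnorm(20) + 10, "mann_whitney")
  expect_lt(mw$p, 0.001)
  # perfectly separated 2x2 table: doubled hypergeometric point mass
  ft <- group_compare(matrix(c(10, 0, 0, 10), 2), kind = "fisher")
  expect_equal(ft$p, oracle_fisher(10, 0, 0, 10), tolerance = 1e-9)
  expect_equal(ft$p, 2 / choose(20, 10), tolerance = 1e-7)
  ct <- group_compare(matrix(c(30, 10, 10, 30), 2), kind = "chi_square")
  expect_lt(ct$p, 0.01)
})

test_that("distribution checks route correctly", {
  set.seed(11)
  dc <- distribution_checks(rnorm(100), rnorm(100))
  expect_true(dc$shapiro_p > 0 && dc$shapiro_p <= 1)
  expect_false(is.na(dc$levene_p))
  expect_error(distribution_checks(c(1, 2)), "n >= 3")
  # exponential data are reliably non-normal at n = 200
  rej <- vapply(1:50, function(i) {
    set.seed(100 + i)
    stats::shapiro.test(rexp(200))$p.value < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.95)
})

test_that("percentage formatting matches reporting conventions", {
  expect_identical(fmt_pct(74, 197), "37.6%")
  expect_identical(fmt_pct(17, 64), "26.6%")
  expect_identical(fmt_pct(58, 64, digits = 0), "91%")
})
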