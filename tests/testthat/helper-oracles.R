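# Independent brute-force oracles used across the suite.  These are written
# from first principles (plain loops / enumeration) and never share code with
# the package internals they check.

# direct 2-D correlation with symmetric (edge-repeating) padding
oracle_conv2 <- function(img, kernel) {
  ky <- (nrow(kernel) - 1L) / 2L
  kx <- (ncol(kernel) - 1L) / 2L
  n <- nrow(img); m <- ncol(img)
  ridx <- c(ky:1, 1:n, n:(n - ky + 1L))
  cidx <- c(kx:1, 1:m, m:(m - kx + 1L))
  if (ky == 0L) ridx <- 1:n
  if (kx == 0L) cidx <- 1:m
  pad <- img[ridx, cidx]
  out <- matrix(if (is.complex(kernel)) 0i else 0, n, m)
  for (i in 1:n) for (j in 1:m) {
    out[i, j] <- sum(kernel * pad[i:(i + 2 * ky), j:(j + 2 * kx)])
  }
  out
}

# Cox partial log-likelihood (Breslow ties; toy fixtures avoid ties so it
# agrees with Efron), brute-force over the risk sets
oracle_cox_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (i in seq_along(times)) {
    if (events[i] == 1) {
      risk <- times >= times[i]
      ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
    }
  }
  ll
}

oracle_cox_grid <- function(times, events, x,
                            grid = seq(-5, 5, by = 1e-4)) {
  ll <- vapply(grid, oracle_cox_loglik, 0, times = times, events = events,
               x = x)
  grid[which.max(ll)]
}

# hand product-limit estimator by risk-set enumeration
oracle_km <- function(times, events, at) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  for (t in ut) {
    if (t > at) break
    d <- sum(times == t & events == 1)
    r <- sum(times >= t)
    s <- s * (1 - d / r)
  }
  s
}

# two-sided Fisher exact P by hypergeometric enumeration (sum of tables with
# probability <= observed)
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) dhyper(x, m, n2, k), 0)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small planted-effect records without images: z drives an exponential
# progression hazard, censoring exponential
make_records <- function(n, beta = 1, base = 0.115, cens = 0.115,
                         z = stats::rnorm(n), extra = NULL) {
  h <- base * exp(beta * z)
  tp <- stats::rexp(n) / h
  cn <- stats::rexp(n, cens)
  rec <- data.frame(
    patient_id = sprintf("S%04d", seq_len(n)),
    arm = "TACE",
    ttp_time = pmin(tp, cn), ttp_event = as.integer(tp <= cn),
    os_time = pmin(tp, cn) + 1, os_event = as.integer(tp <= cn),
    z = z, stringsAsFactors = FALSE)
  if (!is.null(extra)) rec <- cbind(rec, extra)
  rec
}

# quick small ROI image helpers
flat_image <- function(n = 64, value = 100) {
  roi_image(matrix(value, n, n), matrix(TRUE, n, n))
}

noise_image <- function(n = 64, seed = 1, sd = 20, mean = 70) {
  set.seed(seed)
  roi_image(matrix(rnorm(n * n, mean, sd), n, n), matrix(TRUE, n, n))
}
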