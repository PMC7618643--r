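# Independent oracles and tiny fixture builders shared across tests.

# Breslow log partial likelihood, written directly from the definition:
# sum over events of x_i'beta minus, at each distinct event time, d_t times
# the log of the risk-set sum of exp(x'beta).
breslow_loglik <- function(beta, time, status, x) {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  ll <- 0
  for (t in unique(time[status == 1])) {
    events <- which(time == t & status == 1)
    risk <- which(time >= t)
    ll <- ll + sum(eta[events]) -
      length(events) * log(sum(exp(eta[risk])))
  }
  ll
}

# Brute-force maximization by iterated grid refinement (no gradients, no
# Newton steps): start from a wide grid and zoom until the spacing is well
# below the comparison tolerance.
grid_maximize <- function(f, p, lower = -4, upper = 4, levels = 8L,
                          points = 13L) {
  lo <- rep(lower, p); hi <- rep(upper, p)
  best <- rep(0, p)
  for (lev in seq_len(levels)) {
    grids <- lapply(seq_len(p), function(j) seq(lo[j], hi[j], length.out = points))
    cand <- as.matrix(expand.grid(grids))
    vals <- apply(cand, 1L, f)
    best <- cand[which.max(vals), ]
    step <- (hi - lo) / (points - 1)
    lo <- best - step; hi <- best + step
  }
  unname(best)
}

# Small survival fixtures (n <= 8) with known structure, including ties.
cox_toy_fixtures <- function() {
  list(
    single_binary = data.frame(
      followup = c(1, 2, 3, 4, 5, 6), dementia = c(1, 0, 1, 1, 0, 1),
      death = 0, x1 = c(1, 1, 0, 1, 0, 0)),
    continuous = data.frame(
      followup = c(2, 5, 1, 7, 4, 3, 6), dementia = c(1, 1, 0, 1, 1, 0, 1),
      death = 0, x1 = c(0.5, -1.2, 0.3, 2.1, -0.7, 1.0, 0.0)),
    with_ties = data.frame(
      followup = c(1, 1, 2, 2, 3, 3, 4, 5), dementia = c(1, 1, 1, 0, 1, 1, 0, 1),
      death = 0, x1 = c(1, 0, 1, 1, 0, 1, 0, 0)),
    two_covariates = data.frame(
      followup = c(3, 1, 4, 2, 6, 5, 7, 8), dementia = c(1, 1, 0, 1, 1, 0, 1, 0),
      death = 0, x1 = c(0.2, 1.5, -0.4, 0.9, -1.1, 0.3, 0.8, -0.2),
      x2 = c(1, 0, 1, 0, 0, 1, 1, 0)))
}

# Toy 3-variant harmonized set used for the IVW oracle checks.
ivw_toy_set <- function() {
  structure(data.frame(
    variant_id = c("v1", "v2", "v3"), effect_allele = "A",
    eaf = c(0.3, 0.4, 0.5),
    beta_x = c(0.1, 0.2, 0.1), se_x = c(0.01, 0.01, 0.01),
    beta_y = c(0.02, 0.05, 0.01), se_y = c(0.01, 0.02, 0.01),
    stringsAsFactors = FALSE), class = c("harmonized_set", "data.frame"))
}

# Well-formed small summary-statistics data frame.
toy_stats <- function(n = 5L, beta = NULL, se = NULL, pval = NULL,
                      effect_allele = NULL, other_allele = NULL, eaf = NULL) {
  data.frame(
    variant_id = paste0("rs", seq_len(n)), chrom = "1",
    pos = seq_len(n) * 100L,
    effect_allele = effect_allele %||% rep("A", n),
    other_allele = other_allele %||% rep("G", n),
    eaf = eaf %||% rep(0.3, n),
    beta = beta %||% seq(0.1, by = 0.05, length.out = n),
    se = se %||% rep(0.02, n),
    pval = pval %||% rep(1e-10, n),
    n = 10000L, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Summary-level two-sample MR generator: J instruments at sample size n per
# trait, each explaining r2 of the (unit-variance) exposure; the outcome
# betas are truth * beta_x plus independent sampling noise.
make_two_sample <- function(j = 50L, n = 50000L, truth = 0.1, r2 = 0.001,
                            pleiotropy_sd = 0) {
  eaf <- stats::runif(j, 0.1, 0.9)
  vg <- 2 * eaf * (1 - eaf)
  if (length(r2) == 2L) r2 <- stats::runif(j, r2[1], r2[2])
  beta_x_true <- sqrt(r2 / vg)
  se_x <- sqrt(1 / (n * vg))
  se_y <- sqrt(1 / (n * vg))
  bx <- stats::rnorm(j, beta_x_true, se_x)
  alpha <- if (pleiotropy_sd > 0) stats::rnorm(j, 0, pleiotropy_sd) else 0
  by <- stats::rnorm(j, truth * beta_x_true + alpha, se_y)
  expo <- summary_stats(data.frame(
    variant_id = paste0("rs", seq_len(j)), chrom = "1", pos = seq_len(j),
    effect_allele = "A", other_allele = "G", eaf = eaf,
    beta = bx, se = se_x,
    pval = pmax(2 * stats::pnorm(-abs(bx / se_x)), 1e-300), n = n))
  outc <- expo
  outc$beta <- by
  outc$se <- se_y
  outc$pval <- pmax(2 * stats::pnorm(-abs(by / se_y)), 1e-300)
  list(exposure = expo, outcome = summary_stats(outc))
}
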