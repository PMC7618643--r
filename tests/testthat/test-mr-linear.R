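test_that("instrument selection filters on the p-value threshold", {
  stats <- summary_stats(toy_stats(5L, pval = c(1e-9, 0.2, 4e-8, 1e-4, 0.9)))
  sel <- select_instruments(stats)
  expect_equal(sel$variant_id, c("rs1", "rs3"))
  expect_equal(attr(sel, "threshold_used"), 5e-8)
  # fallback threshold engages when nothing is genome-wide significant
  weak <- summary_stats(toy_stats(3L, pval = c(1e-6, 1e-3, 0.5)))
  sel2 <- select_instruments(weak)
  expect_equal(attr(sel2, "threshold_used"), 5e-5)
  expect_equal(sel2$variant_id, "rs1")
  expect_error(select_instruments(
    summary_stats(toy_stats(2L, pval = c(0.5, 0.9)))), "no instruments")
  # threshold 1 keeps everything
  expect_equal(nrow(select_instruments(stats, threshold = 1)), 5L)
})

test_that("harmonization aligns, flips and excludes ambiguous palindromes", {
  expo <- summary_stats(toy_stats(4L, beta = c(0.1, 0.2, 0.15, 0.1),
                                  effect_allele = c("A", "A", "A", "C"),
                                  other_allele = c("G", "G", "T", "G"),
                                  eaf = c(0.3, 0.3, 0.50, 0.3)))
  outc <- toy_stats(4L, beta = c(0.05, -0.03, 0.02, 0.04),
                    effect_allele = c("A", "G", "A", "C"),
                    other_allele = c("G", "A", "T", "G"),
                    eaf = c(0.3, 0.7, 0.5, 0.3))
  h <- harmonize(expo, summary_stats(outc))
  expect_equal(h$variant_id, c("rs1", "rs2", "rs4"))
  expect_equal(h$beta_y, c(0.05, 0.03, 0.04))  # rs2 was swapped: sign flipped
  excl <- attr(h, "excluded")
  expect_equal(excl$variant_id, "rs3")
  expect_equal(excl$reason, "ambiguous_palindromic")
  # palindromic but outside the ambiguity window is retained
  expo2 <- summary_stats(toy_stats(1L, effect_allele = "A",
                                   other_allele = "T", eaf = 0.2))
  h2 <- harmonize(expo2, expo2)
  expect_equal(nrow(h2), 1L)
  expect_error(harmonize(expo, summary_stats(toy_stats(2L))[0, ]),
               "no overlapping")
})

test_that("Wald ratios follow the first-order formulas", {
  h <- ivw_toy_set()
  r <- ratio_estimates(h)
  expect_equal(r$theta[1L], 0.2)
  # beta_x=0.1, beta_y=0.05, se_y=0.01 -> theta=0.5, se=0.1
  h2 <- h; h2$beta_y[1L] <- 0.05
  r2 <- ratio_estimates(h2)
  expect_equal(r2$theta[1L], 0.5)
  expect_equal(r2$se[1L], 0.1)
  # beta_y = 0 gives ratio 0 with se se_y/|beta_x|
  h3 <- h; h3$beta_y[2L] <- 0
  r3 <- ratio_estimates(h3)
  expect_equal(r3$theta[2L], 0)
  expect_equal(r3$se[2L], 0.02 / 0.2)
  # scale invariance: doubling both betas leaves theta unchanged
  h4 <- h; h4$beta_x <- 2 * h$beta_x; h4$beta_y <- 2 * h$beta_y
  expect_equal(ratio_estimates(h4)$theta, r$theta)
  # zero denominators are excluded with a reason
  h5 <- h; h5$beta_x[3L] <- 0
  r5 <- ratio_estimates(h5)
  expect_equal(nrow(r5), 2L)
  expect_equal(attr(r5, "excluded")$reason, "beta_x_zero")
})

test_that("IVW matches its closed form, identities and the WLS oracle", {
  h <- ivw_toy_set()
  fit <- mr_ivw(h, model = "fixed")
  expect_equal(fit$beta, 55 / 300, tolerance = 1e-12)
  # grid/optimize oracle: weighted least squares through the origin
  oracle <- optimize(function(b) sum((h$beta_y - b * h$beta_x)^2 / h$se_y^2),
                     c(-5, 5), tol = 1e-10)$minimum
  expect_equal(fit$beta, oracle, tolerance = 1e-6)

  # IVW = weighted mean of Wald ratios with weights beta_x^2/se_y^2
  set.seed(8)
  for (i in 1:10) {
    hh <- ivw_toy_set()
    hh <- hh[rep(1:3, 3L), ]
    hh$variant_id <- paste0("v", 1:9)
    hh$beta_x <- rnorm(9, 0.1, 0.03)
    hh$beta_y <- rnorm(9, 0.02, 0.01)
    hh$se_y <- runif(9, 0.005, 0.02)
    fitr <- mr_ivw(hh, model = "fixed")
    r <- ratio_estimates(hh)
    w <- hh$beta_x^2 / hh$se_y^2
    expect_equal(fitr$beta, sum(w * r$theta) / sum(w), tolerance = 1e-12)
    # invariance to ordering and to allele-flipping a subset
    perm <- sample(9)
    expect_equal(mr_ivw(hh[perm, ], model = "fixed")$beta, fitr$beta,
                 tolerance = 1e-12)
    flip <- rbinom(9, 1, 0.5) == 1
    hf <- hh
    hf$beta_x[flip] <- -hf$beta_x[flip]
    hf$beta_y[flip] <- -hf$beta_y[flip]
    expect_equal(mr_ivw(hf, model = "fixed")$beta, fitr$beta,
                 tolerance = 1e-12)
  }

  # single variant: IVW equals the Wald ratio
  single <- h[1L, ]
  expect_equal(mr_ivw(single)$beta, 0.2)
  # identical ratios: beta = c and Q = 0
  hc <- h; hc$beta_y <- 0.3 * hc$beta_x
  fc <- mr_ivw(hc)
  expect_equal(fc$beta, 0.3, tolerance = 1e-12)
  expect_equal(fc$Q, 0, tolerance = 1e-12)
  expect_equal(fc$or, exp(fc$beta))
})

test_that("Cochran Q and leave-one-out behave as hand-computed", {
  h <- ivw_toy_set()
  beta <- mr_ivw(h, model = "fixed")$beta
  q <- cochran_q(h)
  r <- ratio_estimates(h)
  w <- 1 / r$se^2
  expect_equal(q$Q, sum(w * (r$theta - beta)^2), tolerance = 1e-12)
  expect_equal(q$df, 2L)
  expect_equal(nrow(q$leave_one_out), 3L)
  # dropping a variant reproduces IVW on the remainder
  expect_equal(q$leave_one_out$beta[1L],
               mr_ivw(h[-1L, ], model = "fixed")$beta)
  hc <- h; hc$beta_y <- 0.1 * hc$beta_x
  expect_equal(cochran_q(hc)$Q, 0, tolerance = 1e-12)
  expect_equal(cochran_q(hc)$p, 1)
  expect_error(cochran_q(h[1L, ]), "at least 2")
})

test_that("Egger regression estimates directional pleiotropy", {
  expect_error(egger(ivw_toy_set()[1:2, ]), "at least 3")
  set.seed(10)
  j <- 30L
  bx <- runif(j, 0.05, 0.2)
  se_y <- rep(0.001, j)
  h <- data.frame(variant_id = paste0("v", 1:j), effect_allele = "A",
                  eaf = 0.3, beta_x = bx, se_x = 0.001,
                  beta_y = 0.25 * bx, se_y = se_y)
  base <- egger(h)
  # constant pleiotropy added to every outcome beta moves only the intercept
  hp <- h; hp$beta_y <- h$beta_y + 0.02
  shifted <- egger(hp)
  expect_equal(shifted$intercept - base$intercept, 0.02, tolerance = 1e-8)
  expect_equal(shifted$slope, base$slope, tolerance = 1e-8)
  # with no pleiotropy the intercept CI covers 0 at roughly nominal rate
  covered <- vapply(1:40, function(s) {
    set.seed(200 + s)
    hh <- h
    hh$se_y <- 0.01
    hh$beta_y <- rnorm(j, 0.25 * bx, 0.01)
    e <- egger(hh)
    abs(e$intercept) <= qt(0.975, j - 2) * e$intercept_se
  }, logical(1L))
  expect_gte(mean(covered), 0.85)
})

test_that("balanced pleiotropy inflates Q while the Egger slope stays consistent", {
  res <- t(vapply(1:50, function(s) {
    set.seed(300 + s)
    ss <- make_two_sample(j = 50L, n = 100000L, truth = 0.1,
                          r2 = c(0.001, 0.004), pleiotropy_sd = 0.01)
    h <- harmonize(ss$exposure, ss$outcome)
    fit <- mr_ivw(h)
    e <- egger(h)
    c(qdf = fit$Q / fit$df, slope = e$slope)
  }, c(qdf = 0, slope = 0)))
  expect_gte(mean(res[, "qdf"] > 1), 0.9)
  expect_lt(abs(mean(res[, "slope"]) - 0.1), 0.05)
})

test_that("multivariable MR solves the weighted normal equations", {
  # reduction: an all-zero second exposure leaves the first at univariable IVW
  h <- ivw_toy_set()
  x <- cbind(dpw = h$beta_x, aud = c(0, 0, 0))
  out <- mvmr(h$beta_y, x, h$se_y)
  expect_equal(out$beta[1L], mr_ivw(h, model = "fixed")$beta,
               tolerance = 1e-12)
  expect_true(is.na(out$beta[2L]))

  # 4-variant, 2-exposure system against the hand normal-equations solution
  by <- c(0.03, 0.05, 0.02, 0.06)
  bx <- cbind(e1 = c(0.1, 0.2, 0.05, 0.15), e2 = c(0.02, 0.01, 0.08, 0.03))
  se_y <- c(0.01, 0.02, 0.01, 0.015)
  w <- diag(1 / se_y^2)
  manual <- solve(t(bx) %*% w %*% bx, t(bx) %*% w %*% by)
  out2 <- mvmr(by, bx, se_y)
  expect_equal(out2$beta, drop(manual), tolerance = 1e-12,
               ignore_attr = TRUE)

  # duplicated exposures are collinear
  expect_error(mvmr(by, cbind(e1 = bx[, 1], e1b = bx[, 1]), se_y),
               "collinear")
  expect_error(mvmr(by[1:2], bx[1:2, ], se_y[1:2]), "more variants")
})

test_that("binary-exposure scaling and its inverse are exact", {
  expect_equal(scale_binary_exposure(0)$or_doubling, 1.0)
  expect_equal(scale_binary_exposure(0.2)$or_doubling, exp(0.2 * log(2)),
               tolerance = 1e-15)
  expect_equal(invert_binary_scaling(1.16), log(1.16) / log(2),
               tolerance = 1e-15)
  expect_equal(invert_binary_scaling(scale_binary_exposure(0.214)$or_doubling),
               0.214, tolerance = 1e-12)
})

test_that("reverse MR swaps roles and recovers simulated reverse effects", {
  set.seed(12)
  ss <- make_two_sample(j = 40L, truth = 0.1)
  forward <- mr_ivw(harmonize(select_instruments(ss$exposure), ss$outcome))
  # swapping roles twice returns the forward analysis
  double_swap <- reverse_mr(ss$exposure, ss$outcome)
  expect_equal(double_swap$beta, forward$beta, tolerance = 1e-12)

  # null reverse effect: CI covers 0 in most replicates
  cover0 <- vapply(1:30, function(s) {
    set.seed(400 + s)
    ssn <- make_two_sample(j = 40L, truth = 0)
    fit <- reverse_mr(ssn$exposure, ssn$outcome)
    fit$ci_lower <= 0 && fit$ci_upper >= 0
  }, logical(1L))
  expect_gte(mean(cover0), 0.85)

  # a simulated effect of 0.1 is recovered within 3 SE
  set.seed(13)
  ssr <- make_two_sample(j = 40L, truth = 0.1)
  fit <- reverse_mr(ssr$exposure, ssr$outcome)
  expect_lt(abs(fit$beta - 0.1), 3 * fit$se)
})
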