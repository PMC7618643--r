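test_that("genetic risk scores are weighted allele counts", {
  g <- matrix(c(2, 1, 0, 1), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(compute_grs(g, c(a = 0, b = 0)), c(0, 0), ignore_attr = TRUE)
  g1 <- matrix(2, 1, 1, dimnames = list(NULL, "a"))
  expect_equal(as.numeric(compute_grs(g1, c(a = 0.3))), 0.6)
  # order-invariance via name alignment
  s1 <- compute_grs(g, c(a = 0.2, b = 0.5))
  s2 <- compute_grs(g, c(b = 0.5, a = 0.2))
  expect_equal(s1, s2)
  # missing dosages are mean-imputed and counted
  gna <- g; gna[1L, 1L] <- NA
  s3 <- compute_grs(gna, c(a = 1, b = 0))
  expect_equal(attr(s3, "n_imputed"), 1L)
  expect_equal(as.numeric(s3), c(1, 1))  # NA replaced by the column mean (1)
  expect_error(compute_grs(g, 1), "length")
  # a 641-SNP panel (the scale of real drinks-per-week instruments) works
  set.seed(1)
  gbig <- matrix(rbinom(50 * 641, 2, 0.3), 50, 641)
  expect_length(as.numeric(compute_grs(gbig, runif(641))), 50L)
})

test_that("doubly-ranked assignment matches the hand enumeration at N=10, K=5", {
  iv <- c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100)
  expo <- c(5, 3, 9, 1, 7, 2, 8, 6, 10, 4)
  st <- doubly_ranked_strata(iv, expo, K = 5L)
  # pre-stratum 1 = iv ranks 1..5 (exposures 5,3,9,1,7), pre-stratum 2 =
  # ranks 6..10 (exposures 2,8,6,10,4): within-pre-stratum exposure ranks
  expect_equal(st$stratum, c(3L, 2L, 5L, 1L, 4L, 1L, 4L, 3L, 5L, 2L))
  expect_equal(st$sizes, rep(2L, 5L))
  expect_equal(st$dropped, 0L)
  expect_error(doubly_ranked_strata(1:5, 1:5, K = 3L), "two complete")
  expect_error(doubly_ranked_strata(1:30, 1:30, K = 2L), ">= 3")
})

test_that("exposure strictly monotone in the instrument gives within-block positions", {
  # degenerate case: with no exposure noise around the instrument, the
  # within-pre-stratum exposure rank is the position in the consecutive
  # instrument block, so stratum = ((iv rank - 1) mod K) + 1
  set.seed(2)
  iv <- rnorm(100)
  expo <- exp(iv)  # strictly increasing in the instrument
  st <- doubly_ranked_strata(iv, expo, K = 5L)
  expected <- (rank(iv) - 1) %% 5 + 1
  expect_equal(st$stratum, as.integer(expected))
  # and all stratum means are then nearly equal (no exposure separation)
  expect_true(all(diff(st$mean_exposure) >= 0))
})

test_that("stratification invariants hold on random instances", {
  set.seed(3)
  for (i in 1:50) {
    k <- sample(3:7, 1L)
    n <- sample(k^2:300, 1L)
    iv <- rnorm(n)
    expo <- rexp(n)
    st <- doubly_ranked_strata(iv, expo, K = k, seed = i)
    kept <- !is.na(st$stratum)
    expect_equal(sum(kept), (n %/% k) * k)
    expect_lt(st$dropped, k)
    expect_true(all(table(st$stratum) == n %/% k))
    expect_true(all(diff(st$mean_exposure) >= 0))
    # exact invariance to strictly monotone exposure transforms
    st2 <- doubly_ranked_strata(iv, log1p(expo) * 3 + 2, K = k, seed = i)
    expect_identical(st$stratum, st2$stratum)
  }
  # tie-breaking is deterministic given the seed
  iv_ties <- rep(1:20, each = 5L)
  ex <- rnorm(100)
  a <- doubly_ranked_strata(iv_ties, ex, K = 5L, seed = 9)
  b <- doubly_ranked_strata(iv_ties, ex, K = 5L, seed = 9)
  expect_identical(a$stratum, b$stratum)
})

test_that("stratum LACE recovers a constant causal effect", {
  covered <- vapply(1:40, function(s) {
    set.seed(s)
    n <- 3000L
    grs <- rnorm(n)
    expo <- 5 + 2 * grs + rnorm(n)
    y <- 0.04 * expo + rnorm(n, 0, 0.5)   # constant effect 0.04 per unit
    d <- data.frame(dementia = y, age = rnorm(n, 65, 5), sex = rbinom(n, 1, 0.5))
    st <- doubly_ranked_strata(grs, expo, K = 5L, seed = s)
    est <- stratum_lace(d, grs, st, expo, covariates = c("age", "sex"),
                        outcome_model = "linear")
    all(est$lace - 1.96 * est$lace_se <= 0.04 &
          est$lace + 1.96 * est$lace_se >= 0.04)
  }, logical(1L))
  expect_gte(mean(covered), 0.7)  # joint coverage of 5 intervals

  # a score unrelated to the outcome gives LACE intervals covering zero
  set.seed(100)
  n <- 4000L
  grs <- rnorm(n)
  expo <- 5 + 2 * grs + rnorm(n)
  d <- data.frame(dementia = rbinom(n, 1L, 0.05),
                  age = rnorm(n, 65, 5), sex = rbinom(n, 1L, 0.5))
  st <- doubly_ranked_strata(grs, expo, K = 5L, seed = 100)
  est <- stratum_lace(d, grs, st, expo, covariates = c("age", "sex"))
  expect_true(mean(est$lace - 1.96 * est$lace_se <= 0 &
                     est$lace + 1.96 * est$lace_se >= 0) >= 0.8)
})

test_that("constant LACE reduces the fractional polynomial to IVW pooling", {
  est <- data.frame(stratum = 1:5, n = 100L,
                    mean_exposure = c(1, 4, 7, 11, 19),
                    lace = rep(0.03, 5L), lace_se = rep(0.01, 5L))
  fp <- fracpoly_fit(est, degree = 2L, reference = 1)
  expect_equal(fp$degree_used, 1L)
  expect_equal(fp$powers, 1)           # constant derivative
  expect_equal(unname(fp$coef), 0.03, tolerance = 1e-10)
  # curve is log-linear with slope c, anchored at OR 1 at the reference
  expect_equal(fp$grid$log_or, 0.03 * (fp$grid$exposure - 1),
               tolerance = 1e-10)
  expect_equal(fp$grid$or[fp$grid$exposure == 1], 1, tolerance = 1e-15)

  # unequal standard errors: the pooled value is the IVW mean of the LACE
  est$lace <- c(0.031, 0.029, 0.030, 0.032, 0.028)
  est$lace_se <- c(0.01, 0.02, 0.01, 0.03, 0.015)
  fp2 <- fracpoly_fit(est, degree = 1L, powers = 1)
  w <- 1 / est$lace_se^2
  expect_equal(unname(fp2$coef), sum(w * est$lace) / sum(w),
               tolerance = 1e-10)
})

test_that("a known quadratic derivative is reconstructed on the grid", {
  # derivative d(x) = b1 + 2 b2 x  (curve powers 1 and 2)
  b1 <- 0.01; b2 <- 0.0015
  x <- c(1.5, 4, 7, 11, 16, 22)
  est <- data.frame(stratum = 1:6, n = 100L, mean_exposure = x,
                    lace = b1 + 2 * b2 * x, lace_se = 1e-5)
  fp <- fracpoly_fit(est, degree = 2L, reference = 1)
  expect_equal(fp$degree_used, 2L)
  expect_setequal(fp$powers, c(1, 2))
  truth <- b1 * (fp$grid$exposure - 1) + b2 * (fp$grid$exposure^2 - 1)
  expect_lt(max(abs(fp$grid$log_or - truth) /
                  pmax(abs(truth), 0.01)), 0.01)
  expect_error(fracpoly_fit(est[1:2, ], degree = 2L), "degree \\+ 1")
})

test_that("nonlinearity and trend tests respond to the generating shape", {
  flat <- data.frame(stratum = 1:5, n = 100L,
                     mean_exposure = c(1, 4, 7, 11, 19),
                     lace = rep(0.02, 5L), lace_se = rep(0.01, 5L))
  t_flat <- test_nonlinearity_and_trend(flat)
  expect_gt(t_flat$p_linearity, 0.9)
  expect_gt(t_flat$p_trend, 0.9)
  expect_equal(t_flat$slope, 0, tolerance = 1e-12)

  rising <- flat
  rising$lace <- 0.01 + 0.002 * rising$mean_exposure
  rising$lace_se <- 1e-4
  t_rise <- test_nonlinearity_and_trend(rising)
  expect_lt(t_rise$p_trend, 0.001)
  expect_gt(t_rise$p_linearity, 0.5)

  curved <- flat
  curved$lace <- 0.01 + 0.002 * curved$mean_exposure^2
  curved$lace_se <- 1e-4
  expect_lt(test_nonlinearity_and_trend(curved)$p_linearity, 0.001)
  expect_error(test_nonlinearity_and_trend(flat[1:2, ]), "at least 3")
})

test_that("negative controls are null for valid instruments", {
  set.seed(4)
  n <- 3000L
  grs <- rnorm(n)
  d <- data.frame(age = rnorm(n, 65, 8), sex = rbinom(n, 1L, 0.5))
  expo <- 5 + 2 * grs + rnorm(n)
  st <- doubly_ranked_strata(grs, expo, K = 5L, seed = 4)
  nc <- negative_control(d, grs, st)
  expect_equal(nrow(nc), 10L)  # 2 controls x 5 strata
  expect_setequal(unique(nc$control), c("age", "sex"))
  expect_gte(mean(nc$ci_lower <= 0 & nc$ci_upper >= 0), 0.8)
  d$flat <- 1
  expect_error(negative_control(d, grs, st, controls = "flat"), "constant")
  expect_error(negative_control(d, grs, st, controls = "height"), "absent")
})

test_that("the nlmr wrapper runs end to end with methods", {
  cfg <- sim_config(n = 6000L, m = 30L, curve_kind = "linear", seed = 15)
  sim <- simulate_cohort(cfg, with_trajectories = FALSE)
  grs <- compute_grs(sim$dosages, sim$weights)
  fit <- suppressWarnings(nlmr(sim$cohort, grs, K = 5L, seed = 15))
  expect_s3_class(fit, "nlmr")
  expect_equal(nrow(fit$estimates), 5L)
  expect_length(coef(fit), 5L)
  expect_equal(fit$curve$grid$or[fit$curve$grid$exposure == 1], 1)
  expect_output(print(fit), "doubly-ranked")
  expect_output(print(summary(fit)), "localized average causal effects")
  pdf(NULL)
  on.exit(dev.off(), add = TRUE)
  expect_invisible(plot(fit))
})
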