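test_that("AUDIT-C midpoint products give drinks per week", {
  expect_equal(audit_c_to_dpw(0, 3), 0)           # never drinks: 0 regardless
  expect_equal(audit_c_to_dpw(4, 1), 19.25)       # 5.5/week x 3.5/day
  expect_equal(audit_c_to_dpw(2, 0), 0.75 * 1.5)
  expect_error(audit_c_to_dpw(5, 1), "0..4")
  # monotone over the full 5x5 grid in both arguments
  grid <- outer(0:4, 0:4, audit_c_to_dpw)
  expect_true(all(apply(grid, 1L, function(r) all(diff(r) >= 0))))
  expect_true(all(apply(grid, 2L, function(cc) all(diff(cc) >= 0))))
})

test_that("AUDIT-C risk groups use the clinical cutpoints", {
  expect_equal(as.character(audit_c_risk_group(c(0, 1, 2, 3, 4, 12))),
               c("non_occasional", "non_occasional", "low", "low",
                 "high", "high"))
  expect_error(audit_c_risk_group(13), "0..12")
})

test_that("drinking categories partition intake with half-open bands", {
  expect_equal(as.character(categorize_dpw(7, 1)), "7-<14")
  expect_equal(as.character(categorize_dpw(0, 0)), "nondrinker")
  expect_equal(as.character(categorize_dpw(40, 1)), ">40")
  expect_equal(as.character(categorize_dpw(39.99, 1)), "22-<40")
  expect_equal(levels(categorize_dpw(1, 1))[1L], "<7")  # reference band
  expect_error(categorize_dpw(-1, 1), ">= 0")
})

test_that("Cox fits maximize the Breslow partial likelihood (grid oracle)", {
  for (fx in cox_toy_fixtures()) {
    xcols <- grep("^x", names(fx), value = TRUE)
    f <- as.formula(paste("survival::Surv(followup, dementia) ~",
                          paste(xcols, collapse = "+")))
    fit <- fit_cox(fx, f)
    oracle <- grid_maximize(
      function(b) breslow_loglik(b, fx$followup, fx$dementia,
                                 as.matrix(fx[xcols])),
      p = length(xcols))
    expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-4)
  }
})

test_that("Cox estimates are invariant to duplicating every row", {
  fx <- cox_toy_fixtures()$continuous
  f <- survival::Surv(followup, dementia) ~ x1
  fit1 <- fit_cox(fx, f)
  fit2 <- fit_cox(rbind(fx, fx), f)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-8)
  expect_equal(fit2$hr, exp(fit2$coefficients))
  expect_equal(fit2$ci_lower, exp(fit2$coefficients - 1.96 * fit2$se))
})

test_that("zero-variance covariates are rejected by name", {
  fx <- cox_toy_fixtures()$continuous
  fx$flat <- 1
  expect_error(fit_cox(fx, survival::Surv(followup, dementia) ~ x1 + flat),
               "zero variance.*flat")
})

test_that("Schoenfeld flags are calibrated under proportional hazards", {
  flagged <- vapply(1:400, function(s) {
    set.seed(s)
    n <- 150L
    x <- rnorm(n)
    t_ev <- rexp(n, 0.2 * exp(0.5 * x))
    d <- data.frame(followup = pmin(t_ev, 5), dementia = as.integer(t_ev <= 5),
                    death = 0L, x = x)
    fit <- fit_cox(d, survival::Surv(followup, dementia) ~ x)
    schoenfeld_check(fit)$flagged[1L]
  }, logical(1L))
  expect_gt(mean(flagged), 0.02)
  expect_lt(mean(flagged), 0.09)
})

test_that("Schoenfeld check reports insufficient events and finds violations", {
  one_event <- data.frame(followup = c(1, 2, 3), dementia = c(1, 0, 0),
                          death = 0L, x = c(0.1, -0.2, 0.4))
  fit1 <- fit_cox(one_event, survival::Surv(followup, dementia) ~ x)
  out <- schoenfeld_check(fit1)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "note"), "insufficient events")
  # strong reversal of the effect over time must be flagged
  set.seed(99)
  n <- 3000L
  x <- rbinom(n, 1L, 0.5)
  t1 <- rexp(n, 0.5 * exp(1.5 * x))
  t2 <- 1 + rexp(n, 0.5 * exp(-1.5 * x))
  tt <- ifelse(t1 < 1, t1, t2)
  d <- data.frame(followup = pmin(tt, 4), dementia = as.integer(tt <= 4),
                  death = 0L, x = x)
  fit2 <- fit_cox(d, survival::Surv(followup, dementia) ~ x)
  expect_lt(schoenfeld_check(fit2)$p[1L], 0.01)
})

test_that("Aalen-Johansen reduces to 1 - KM without competing events", {
  set.seed(5)
  n <- 200L
  d <- data.frame(followup = rexp(n, 0.3), dementia = rbinom(n, 1L, 0.7),
                  death = 0L)
  d$followup <- pmin(d$followup, 3)
  d$dementia[d$followup == 3] <- 0L
  aj <- aalen_johansen(d, "dementia")
  km <- survival::survfit(survival::Surv(followup, dementia) ~ 1, data = d)
  expect_equal(aj$cif_dementia, 1 - summary(km, times = aj$time)$surv,
               tolerance = 1e-12)
  expect_true(all(aj$cif_death == 0))
})

test_that("Aalen-Johansen matches the hand-computed 5-subject CIF", {
  # subjects: times 1,2,3,4,5; events: dementia at 1, death at 3, censor else
  d <- data.frame(followup = 1:5, dementia = c(1, 0, 0, 0, 0),
                  death = c(0, 0, 1, 0, 0))
  aj <- aalen_johansen(d, "dementia")
  # at t=1: CIF_dem = 1/5; survivor 4/5; at t=3: CIF_death = (4/5)*(1/3)
  expect_equal(aj$cif_dementia[aj$time == 1], 0.2, tolerance = 1e-12)
  expect_equal(aj$cif_death[aj$time == 3], 0.8 / 3, tolerance = 1e-12)
  expect_equal(aj$cif_dementia[aj$time == 5], 0.2, tolerance = 1e-12)
  # identity: CIFs plus survivor sum to one at every time
  expect_equal(aj$cif_dementia + aj$cif_death + aj$surv, rep(1, nrow(aj)),
               tolerance = 1e-12)
  expect_error(aalen_johansen(d[0, ]), "empty")
})

test_that("DerSimonian-Laird pooling matches the hand computation", {
  pe <- meta_analyze(c(0.1, 0.3), c(0.05, 0.05))
  # w = 400 each; Q = 8; C = 400; tau2 = (8-1)/400 = 0.0175
  expect_equal(pe$tau2, 0.0175, tolerance = 1e-10)
  expect_equal(pe$beta, 0.2, tolerance = 1e-10)
  expect_equal(pe$se, 0.1, tolerance = 1e-10)

  same <- meta_analyze(c(0.2, 0.2), c(0.04, 0.04))
  expect_equal(same$beta, 0.2)
  expect_equal(same$tau2, 0)

  single <- meta_analyze(0.15, 0.03)
  expect_equal(single$beta, 0.15)
  expect_equal(single$se, 0.03, tolerance = 1e-10)
  expect_error(meta_analyze(c(0.1, 0.2), c(0.05, 0)), "> 0")
})

test_that("exposure timing comparison shows prodromal attenuation", {
  # prodrome off: the two measurements coincide, so the fits are identical
  cfg0 <- sim_config(n = 4000L, m = 5L, prodrome_extra_slope = 0,
                     curve_kind = "linear", seed = 71)
  sim0 <- simulate_cohort(cfg0, with_trajectories = FALSE)
  expect_equal(sim0$cohort$dpw_enrol, sim0$cohort$dpw)
  tc0 <- compare_timing(sim0$cohort)
  expect_equal(tc0$attenuation$hr_early, tc0$attenuation$hr_late,
               tolerance = 1e-8)
  expect_true(all(startsWith(names(tc0$early$coefficients)[1:5],
                             "dpw_cat_early")))
  expect_equal(levels(categorize_dpw(1, 1))[1L], "<7")

  # prodrome on: late-measured heavy-drinking hazard ratios attenuate
  direction <- vapply(1:50, function(s) {
    cfg <- sim_config(n = 10000L, m = 5L, curve_kind = "linear", seed = s)
    sim <- simulate_cohort(cfg, with_trajectories = FALSE)
    tc <- compare_timing(sim$cohort)
    att <- tc$attenuation
    heavy <- att$category %in% c("22-<40", ">40")
    mean(att$ratio_late_to_early[heavy]) < 1
  }, logical(1L))
  expect_gte(mean(direction), 0.9)
})
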