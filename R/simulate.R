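#' Simulate Hardy-Weinberg genotype dosages
#'
#' Draws an `n x m` matrix of allele dosages, each SNP binomial(2, p_j) with
#' its effect-allele frequency p_j uniform on `eaf_range`. SNPs are
#' independent (no linkage disequilibrium), standing in for an LD-clumped
#' instrument panel.
#'
#' @param n,m individuals and SNP count (both >= 1).
#' @param eaf_range interval (or single value) strictly inside (0,1).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (so an orchestrating caller can seed once).
#' @return integer matrix with entries in 0/1/2; allele frequencies are
#'   attached as `attr(, "eaf")`.
#' @export
simulate_genotypes <- function(n, m, eaf_range = c(0.1, 0.9), seed = NULL) {
  if (n < 1L || m < 1L) stop("n and m must be >= 1", call. = FALSE)
  if (any(eaf_range <= 0) || any(eaf_range >= 1)) {
    stop("degenerate eaf_range: must lie strictly inside (0,1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  p <- if (length(eaf_range) == 1L) rep(eaf_range, m) else
    stats::runif(m, eaf_range[1], eaf_range[2])
  g <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
  colnames(g) <- sprintf("snp%04d", seq_len(m))
  attr(g, "eaf") <- p
  g
}

#' Simulate drinks per week with a hurdle abstention process
#'
#' Latent log-intake is `exposure_mean_log + grs_effect * z(GRS) +
#' confounder_effect_exposure * U + eps`, with `eps ~ N(0,
#' exposure_sd_log)`. Drinkers report `dpw = exp(latent)`; abstention is
#' drawn with probability `logistic(logit(abstain_base_rate) +
#' sick_quitter_strength * U)`, so high-frailty individuals are
#' preferentially pushed out of drinking (sick quitters). Abstainers get
#' `dpw = 0` and a `never`/`former` label, `former` with probability
#' `logistic(U)` — former drinkers are concentrated at high frailty.
#'
#' @param dosages genotype matrix from [simulate_genotypes()].
#' @param weights per-SNP exposure-increasing weights (length `ncol(dosages)`).
#' @param config a [sim_config()].
#' @param u latent frailty vector (standard normal); drawn if `NULL`.
#' @param seed optional integer seed.
#' @return data frame with columns `dpw`, `drinker`, `drink_status` and
#'   hidden columns `.u`, `.latent`.
#' @export
simulate_exposure <- function(dosages, weights, config, u = NULL, seed = NULL) {
  if (length(weights) != ncol(dosages)) {
    stop("weights length must equal number of SNP columns", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(dosages)
  if (is.null(u)) u <- stats::rnorm(n)
  raw <- drop(dosages %*% weights)
  z <- if (stats::sd(raw) > 0) (raw - mean(raw)) / stats::sd(raw) else rep(0, n)
  latent <- config$exposure_mean_log + config$grs_effect * z +
    config$confounder_effect_exposure * u +
    stats::rnorm(n, 0, config$exposure_sd_log)
  p_abstain <- stats::plogis(stats::qlogis(max(config$abstain_base_rate, 1e-12)) +
                               config$sick_quitter_strength * u)
  abstain <- stats::rbinom(n, 1L, p_abstain) == 1L
  dpw <- ifelse(abstain, 0, exp(latent))
  former <- abstain & (stats::rbinom(n, 1L, stats::plogis(u)) == 1L)
  status <- ifelse(!abstain, "current", ifelse(former, "former", "never"))
  data.frame(dpw = dpw, drinker = as.integer(!abstain), drink_status = status,
             .u = u, .latent = latent, stringsAsFactors = FALSE)
}

#' Simulate competing dementia and death events
#'
#' Cause-specific exponential hazards given covariates:
#' `lambda_dem = b_dem * exp(h(dpw) + delta*U + age/sex terms)` and
#' `lambda_death = b_death * exp(delta*U + age/sex terms)` (the causal
#' curve `h` acts on dementia only). The observed time is the minimum of
#' the two latent event times and administrative censoring at
#' `followup_years`; indicators record the first event.
#'
#' @param data data frame with columns `dpw`, `.u`, `age`, `sex`.
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return `data` with columns `followup`, `dementia`, `death` and hidden
#'   `.h_true` appended.
#' @export
simulate_outcomes <- function(data, config, seed = NULL) {
  stopifnot(all(c("dpw", ".u", "age", "sex") %in% names(data)))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  h <- causal_curve_value(data$dpw, config$curve_kind, config$curve_params)
  lp_shared <- config$confounder_effect_outcome * data$.u
  rate_dem <- config$baseline_hazard_dementia *
    exp(h + lp_shared + config$age_effect_dementia * (data$age - 65) +
          config$sex_effect_dementia * data$sex)
  rate_death <- config$baseline_hazard_death *
    exp(lp_shared + config$age_effect_death * (data$age - 65) +
          config$sex_effect_death * data$sex)
  t_dem <- ifelse(rate_dem > 0, stats::rexp(n) / rate_dem, Inf)
  t_death <- ifelse(rate_death > 0, stats::rexp(n) / rate_death, Inf)
  followup <- pmin(t_dem, t_death, config$followup_years)
  data$followup <- followup
  data$dementia <- as.integer(t_dem <= config$followup_years & t_dem <= t_death)
  data$death <- as.integer(t_death < t_dem & t_death <= config$followup_years)
  data$.h_true <- h
  data
}

# Baseline AUDIT-C level implied by drinks per week (latent points scale).
audit_level_from_dpw <- function(dpw) {
  pmin(12, pmax(0, round(3 * log1p(dpw))))
}

#' Simulate longitudinal AUDIT-C records
#'
#' Repeated AUDIT-C scores at `audit_visits` times evenly spaced on
#' `[-audit_span_years, 0]`, with time measured relative to diagnosis
#' (cases) or last follow-up (controls). The latent points-scale trajectory
#' has a baseline level set by the participant's drinking intensity, a
#' common slow decline over calendar time, and — for dementia cases inside
#' the prodrome window — an extra decline of `prodrome_extra_slope` points
#' per year. Scores are observed with noise, rounded and clamped to the
#' 0-12 integer scale. Nondrinkers abstain consistently: all their repeated
#' scores are 0.
#'
#' @param data cohort data frame with `id`, `dpw`, `drinker`, `dementia`,
#'   and the covariates carried into the longitudinal records.
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return a long data frame: `id`, `time` (years, <= 0), `audit_c`,
#'   `dementia`, `risk_group` (baseline), plus covariates.
#' @export
simulate_trajectories <- function(data, config, seed = NULL) {
  if (config$audit_visits < 2L) stop("audit_visits must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  v <- config$audit_visits
  times <- seq(-config$audit_span_years, 0, length.out = v)
  audit0 <- audit_level_from_dpw(data$dpw)
  risk_group <- audit_c_risk_group(audit0)
  s0 <- audit0 + stats::rnorm(n, 0, 1.5)
  prodrome_on <- data$dementia == 1
  if (config$prodrome_scope == "high") {
    prodrome_on <- prodrome_on & risk_group == "high"
  }
  common_slope <- -0.10  # points per year of general decline toward the anchor
  long <- data.frame(
    id = rep(data$id, each = v),
    time = rep(times, times = n),
    dementia = rep(data$dementia, each = v))
  s <- rep(s0, each = v) + common_slope * long$time -
    config$prodrome_extra_slope *
    pmax(0, long$time + config$prodrome_years) * rep(prodrome_on, each = v)
  score <- pmin(12, pmax(0, round(s + stats::rnorm(n * v, 0, 0.8))))
  score[rep(data$drinker == 0L, each = v)] <- 0L
  long$audit_c <- as.integer(score)
  long$risk_group <- rep(risk_group, each = v)
  for (col in intersect(c("age", "sex", "education", "income", "bmi", "smoking"),
                        names(data))) {
    long[[col]] <- rep(data[[col]], each = v)
  }
  long
}

#' Derive per-SNP GWAS summary statistics from a simulated cohort
#'
#' The exposure trait is drinks per week among current drinkers (on the log
#' or raw scale) analysed by per-SNP linear regression; the outcome trait is
#' dementia analysed by per-SNP logistic regression; both adjust for age and
#' sex. Monomorphic SNPs are excluded and recorded in `attr(, "excluded")`.
#'
#' @param sim a `sim_cohort` object from [simulate_cohort()], or a list with
#'   elements `cohort` (data frame) and `dosages` (matrix).
#' @param scale scale of the exposure trait: `"log"` (log-DPW, the
#'   convention of quantity-frequency GWAS) or `"identity"` (raw DPW, on
#'   which a linear causal curve's slope is the Wald-ratio estimand).
#' @param method per-SNP logistic fits: `"glm"` (exact maximum likelihood
#'   per SNP) or `"score"` (one-step efficient-score estimate from a single
#'   null model — the standard biobank-scale approximation, used by the
#'   large simulation loops). Linear exposure fits are always exact (via
#'   residualization, identical to per-SNP least squares).
#' @return list with elements `exposure` and `outcome`, each a
#'   [summary_stats] table over the same retained variants.
#' @export
generate_summary_stats <- function(sim, scale = c("log", "identity"),
                                   method = c("glm", "score")) {
  scale <- match.arg(scale)
  method <- match.arg(method)
  ch <- sim$cohort
  g <- sim$dosages
  keep <- apply(g, 2L, stats::var) > 0
  excluded <- colnames(g)[!keep]
  g <- g[, keep, drop = FALSE]
  m <- ncol(g)
  if (m == 0L) stop("no polymorphic SNPs retained", call. = FALSE)
  eaf <- colMeans(g) / 2

  drink <- ch$drinker == 1L
  y_exp <- if (scale == "log") log(ch$dpw[drink]) else ch$dpw[drink]
  exp_fit <- snp_linear_scan(g[drink, , drop = FALSE], y_exp,
                             cbind(age = ch$age[drink], sex = ch$sex[drink]))
  out_fit <- snp_logistic_scan(g, ch$dementia,
                               cbind(age = ch$age, sex = ch$sex), method)
  make_tab <- function(fit, n_used) {
    summary_stats(data.frame(
      variant_id = colnames(g), chrom = "1",
      pos = 1000L * seq_len(m),
      effect_allele = "A", other_allele = "G",
      eaf = eaf, beta = fit$beta, se = fit$se, pval = fit$pval,
      n = n_used, stringsAsFactors = FALSE))
  }
  res <- list(exposure = make_tab(exp_fit, sum(drink)),
              outcome = make_tab(out_fit, nrow(ch)))
  attr(res, "excluded") <- excluded
  res
}

# Per-SNP linear regression adjusted for covariates, by residualization
# (Frisch-Waugh: identical to fitting each SNP in a full lm).
snp_linear_scan <- function(g, y, covars) {
  x <- cbind(1, covars)
  qx <- qr(x)
  ry <- qr.resid(qx, y)
  rg <- qr.resid(qx, g)
  sxx <- colSums(rg^2)
  beta <- colSums(rg * ry) / sxx
  df <- length(y) - ncol(x) - 1L
  rss <- sum(ry^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tval <- beta / se
  list(beta = beta, se = se,
       pval = pmax(2 * stats::pt(-abs(tval), df), .Machine$double.xmin))
}

snp_logistic_scan <- function(g, y, covars, method = c("glm", "score")) {
  method <- match.arg(method)
  m <- ncol(g)
  if (method == "glm") {
    beta <- se <- numeric(m)
    for (j in seq_len(m)) {
      x <- cbind(1, g[, j], covars)
      fit <- stats::glm.fit(x, y, family = stats::binomial())
      cov <- chol2inv(chol(crossprod(x * sqrt(fit$weights))))
      beta[j] <- fit$coefficients[2L]
      se[j] <- sqrt(cov[2L, 2L])
    }
  } else {
    x <- cbind(1, covars)
    null_fit <- stats::glm.fit(x, y, family = stats::binomial())
    p <- null_fit$fitted.values
    w <- p * (1 - p)
    xtwx_inv <- chol2inv(chol(crossprod(x * sqrt(w))))
    g_adj <- g - x %*% (xtwx_inv %*% crossprod(x * w, g))
    v <- colSums(w * g_adj^2)
    beta <- colSums(g_adj * (y - p)) / v
    se <- 1 / sqrt(v)
  }
  z <- beta / se
  list(beta = beta, se = se,
       pval = pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin))
}

#' Simulate a full cohort with genotypes, outcomes and drinking histories
#'
#' Orchestrates the generator: genotypes, instrument weights, latent
#' frailty, covariates, the hurdle exposure, competing outcomes, the
#' enrolment re-measurement of drinks per week (attenuated inside the
#' prodrome window for cases), and longitudinal AUDIT-C records. All draws
#' come from `config$seed`; re-running with the same configuration
#' reproduces the cohort exactly.
#'
#' @param config a [sim_config()].
#' @param with_trajectories generate the longitudinal AUDIT-C records?
#'   (Skipping them speeds up simulation loops that only need baseline
#'   data.)
#' @return an object of class `sim_cohort`: a list with elements `cohort`
#'   (baseline table including hidden ground-truth columns), `dosages`,
#'   `weights` (true per-SNP exposure weights), `longitudinal` (`NULL` when
#'   skipped) and `config`.
#' @export
simulate_cohort <- function(config = sim_config(), with_trajectories = TRUE) {
  set.seed(config$seed)
  n <- config$n
  g <- simulate_genotypes(n, config$m, config$eaf_range)
  weights <- abs(stats::rnorm(config$m))
  names(weights) <- colnames(g)
  u <- stats::rnorm(n)
  expo <- simulate_exposure(g, weights, config, u = u)

  age <- pmin(90, pmax(40, stats::rnorm(n, 65, 8)))
  sex <- stats::rbinom(n, 1L, 0.9)
  edu_latent <- -0.3 * u + stats::rnorm(n)
  education <- cut(edu_latent, c(-Inf, -0.6, 0.8, Inf),
                   labels = c("low", "mid", "high"))
  inc_latent <- -0.3 * u + stats::rnorm(n)
  income <- cut(inc_latent, c(-Inf, -0.6, 0.8, Inf),
                labels = c("low", "mid", "high"))
  bmi <- 28 + 0.8 * u + stats::rnorm(n, 0, 3.5)
  smoking <- factor(ifelse(stats::rbinom(n, 1L, stats::plogis(-2 + 0.4 * u)) == 1L,
                           "daily", "never"), levels = c("never", "daily"))
  pcs <- matrix(stats::rnorm(n * 10L), n, 10L,
                dimnames = list(NULL, paste0("pc", 1:10)))

  ch <- data.frame(id = seq_len(n), age = age, sex = sex,
                   education = as.character(education),
                   income = as.character(income),
                   bmi = bmi, smoking = as.character(smoking),
                   stringsAsFactors = FALSE)
  ch <- cbind(ch, pcs, expo)
  ch <- simulate_outcomes(ch, config)
  ch$.abstain_cause <- ifelse(ch$drinker == 1L, "",
                              ifelse(ch$drink_status == "former",
                                     "sick_quitter_or_quit", "never"))
  # Enrolment re-measurement: cases already inside the prodrome window at
  # enrolment report proportionally lower intake than their earliest record;
  # the relative decline scales with the prodromal AUDIT-C slope.
  prodrome_frac <- pmax(0, config$prodrome_years - ch$followup)
  decline_rate <- 0.5 * config$prodrome_extra_slope
  ch$dpw_enrol <- ch$dpw *
    exp(-decline_rate * prodrome_frac * (ch$dementia == 1L))
  long <- if (with_trajectories) simulate_trajectories(ch, config) else NULL
  structure(list(cohort = cohort(ch), dosages = g, weights = weights,
                 longitudinal = long, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  ch <- x$cohort
  cat(sprintf("Simulated cohort: n=%d, m=%d SNPs, curve=%s\n",
              nrow(ch), ncol(x$dosages), x$config$curve_kind))
  cat(sprintf("  drinkers %.1f%%, dementia %d, deaths %d, mean follow-up %.2f y\n",
              100 * mean(ch$drinker), sum(ch$dementia), sum(ch$death),
              mean(ch$followup)))
  if (!is.null(x$longitudinal)) {
    cat(sprintf("  AUDIT-C records: %d visits x %d participants\n",
                x$config$audit_visits, nrow(ch)))
  }
  invisible(x)
}
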