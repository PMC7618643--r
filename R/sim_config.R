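#' Simulation configuration
#'
#' Collects every knob of the synthetic-cohort generator. Defaults encode
#' the study conditions the analyses are designed for: a veteran-style
#' cohort (mean age 65, ~90% male, ~92% current drinkers) followed for a
#' mean of 4.3 years, a right-skewed drinks-per-week (DPW) distribution that
#' is log-normal above zero with a separate abstention process, dementia and
#' death as competing cause-specific exponential hazards, and the two
#' reverse-causation mechanisms under study: sick-quitter abstention (latent
#' frailty pushes people out of drinking and raises both hazards) and
#' prodromal decline in AUDIT-C before a dementia diagnosis.
#'
#' @param n number of individuals.
#' @param m number of biallelic SNPs in the instrument panel.
#' @param eaf_range interval (or single value) in (0,1) from which per-SNP
#'   effect-allele frequencies are drawn uniformly.
#' @param grs_effect effect of one standard deviation of the weighted
#'   genetic score on latent log-DPW (unitless; default 0.25, i.e. the score
#'   explains ~6% of latent variance — at the upper end of what current DPW
#'   instrument panels achieve, chosen so desk-scale cohorts retain the
#'   instrument strength the full-size studies have).
#' @param confounder_effect_exposure effect of the latent confounder/frailty
#'   `U` (standard normal) on latent log-DPW.
#' @param confounder_effect_outcome effect of `U` on both log cause-specific
#'   hazards; this is what makes sick quitters high-risk.
#' @param abstain_base_rate marginal abstention probability at `U = 0`.
#' @param sick_quitter_strength log-odds increase in abstention per unit
#'   `U`; 0 switches the sick-quitter mechanism off.
#' @param curve_kind ground-truth causal dose-response of DPW on the
#'   dementia log-hazard: `"null"` (0), `"linear"` (`c * dpw`), `"threshold"`
#'   (`c * max(dpw - tau, 0)`) or `"ushape"` (`c1 * (dpw - nu)^2`).
#' @param curve_params named list of curve parameters; unspecified entries
#'   take the defaults `c = 0.02` (linear, per DPW), `c = 0.03, tau = 14`
#'   (threshold), `c1 = 0.002, nu = 7` (U-shape).
#' @param baseline_hazard_dementia,baseline_hazard_death per-year baseline
#'   rates (at `dpw = 0`, `U = 0`, age 65, female); the defaults give
#'   roughly 5% dementia incidence and 9% mortality over the default
#'   follow-up, matching the veteran cohort the generator emulates.
#' @param followup_years administrative censoring time in years (default
#'   4.3, the mean follow-up of the cohort the generator emulates).
#' @param prodrome_years length in years of the pre-diagnosis window in
#'   which cases' drinking declines faster (a free parameter of the
#'   mechanism; default 3).
#' @param prodrome_extra_slope extra AUDIT-C decline, in points per year,
#'   for cases inside the prodrome window (default 0.42; chosen so the
#'   fitted dementia-by-time interaction on the logit scale has magnitude
#'   about 0.05 at the default design — see the methods vignette).
#' @param prodrome_scope `"all"` applies the prodromal decline to every
#'   case; `"high"` restricts it to cases whose baseline AUDIT-C risk group
#'   is high (used to emulate magnification by historical drinking).
#' @param audit_visits number of repeated AUDIT-C records per participant
#'   (>= 2, default 5), evenly spaced over `audit_span_years`.
#' @param audit_span_years years before the anchor (diagnosis for cases,
#'   last follow-up for controls) covered by the AUDIT-C records.
#' @param exposure_mean_log,exposure_sd_log intercept and residual standard
#'   deviation of latent log-DPW (defaults 2.0 and 0.7, giving a drinker
#'   median of ~7 DPW with a realistic heavy tail).
#' @param age_effect_dementia,sex_effect_dementia,age_effect_death,sex_effect_death
#'   log-hazard coefficients for age (per year, centred at 65) and male sex.
#' @param seed integer seed governing every random draw of the generator.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n = 20000L,
                       m = 100L,
                       eaf_range = c(0.1, 0.9),
                       grs_effect = 0.25,
                       confounder_effect_exposure = 0.3,
                       confounder_effect_outcome = 0.5,
                       abstain_base_rate = 0.08,
                       sick_quitter_strength = 1.0,
                       curve_kind = c("null", "linear", "threshold", "ushape"),
                       curve_params = list(),
                       baseline_hazard_dementia = 0.007,
                       baseline_hazard_death = 0.012,
                       followup_years = 4.3,
                       prodrome_years = 3,
                       prodrome_extra_slope = 0.42,
                       prodrome_scope = c("all", "high"),
                       audit_visits = 5L,
                       audit_span_years = 9,
                       exposure_mean_log = 2.0,
                       exposure_sd_log = 0.7,
                       age_effect_dementia = 0.10,
                       sex_effect_dementia = 0.10,
                       age_effect_death = 0.09,
                       sex_effect_death = 0.30,
                       seed = 1L) {
  curve_kind <- match.arg(curve_kind)
  prodrome_scope <- match.arg(prodrome_scope)
  defaults <- switch(curve_kind,
    null = list(),
    linear = list(c = 0.02),
    threshold = list(c = 0.03, tau = 14),
    ushape = list(c1 = 0.002, nu = 7))
  curve_params <- utils::modifyList(defaults, curve_params)
  cfg <- list(
    n = as.integer(n), m = as.integer(m), eaf_range = eaf_range,
    grs_effect = grs_effect,
    confounder_effect_exposure = confounder_effect_exposure,
    confounder_effect_outcome = confounder_effect_outcome,
    abstain_base_rate = abstain_base_rate,
    sick_quitter_strength = sick_quitter_strength,
    curve_kind = curve_kind, curve_params = curve_params,
    baseline_hazard_dementia = baseline_hazard_dementia,
    baseline_hazard_death = baseline_hazard_death,
    followup_years = followup_years,
    prodrome_years = prodrome_years,
    prodrome_extra_slope = prodrome_extra_slope,
    prodrome_scope = prodrome_scope,
    audit_visits = as.integer(audit_visits),
    audit_span_years = audit_span_years,
    exposure_mean_log = exposure_mean_log,
    exposure_sd_log = exposure_sd_log,
    age_effect_dementia = age_effect_dementia,
    sex_effect_dementia = sex_effect_dementia,
    age_effect_death = age_effect_death,
    sex_effect_death = sex_effect_death,
    seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n >= 1L, cfg$m >= 0L)
  r <- cfg$eaf_range
  if (!length(r) %in% c(1L, 2L) || any(r <= 0) || any(r >= 1) ||
      (length(r) == 2L && r[2] < r[1])) {
    stop("eaf_range must lie strictly inside (0,1)", call. = FALSE)
  }
  if (cfg$baseline_hazard_dementia <= 0 || cfg$baseline_hazard_death < 0) {
    stop("baseline hazards must be positive", call. = FALSE)
  }
  if (cfg$followup_years <= 0) stop("followup_years must be > 0", call. = FALSE)
  if (cfg$abstain_base_rate < 0 || cfg$abstain_base_rate >= 1) {
    stop("abstain_base_rate must lie in [0,1)", call. = FALSE)
  }
  if (cfg$sick_quitter_strength < 0) {
    stop("sick_quitter_strength must be >= 0", call. = FALSE)
  }
  if (cfg$audit_visits < 2L) stop("audit_visits must be >= 2", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Ground-truth causal dose-response curve
#'
#' Evaluates the configured causal contribution of drinks per week to the
#' dementia log-hazard.
#'
#' @param dpw numeric vector of drinks per week.
#' @param kind one of `"null"`, `"linear"`, `"threshold"`, `"ushape"`.
#' @param params named list of curve parameters (see [sim_config()]).
#' @return numeric vector of log-hazard contributions.
#' @export
causal_curve_value <- function(dpw, kind, params = list()) {
  switch(kind,
    null = rep(0, length(dpw)),
    linear = params$c * dpw,
    threshold = params$c * pmax(dpw - params$tau, 0),
    ushape = params$c1 * (dpw - params$nu)^2,
    stop("unknown curve_kind: ", kind, call. = FALSE))
}
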