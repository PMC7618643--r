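#' Binomial mixed model for AUDIT-C trajectories before diagnosis
#'
#' Models repeated AUDIT-C scores (0-12) as binomial counts with `trials =
#' 12` on the logit scale, with the standard fixed effects — time (years,
#' <= 0, relative to diagnosis for cases or last follow-up for controls),
#' dementia status, baseline risk group, their two- and three-way
#' interactions with time, and the demographic covariates — and a random
#' intercept per participant integrated by adaptive Gauss-Hermite
#' quadrature ([lme4::glmer()]).
#'
#' @param data a longitudinal data frame with columns `id`, `time` (<= 0),
#'   `audit_c` (integer 0-12), `dementia`, `risk_group`, and any covariates
#'   named in the formula.
#' @param formula model formula; the default uses
#'   `time * dementia * risk_group` plus `age + sex + education + income +
#'   bmi + smoking` when those columns are present.
#' @param trials binomial denominator (12, the AUDIT-C maximum).
#' @param nagq number of adaptive Gauss-Hermite quadrature nodes (default
#'   15; 1 gives the Laplace approximation, useful in large simulation
#'   loops).
#' @return object of class `trajectory_fit` with elements `coef`, `se`,
#'   `vcov`, `re_var` (random-intercept variance), `loglik`, `trials`,
#'   `fixed_formula`, `xlev`, `time_range`, `converged` and the underlying
#'   `glmerMod` in `$model`.
#' @export
fit_trajectory_model <- function(data, formula = NULL, trials = 12L,
                                 nagq = 15L) {
  stopifnot(all(c("id", "time", "audit_c") %in% names(data)))
  if (any(data$audit_c < 0 | data$audit_c > trials)) {
    stop("audit_c outside 0..trials", call. = FALSE)
  }
  if (any(data$time > 0)) stop("time must be <= 0 (years before anchor)",
                               call. = FALSE)
  if (all(data$audit_c == 0L) || all(data$audit_c == trials)) {
    stop("degenerate outcomes: all scores are ",
         data$audit_c[1L], call. = FALSE)
  }
  if (is.null(formula)) {
    covs <- intersect(c("age", "sex", "education", "income", "bmi", "smoking"),
                      names(data))
    rhs <- paste(c("time * dementia * risk_group", covs, "(1 | id)"),
                 collapse = " + ")
    formula <- stats::as.formula(
      paste0("cbind(audit_c, ", trials, " - audit_c) ~ ", rhs))
  }
  fit <- lme4::glmer(formula, data = data, family = stats::binomial(),
                     nAGQ = nagq,
                     control = lme4::glmerControl(calc.derivs = FALSE))
  beta <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  fixed_formula <- lme4::nobars(stats::formula(fit))[-2L]
  fr <- stats::model.frame(fit)
  fac <- names(fr)[vapply(fr, function(v) is.factor(v) || is.character(v),
                          logical(1L))]
  xlev <- lapply(fr[fac], function(v) levels(factor(v)))
  new_trajectory_fit(
    coef = beta, se = sqrt(diag(vc)), vcov = vc,
    re_var = as.numeric(lme4::VarCorr(fit)$id[1L]),
    loglik = as.numeric(stats::logLik(fit)),
    trials = trials, fixed_formula = fixed_formula, xlev = xlev,
    time_range = range(data$time),
    converged = length(fit@optinfo$conv$lme4$messages) == 0L,
    model = fit)
}

new_trajectory_fit <- function(coef, se, vcov, re_var, loglik, trials,
                               fixed_formula, xlev = list(),
                               time_range = c(-Inf, 0), converged = TRUE,
                               model = NULL) {
  structure(list(coef = coef, se = se, vcov = vcov, re_var = re_var,
                 loglik = loglik, trials = trials,
                 fixed_formula = fixed_formula, xlev = xlev,
                 time_range = time_range, converged = converged,
                 model = model), class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf(
    "Binomial (trials=%d) random-intercept trajectory model\n  random-intercept variance %.4f, logLik %.1f%s\n",
    x$trials, x$re_var, x$loglik,
    if (!x$converged) " [did not converge cleanly]" else ""))
  tab <- data.frame(coef = x$coef, se = x$se, z = x$coef / x$se)
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.trajectory_fit <- function(object, ...) object$coef

#' Wald test of a block of trajectory coefficients
#'
#' Tests the joint null that a subset of fixed effects is zero:
#' `W = theta' V^-1 theta ~ chi-square(|terms|)`. Used for the overall
#' dementia-by-time interaction effect.
#'
#' @param fit a `trajectory_fit` (or any object with `coef` and `vcov`
#'   elements).
#' @param terms character vector of coefficient names, or a regular
#'   expression when `regex = TRUE`.
#' @param regex interpret `terms` as a regular expression?
#' @return list with `statistic`, `df`, `p`, and the tested `terms`.
#' @export
wald_interaction_test <- function(fit, terms, regex = FALSE) {
  cf <- fit$coef
  if (regex) terms <- grep(terms, names(cf), value = TRUE)
  missing_terms <- setdiff(terms, names(cf))
  if (length(missing_terms) > 0L) {
    stop("unknown coefficient(s): ", paste(missing_terms, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(terms, names(cf))
  theta <- cf[idx]
  v <- fit$vcov[idx, idx, drop = FALSE]
  vi <- tryCatch(solve(v), error = function(e)
    stop("singular covariance block for tested terms", call. = FALSE))
  w <- as.numeric(t(theta) %*% vi %*% theta)
  list(statistic = w, df = length(terms),
       p = stats::pchisq(w, df = length(terms), lower.tail = FALSE),
       terms = terms)
}

#' Predicted AUDIT-C trajectories
#'
#' Population-average predictions (random intercept at zero):
#' `trials * logistic(x' beta)` on a time grid, for each dementia status by
#' risk-group combination, holding covariates at the supplied profile
#' (conventionally a male participant of average age, BMI, education and
#' income).
#'
#' @param fit a `trajectory_fit`.
#' @param profile one-row data frame (or named list) of covariate values;
#'   entries for `time`, `dementia` and `risk_group` are ignored.
#' @param times numeric grid of times (years, <= 0). Values outside the
#'   fitted range trigger an extrapolation warning.
#' @return data frame with columns `time`, `dementia`, `risk_group`,
#'   `predicted` (expected AUDIT-C score, bounded in \[0, trials\]).
#' @export
predict_trajectory <- function(fit, profile, times) {
  stopifnot(inherits(fit, "trajectory_fit"))
  if (any(times < fit$time_range[1L] - 1e-9) ||
      any(times > fit$time_range[2L] + 1e-9)) {
    warning("times outside the fitted range: predictions are extrapolations")
  }
  groups <- fit$xlev$risk_group
  if (is.null(groups)) groups <- "all"
  grid <- expand.grid(time = times, dementia = c(0L, 1L),
                      risk_group = groups, stringsAsFactors = FALSE)
  profile <- as.data.frame(profile, stringsAsFactors = FALSE)
  for (nm in setdiff(names(profile), names(grid))) grid[[nm]] <- profile[[nm]]
  x <- stats::model.matrix(fit$fixed_formula, data = grid, xlev = fit$xlev)
  keep <- colnames(x) %in% names(fit$coef)
  if (!setequal(colnames(x)[keep], names(fit$coef))) {
    stop("profile does not cover all fixed effects; missing: ",
         paste(setdiff(names(fit$coef), colnames(x)), collapse = ", "),
         call. = FALSE)
  }
  lp <- drop(x[, names(fit$coef), drop = FALSE] %*% fit$coef)
  grid$predicted <- fit$trials * stats::plogis(lp)
  grid[c("time", "dementia", "risk_group", "predicted")]
}
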