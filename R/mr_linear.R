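#' Select genetic instruments by p-value threshold
#'
#' Keeps variants below genome-wide significance (default `5e-8`); when no
#' variant passes, falls back to the relaxed threshold (default `5e-5`).
#' The threshold actually applied is recorded in `attr(, "threshold_used")`.
#'
#' @param stats a [summary_stats] table for the exposure trait.
#' @param threshold primary p-value threshold.
#' @param fallback relaxed threshold tried when the primary yields nothing;
#'   `NULL` disables the fallback.
#' @return the selected subset, still a `summary_stats` table.
#' @export
select_instruments <- function(stats, threshold = 5e-8, fallback = 5e-5) {
  sel <- stats[stats$pval < threshold, , drop = FALSE]
  used <- threshold
  if (nrow(sel) == 0L && !is.null(fallback)) {
    sel <- stats[stats$pval < fallback, , drop = FALSE]
    used <- fallback
  }
  if (nrow(sel) == 0L) stop("no instruments at either threshold", call. = FALSE)
  rownames(sel) <- NULL
  attr(sel, "threshold_used") <- used
  sel
}

is_palindromic <- function(a1, a2) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[a1]) & !is.na(comp[a2]) & comp[a1] == a2
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the two tables on shared variants so that both betas refer to the
#' same effect allele: exact allele matches are kept as-is; swapped
#' effect/other pairs have the outcome beta negated (and its frequency
#' reflected); palindromic variants (A/T or C/G) whose exposure
#' effect-allele frequency lies inside the ambiguity window are excluded,
#' as are variants whose alleles cannot be reconciled. Harmonizing an
#' already-aligned pair is a no-op (the operation is idempotent).
#'
#' @param exposure,outcome [summary_stats] tables.
#' @param palindromic_window effect-allele-frequency interval within which
#'   palindromic variants are treated as ambiguous (default \[0.42, 0.58\]).
#' @return object of class `harmonized_set`: a data frame with columns
#'   `variant_id`, `effect_allele`, `eaf`, `beta_x`, `se_x`, `beta_y`,
#'   `se_y`, plus an `excluded` attribute (data frame of variant, reason).
#' @export
harmonize <- function(exposure, outcome, palindromic_window = c(0.42, 0.58)) {
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0L) stop("no overlapping variants", call. = FALSE)
  ex <- exposure[match(shared, exposure$variant_id), ]
  ou <- outcome[match(shared, outcome$variant_id), ]
  same <- ex$effect_allele == ou$effect_allele & ex$other_allele == ou$other_allele
  swapped <- ex$effect_allele == ou$other_allele & ex$other_allele == ou$effect_allele
  palin <- is_palindromic(ex$effect_allele, ex$other_allele)
  ambiguous <- palin & ex$eaf >= palindromic_window[1] &
    ex$eaf <= palindromic_window[2]
  mismatch <- !(same | swapped)
  keep <- (same | swapped) & !ambiguous
  beta_y <- ifelse(swapped, -ou$beta, ou$beta)
  excluded <- data.frame(
    variant_id = shared[!keep],
    reason = ifelse(mismatch[!keep], "allele_mismatch", "ambiguous_palindromic"),
    stringsAsFactors = FALSE)
  out <- data.frame(variant_id = shared[keep],
                    effect_allele = ex$effect_allele[keep],
                    eaf = ex$eaf[keep],
                    beta_x = ex$beta[keep], se_x = ex$se[keep],
                    beta_y = beta_y[keep], se_y = ou$se[keep],
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) stop("no variants survive harmonization", call. = FALSE)
  attr(out, "excluded") <- excluded
  class(out) <- c("harmonized_set", "data.frame")
  out
}

#' Per-variant Wald ratio estimates
#'
#' The ratio estimate for variant j is `theta_j = beta_Yj / beta_Xj` with
#' first-order standard error `se(beta_Yj) / |beta_Xj|` (denominator
#' uncertainty ignored, the standard summary-MR approximation). Variants
#' with `beta_X = 0` are excluded with a reason.
#'
#' @param h a `harmonized_set`.
#' @return data frame `variant_id`, `theta`, `se`, with an `excluded`
#'   attribute listing zero-denominator variants.
#' @export
ratio_estimates <- function(h) {
  zero <- h$beta_x == 0
  out <- data.frame(variant_id = h$variant_id[!zero],
                    theta = h$beta_y[!zero] / h$beta_x[!zero],
                    se = h$se_y[!zero] / abs(h$beta_x[!zero]),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- data.frame(variant_id = h$variant_id[zero],
                                      reason = rep("beta_x_zero", sum(zero)),
                                      stringsAsFactors = FALSE)
  out
}

#' Inverse-variance-weighted Mendelian randomization
#'
#' The IVW estimate is `sum(beta_X beta_Y / se_Y^2) / sum(beta_X^2 /
#' se_Y^2)` — equivalently the `beta_X^2/se_Y^2`-weighted mean of the Wald
#' ratios, or weighted least squares of `beta_Y` on `beta_X` through the
#' origin. The fixed-effect standard error is `(sum beta_X^2/se_Y^2)^-1/2`;
#' under the multiplicative random-effects model it is inflated by
#' `max(1, sqrt(Q/df))`. The default picks random-effects scaling whenever
#' `Q > df`.
#'
#' @param h a `harmonized_set` (or data frame with `beta_x`, `se_x`,
#'   `beta_y`, `se_y`).
#' @param model `"auto"`, `"fixed"` or `"random"`.
#' @param label optional exposure/outcome label carried into the result.
#' @return object of class `mr_result`: list with `beta`, `se`, `ci_lower`,
#'   `ci_upper`, `or`, `or_ci`, `Q`, `df`, `p_het`, `n_variants`,
#'   `model_used`, `per_variant` (Wald ratios and weights) and `method`.
#' @export
mr_ivw <- function(h, model = c("auto", "fixed", "random"), label = NULL) {
  model <- match.arg(model)
  if (nrow(h) < 1L) stop("empty harmonized set", call. = FALSE)
  w <- 1 / h$se_y^2
  beta <- sum(h$beta_x * h$beta_y * w) / sum(h$beta_x^2 * w)
  se_fixed <- 1 / sqrt(sum(h$beta_x^2 * w))
  ratios <- ratio_estimates(h)
  j <- nrow(h)
  if (j >= 2L) {
    wq <- h$beta_x^2 / h$se_y^2
    q <- sum(wq * (ratios$theta - beta)^2)
    df <- j - 1L
    p_het <- stats::pchisq(q, df, lower.tail = FALSE)
  } else {
    q <- NA_real_; df <- 0L; p_het <- NA_real_
  }
  scale_re <- if (j >= 2L) max(1, sqrt(q / df)) else 1
  use_random <- switch(model,
    fixed = FALSE,
    random = j >= 2L,
    auto = j >= 2L && !is.na(q) && q > df)
  se <- if (use_random) se_fixed * scale_re else se_fixed
  structure(list(
    method = "IVW", label = label,
    beta = beta, se = se,
    ci_lower = beta - 1.96 * se, ci_upper = beta + 1.96 * se,
    or = exp(beta), or_ci = exp(beta + c(-1.96, 1.96) * se),
    Q = q, df = df, p_het = p_het, n_variants = j,
    model_used = if (use_random) "multiplicative-random" else "fixed",
    per_variant = data.frame(ratios,
                             weight = h$beta_x^2 / h$se_y^2)),
    class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s Mendelian randomization%s: %d variants (%s)\n",
              x$method, if (!is.null(x$label)) paste0(" [", x$label, "]") else "",
              x$n_variants, x$model_used))
  cat(sprintf("  beta=%.4f (SE %.4f), OR=%.3f [%.3f, %.3f]\n",
              x$beta, x$se, x$or, x$or_ci[1], x$or_ci[2]))
  if (!is.na(x$Q)) {
    cat(sprintf("  heterogeneity Q=%.2f on %d df (p=%.3g)\n", x$Q, x$df, x$p_het))
  }
  invisible(x)
}

#' Cochran's Q heterogeneity and leave-one-out diagnostics
#'
#' `Q = sum w_j (theta_j - beta)^2` over the Wald ratios with weights
#' `w_j = 1/se(theta_j)^2`, on `J - 1` degrees of freedom, with per-variant
#' contributions and a leave-one-out table re-running IVW without each
#' variant (the in-scope outlier diagnostics).
#'
#' @param h a `harmonized_set` (>= 2 variants).
#' @param beta pooled estimate to test around; defaults to the IVW estimate.
#' @return list with `Q`, `df`, `p`, `contributions` (variant, theta,
#'   weight, q_j) and `leave_one_out` (variant dropped, beta, se).
#' @export
cochran_q <- function(h, beta = NULL) {
  if (nrow(h) < 2L) stop("at least 2 variants required", call. = FALSE)
  if (is.null(beta)) beta <- mr_ivw(h, model = "fixed")$beta
  ratios <- ratio_estimates(h)
  w <- 1 / ratios$se^2
  qj <- w * (ratios$theta - beta)^2
  loo <- do.call(rbind, lapply(seq_len(nrow(h)), function(j) {
    fit <- mr_ivw(h[-j, , drop = FALSE], model = "fixed")
    data.frame(dropped = h$variant_id[j], beta = fit$beta, se = fit$se,
               stringsAsFactors = FALSE)
  }))
  list(Q = sum(qj), df = nrow(h) - 1L,
       p = stats::pchisq(sum(qj), nrow(h) - 1L, lower.tail = FALSE),
       contributions = data.frame(variant_id = ratios$variant_id,
                                  theta = ratios$theta, weight = w, q = qj),
       leave_one_out = loo)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas *with* an
#' intercept (weights `1/se_Y^2`), after orienting every exposure beta
#' positive. The intercept estimates directional pleiotropy; the slope is
#' the pleiotropy-adjusted causal effect. Standard errors use the usual
#' multiplicative random-effects scaling (never deflated below the
#' fixed-effect value).
#'
#' @param h a `harmonized_set` with at least 3 variants.
#' @return list with `intercept`, `intercept_se`, `intercept_p`, `slope`,
#'   `slope_se`, `slope_p`, `sigma` and `n_variants`.
#' @export
egger <- function(h) {
  if (nrow(h) < 3L) stop("MR-Egger requires at least 3 variants (saturated otherwise)",
                         call. = FALSE)
  flip <- sign(h$beta_x)
  flip[flip == 0] <- 1
  bx <- h$beta_x * flip
  by <- h$beta_y * flip
  fit <- stats::lm(by ~ bx, weights = 1 / h$se_y^2)
  s <- summary(fit)
  scale_se <- 1 / min(1, s$sigma)  # never below the fixed-effect SE
  cf <- s$coefficients
  est <- cf[, 1L]
  se <- cf[, 2L] * scale_se
  df <- nrow(h) - 2L
  p <- 2 * stats::pt(-abs(est / se), df)
  list(intercept = est[[1L]], intercept_se = se[[1L]], intercept_p = p[[1L]],
       slope = est[[2L]], slope_se = se[[2L]], slope_p = p[[2L]],
       sigma = s$sigma, n_variants = nrow(h))
}

#' Multivariable Mendelian randomization
#'
#' Weighted least squares of the outcome betas on the matrix of exposure
#' betas without intercept, weights `1/se_Y^2`, giving each exposure's
#' direct effect conditional on the others. Exposures whose betas are all
#' zero are dropped (reported as `NA`); collinearity among the rest is an
#' error naming the offending exposures.
#'
#' @param beta_y outcome betas (length J).
#' @param beta_x_matrix J x K matrix of exposure betas (K exposures,
#'   J >= K + 1).
#' @param se_y outcome standard errors.
#' @return data frame `exposure`, `beta`, `se`, `p`.
#' @export
mvmr <- function(beta_y, beta_x_matrix, se_y) {
  x <- as.matrix(beta_x_matrix)
  if (is.null(colnames(x))) colnames(x) <- paste0("exposure", seq_len(ncol(x)))
  j <- length(beta_y)
  stopifnot(nrow(x) == j, length(se_y) == j)
  nonzero <- colSums(x != 0) > 0L
  xa <- x[, nonzero, drop = FALSE]
  if (j < ncol(xa) + 1L) stop("need more variants than exposures", call. = FALSE)
  qx <- qr(xa)
  if (qx$rank < ncol(xa)) {
    bad <- colnames(xa)[qx$pivot[(qx$rank + 1L):ncol(xa)]]
    stop("collinear exposures: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  w <- 1 / se_y^2
  xtwx <- crossprod(xa * sqrt(w))
  beta <- solve(xtwx, crossprod(xa, beta_y * w))
  vc <- solve(xtwx)
  se <- sqrt(diag(vc))
  out <- data.frame(exposure = colnames(x), beta = NA_real_, se = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  out$beta[nonzero] <- drop(beta)
  out$se[nonzero] <- se
  out$p[nonzero] <- 2 * stats::pnorm(-abs(drop(beta) / se))
  out
}

#' Rescale a binary-exposure MR estimate to a doubling of prevalence
#'
#' For a binary exposure analysed on the log-odds (liability) scale, the
#' outcome odds ratio per doubling of exposure prevalence is
#' `exp(beta * ln 2)`.
#'
#' @param beta log-OR of the outcome per unit log-odds of the exposure.
#' @param se optional standard error, for a 95% CI on the doubling scale.
#' @return list with `or_doubling` and (when `se` is given) `ci`.
#' @export
scale_binary_exposure <- function(beta, se = NULL) {
  stopifnot(is.finite(beta))
  out <- list(or_doubling = exp(beta * log(2)))
  if (!is.null(se)) {
    out$ci <- exp((beta + c(-1.96, 1.96) * se) * log(2))
  }
  out
}

#' Invert the doubling-of-prevalence scaling
#'
#' Returns the log-odds-scale beta implied by an odds ratio per doubling:
#' `beta = ln(OR) / ln 2`.
#'
#' @param or_doubling odds ratio per doubling of exposure prevalence.
#' @return the log-odds-scale beta.
#' @export
invert_binary_scaling <- function(or_doubling) {
  log(or_doubling) / log(2)
}

#' Reverse Mendelian randomization
#'
#' Estimates the effect of the outcome trait on the exposure trait by
#' swapping roles: instruments are selected from the outcome (e.g.
#' dementia) summary statistics and IVW is run with the original exposure
#' as the new outcome.
#'
#' @param outcome_stats summary statistics of the original outcome, now the
#'   exposure.
#' @param exposure_stats summary statistics of the original exposure, now
#'   the outcome.
#' @param threshold,fallback instrument-selection thresholds (see
#'   [select_instruments()]).
#' @param model IVW model (see [mr_ivw()]).
#' @return an `mr_result` labelled as the reverse analysis.
#' @export
reverse_mr <- function(outcome_stats, exposure_stats, threshold = 5e-8,
                       fallback = 5e-5, model = "auto") {
  inst <- select_instruments(outcome_stats, threshold, fallback)
  h <- harmonize(inst, exposure_stats)
  mr_ivw(h, model = model, label = "reverse")
}
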