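#' Weighted genetic risk score
#'
#' Per-individual weighted allele count: `sum_j w_j g_ij` over the
#' instrument panel, with weights oriented so each allele is
#' exposure-increasing. Missing dosages are mean-imputed per SNP; the
#' number of imputed entries is reported in `attr(, "n_imputed")`. When
#' both the weights and the dosage columns are named, alignment is by name
#' (the score is invariant to SNP ordering).
#'
#' @param dosages n x m dosage matrix (entries in \[0, 2\], `NA` allowed).
#' @param weights numeric vector of length m, optionally named.
#' @return numeric vector of scores with attribute `n_imputed`.
#' @export
compute_grs <- function(dosages, weights) {
  if (length(weights) != ncol(dosages)) {
    stop("weights length must equal number of dosage columns", call. = FALSE)
  }
  if (!is.null(names(weights)) && !is.null(colnames(dosages))) {
    if (!setequal(names(weights), colnames(dosages))) {
      stop("weight names do not match dosage columns", call. = FALSE)
    }
    weights <- weights[colnames(dosages)]
  }
  n_imputed <- 0L
  if (anyNA(dosages)) {
    n_imputed <- sum(is.na(dosages))
    mu <- colMeans(dosages, na.rm = TRUE)
    idx <- which(is.na(dosages), arr.ind = TRUE)
    dosages[idx] <- mu[idx[, 2L]]
  }
  score <- drop(dosages %*% weights)
  attr(score, "n_imputed") <- n_imputed
  score
}

#' Doubly-ranked stratification
#'
#' Divides the sample into `K` strata that are homogeneous in exposure but
#' — unlike naive exposure quantiles — do not condition on the exposure
#' directly: individuals are sorted by the instrument (ties broken by a
#' seeded jitter smaller than the smallest nonzero instrument gap), cut
#' into pre-strata of `K` consecutive individuals, and within each
#' pre-stratum ranked by exposure; stratum `j` collects the `j`-th ranked
#' member of every pre-stratum. An incomplete final pre-stratum is dropped
#' (fewer than `K` individuals). Stratum assignment depends on exposure
#' only through within-pre-stratum ranks, so it is exactly invariant to
#' strictly monotone transformations of the exposure.
#'
#' @param iv instrument values (e.g. a genetic risk score).
#' @param exposure exposure values (drinks per week; nondrinkers enter
#'   with 0).
#' @param K number of strata (>= 3; default 5).
#' @param seed seed for the tie-breaking jitter.
#' @return object of class `stratification`: list with `stratum` (integer
#'   1..K per individual, `NA` for dropped), `K`, `sizes`, `mean_exposure`
#'   (nondecreasing in stratum index), and `dropped` (count < K).
#' @export
doubly_ranked_strata <- function(iv, exposure, K = 5L, seed = NULL) {
  n <- length(iv)
  stopifnot(length(exposure) == n)
  if (K < 3L) stop("K must be >= 3", call. = FALSE)
  if (n < 2L * K) {
    stop("need at least two complete pre-strata (n >= 2K)", call. = FALSE)
  }
  iv_jittered <- iv
  if (anyDuplicated(iv)) {
    if (!is.null(seed)) set.seed(seed)
    gaps <- diff(sort(unique(iv)))
    min_gap <- if (length(gaps) > 0L) min(gaps) else 1
    iv_jittered <- iv + stats::runif(n, 0, min_gap / 2)
  }
  ord <- order(iv_jittered)
  q <- n %/% K
  kept <- ord[seq_len(q * K)]
  pre <- rep(seq_len(q), each = K)
  within_rank <- stats::ave(exposure[kept], pre,
                            FUN = function(e) rank(e, ties.method = "first"))
  stratum <- rep(NA_integer_, n)
  stratum[kept] <- as.integer(within_rank)
  sizes <- tabulate(stratum, nbins = K)
  mean_exposure <- vapply(seq_len(K),
                          function(k) mean(exposure[which(stratum == k)]),
                          numeric(1L))
  structure(list(stratum = stratum, K = K, sizes = sizes,
                 mean_exposure = mean_exposure, dropped = n - q * K),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat(sprintf("Doubly-ranked stratification: K=%d, %d dropped\n",
              x$K, x$dropped))
  print(data.frame(stratum = seq_len(x$K), n = x$sizes,
                   mean_exposure = round(x$mean_exposure, 3)))
  invisible(x)
}

# Covariate design used in the stratum-level regressions: age, age^2, sex
# and the first 10 principal components where present.
lace_covariate_matrix <- function(data, covariates) {
  if (is.null(covariates)) return(NULL)
  cols <- intersect(covariates, names(data))
  z <- NULL
  if (length(cols) > 0L) z <- as.matrix(data[cols])
  if ("age" %in% cols) z <- cbind(z, age2 = data$age^2)
  z
}

#' Localized average causal effects per stratum
#'
#' For each stratum, the LACE is the ratio of the instrument-outcome
#' association (logistic regression of dementia on the genetic score,
#' adjusted for age, age^2, sex and 10 principal components) to the
#' instrument-exposure association (linear regression of drinks per week on
#' the score, same covariates), with first-order standard error
#' `se(numerator) / |denominator|`. Strata whose denominator has
#' |z| < 2 are flagged as weak — never silently dropped.
#'
#' @param data data frame with `dementia` and the covariate columns.
#' @param grs genetic risk score vector.
#' @param strat a [doubly_ranked_strata()] result.
#' @param exposure exposure vector (drinks per week).
#' @param covariates covariate column names (default `age`, `sex`,
#'   `pc1`..`pc10`; `age^2` is added automatically with `age`).
#' @param outcome_model `"logistic"` (odds-ratio scale, default) or
#'   `"linear"` (linear-probability, faster in large simulation loops).
#' @return data frame of class `stratum_estimates`: `stratum`, `n`,
#'   `mean_exposure`, `num`, `num_se`, `den`, `den_se`, `lace`, `lace_se`,
#'   `weak`.
#' @export
stratum_lace <- function(data, grs, strat, exposure,
                         covariates = c("age", "sex", paste0("pc", 1:10)),
                         outcome_model = c("logistic", "linear")) {
  outcome_model <- match.arg(outcome_model)
  z <- lace_covariate_matrix(data, covariates)
  out <- lapply(seq_len(strat$K), function(k) {
    idx <- which(strat$stratum == k)
    x <- cbind(intercept = 1, grs = grs[idx], z[idx, , drop = FALSE])
    den_fit <- stats::lm.fit(x, exposure[idx])
    den <- den_fit$coefficients[["grs"]]
    rdf <- length(idx) - ncol(x)
    sigma2 <- sum(den_fit$residuals^2) / rdf
    xtx_inv <- chol2inv(qr.R(den_fit$qr))
    den_se <- sqrt(sigma2 * xtx_inv[2L, 2L])
    if (den == 0) stop("zero instrument-exposure association in stratum ", k,
                       call. = FALSE)
    y <- data$dementia[idx]
    if (outcome_model == "logistic") {
      fit <- stats::glm.fit(x, y, family = stats::binomial())
      cov <- chol2inv(chol(crossprod(x * sqrt(fit$weights))))
      num <- fit$coefficients[["grs"]]
      num_se <- sqrt(cov[2L, 2L])
    } else {
      fit <- stats::lm.fit(x, y)
      num <- fit$coefficients[["grs"]]
      s2 <- sum(fit$residuals^2) / rdf
      num_se <- sqrt(s2 * xtx_inv[2L, 2L])
    }
    data.frame(stratum = k, n = length(idx),
               mean_exposure = mean(exposure[idx]),
               num = num, num_se = num_se, den = den, den_se = den_se,
               lace = num / den, lace_se = num_se / abs(den),
               weak = abs(den / den_se) < 2)
  })
  out <- do.call(rbind, out)
  if (any(out$weak)) {
    warning("weak instrument in stratum(s) ",
            paste(out$stratum[out$weak], collapse = ", "),
            " (|denominator z| < 2); estimates flagged, not dropped")
  }
  class(out) <- c("stratum_estimates", "data.frame")
  out
}

# Fractional-polynomial basis in the usual convention: power 0 means log.
# fp_level is the curve contribution, fp_deriv its derivative (what a LACE
# estimates at the stratum mean).
fp_level <- function(x, p) if (p == 0) log(x) else x^p
fp_deriv <- function(x, p) if (p == 0) 1 / x else p * x^(p - 1)

#' Fractional-polynomial causal dose-response curve
#'
#' Reconstructs the causal curve from stratum-level LACE estimates by
#' inverse-variance-weighted meta-regression: each candidate fractional
#' polynomial (powers from `powers`, degree 1 or 2 with distinct powers)
#' models the *derivative* of the log-OR curve, which is what a LACE
#' estimates at its stratum's mean exposure. Candidates are fitted by
#' weighted least squares of LACE on the derivative basis evaluated at the
#' stratum means (weights `1/se^2`), the best-fitting powers maximize the
#' weighted likelihood, and the chosen derivative is integrated to a curve
#' anchored at odds ratio exactly 1 at the `reference` exposure, with
#' delta-method pointwise confidence bands. A constant derivative (power 1)
#' reproduces the IVW-pooled LACE and a log-linear curve.
#'
#' @param estimates a `stratum_estimates` data frame (or any frame with
#'   `lace`, `lace_se`, `mean_exposure`).
#' @param degree maximum number of fractional-polynomial terms, 1 or 2
#'   (needs at least `degree + 1` strata).
#' @param reference exposure value at which OR = 1 (default 1 drink per
#'   week).
#' @param powers candidate power set (default `{-2, -1, -0.5, 0, 0.5, 1, 2,
#'   3}`, 0 meaning log).
#' @param grid exposure grid for curve evaluation; defaults to 101 points
#'   spanning the reference and the stratum means.
#' @param select_degree with `degree = 2`, apply the conventional
#'   fractional-polynomial closed test: report the best degree-2 model only
#'   when it improves significantly (chi-square on 2 df of the weighted
#'   deviance difference, at `alpha_degree`) on the best degree-1 model, so
#'   that an adequately linear dose-response is reported by its
#'   single-term curve. `FALSE` forces the requested degree.
#' @param alpha_degree level of the degree-selection test (default 0.05).
#' @return object of class `causal_curve`: list with `powers` (selected),
#'   `coef`, `vcov`, `reference`, `degree_used`, `p_degree` (closed-test
#'   p-value, `NA` when not applicable), `grid` (exposure, log_or, se, or,
#'   ci_lower, ci_upper), `candidates` (power sets and weighted RSS) and
#'   the input `estimates`.
#' @export
fracpoly_fit <- function(estimates, degree = 2L, reference = 1,
                         powers = c(-2, -1, -0.5, 0, 0.5, 1, 2, 3),
                         grid = NULL, select_degree = TRUE,
                         alpha_degree = 0.05) {
  stopifnot(degree %in% c(1L, 2L))
  x <- estimates$mean_exposure
  y <- estimates$lace
  se <- estimates$lace_se
  if (length(x) < degree + 1L) {
    stop("need at least degree + 1 strata", call. = FALSE)
  }
  if (any(x <= 0)) stop("stratum mean exposures must be positive", call. = FALSE)
  w <- 1 / se^2
  fit_one <- function(pset) {
    b <- vapply(pset, function(p) fp_deriv(x, p), numeric(length(x)))
    btwb <- crossprod(b * sqrt(w))
    beta <- solve(btwb, crossprod(b, y * w))
    rss <- sum(w * (y - drop(b %*% beta))^2)
    list(powers = pset, coef = drop(beta), vcov = solve(btwb), rss = rss)
  }
  fit_degree <- function(d) {
    cand <- if (d == 1L) as.list(powers) else
      utils::combn(powers, 2L, simplify = FALSE)
    fits <- lapply(cand, fit_one)
    rss <- vapply(fits, `[[`, numeric(1L), "rss")
    list(best = fits[[which.min(rss)]],
         table = data.frame(
           degree = d,
           powers = vapply(fits, function(f)
             paste(unlist(f$powers), collapse = ","), character(1L)),
           rss = rss))
  }
  d1 <- fit_degree(1L)
  p_degree <- NA_real_
  degree_used <- 1L
  cand_table <- d1$table
  best <- d1$best
  if (degree == 2L) {
    d2 <- fit_degree(2L)
    cand_table <- rbind(cand_table, d2$table)
    if (select_degree) {
      # Weighted deviance drop of the extra term + extra power choice.
      p_degree <- stats::pchisq(d1$best$rss - d2$best$rss, df = 2L,
                                lower.tail = FALSE)
      if (p_degree < alpha_degree) {
        best <- d2$best
        degree_used <- 2L
      }
    } else {
      best <- d2$best
      degree_used <- 2L
    }
  }
  if (is.null(grid)) {
    lo <- min(reference, max(min(x) * 0.5, 0.05))
    hi <- max(x) * 1.1
    grid <- sort(unique(c(reference, seq(lo, hi, length.out = 101L))))
  }
  # Integrated curve: log OR(x) = sum_i beta_i (F_pi(x) - F_pi(reference)).
  basis_diff <- function(xx) {
    vapply(best$powers, function(p) fp_level(xx, p) - fp_level(reference, p),
           numeric(length(xx)))
  }
  a <- basis_diff(grid)
  log_or <- drop(a %*% best$coef)
  se_curve <- sqrt(rowSums((a %*% best$vcov) * a))
  curve <- data.frame(exposure = grid, log_or = log_or, se = se_curve,
                      or = exp(log_or),
                      ci_lower = exp(log_or - 1.96 * se_curve),
                      ci_upper = exp(log_or + 1.96 * se_curve))
  structure(list(
    powers = unlist(best$powers), coef = best$coef, vcov = best$vcov,
    reference = reference, degree_used = degree_used, p_degree = p_degree,
    grid = curve, candidates = cand_table,
    estimates = estimates), class = "causal_curve")
}

#' @export
print.causal_curve <- function(x, ...) {
  cat(sprintf(
    "Fractional-polynomial causal curve: powers (%s), reference %.3g (OR=1)\n",
    paste(x$powers, collapse = ", "), x$reference))
  at <- x$grid[round(seq(1, nrow(x$grid), length.out = 5L)), ]
  print(round_df(at, 3), row.names = FALSE)
  invisible(x)
}

#' Nonlinearity and trend tests on stratum estimates
#'
#' `p_linearity` compares the quadratic to the linear inverse-variance
#' meta-regression of LACE on the stratum mean exposures (chi-square test
#' of the quadratic term); a non-significant result means the quadratic
#' model is not preferred over the linear one. `p_trend` is the zero-slope
#' test in the linear meta-regression; a non-significant result means no
#' evidence for a trend in the stratum estimates.
#'
#' @param estimates a `stratum_estimates` data frame (>= 3 strata).
#' @return list with `p_linearity`, `p_trend`, `quad` (+`quad_se`),
#'   `slope` (+`slope_se`).
#' @export
test_nonlinearity_and_trend <- function(estimates) {
  x <- estimates$mean_exposure
  y <- estimates$lace
  w <- 1 / estimates$lace_se^2
  if (length(x) < 3L) stop("need at least 3 strata", call. = FALSE)
  wls <- function(xm) {
    xtwx <- crossprod(xm * sqrt(w))
    beta <- solve(xtwx, crossprod(xm, y * w))
    list(beta = drop(beta), vcov = solve(xtwx))
  }
  lin <- wls(cbind(1, x))
  quad <- wls(cbind(1, x, x^2))
  z_quad <- unname(quad$beta[3L]) / sqrt(quad$vcov[3L, 3L])
  z_lin <- unname(lin$beta[2L]) / sqrt(lin$vcov[2L, 2L])
  list(p_linearity = stats::pchisq(z_quad^2, 1L, lower.tail = FALSE),
       p_trend = 2 * stats::pnorm(-abs(z_lin)),
       quad = unname(quad$beta[3L]), quad_se = sqrt(quad$vcov[3L, 3L]),
       slope = unname(lin$beta[2L]), slope_se = sqrt(lin$vcov[2L, 2L]))
}

#' Negative-control associations per stratum
#'
#' Regresses a variable the exposure cannot cause (age or sex) on the
#' genetic score within each stratum. Under valid instruments and unbiased
#' stratification every stratum association is null; systematic deviations
#' indicate confounding or selection bias.
#'
#' @param data data frame carrying the control columns.
#' @param grs genetic risk score.
#' @param strat a [doubly_ranked_strata()] result.
#' @param controls control variable column names (default age and sex).
#' @return data frame: `stratum`, `control`, `beta`, `se`, `ci_lower`,
#'   `ci_upper`, `p`.
#' @export
negative_control <- function(data, grs, strat, controls = c("age", "sex")) {
  missing_controls <- setdiff(controls, names(data))
  if (length(missing_controls) > 0L) {
    stop("control variable(s) absent: ",
         paste(missing_controls, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (ctrl in controls) {
    for (k in seq_len(strat$K)) {
      idx <- which(strat$stratum == k)
      yv <- data[[ctrl]][idx]
      if (stats::var(yv) == 0) {
        stop("control '", ctrl, "' constant within stratum ", k, call. = FALSE)
      }
      x <- cbind(1, grs[idx])
      fit <- stats::lm.fit(x, yv)
      s2 <- sum(fit$residuals^2) / (length(idx) - 2L)
      se <- sqrt(s2 * chol2inv(qr.R(fit$qr))[2L, 2L])
      b <- fit$coefficients[[2L]]
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = k, control = ctrl, beta = b, se = se,
        ci_lower = b - 1.96 * se, ci_upper = b + 1.96 * se,
        p = 2 * stats::pnorm(-abs(b / se)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Nonlinear Mendelian randomization of drinks per week on dementia
#'
#' The full individual-level pipeline: doubly-ranked stratification on the
#' genetic risk score, per-stratum localized average causal effects,
#' fractional-polynomial reconstruction of the dose-response curve anchored
#' at the reference exposure, nonlinearity and trend tests, and
#' negative-control checks on age and sex.
#'
#' @param data cohort data frame (needs `dementia` plus covariates).
#' @param grs genetic risk score vector.
#' @param exposure exposure vector (drinks per week; defaults to
#'   `data$dpw_enrol` then `data$dpw`).
#' @param K number of strata (default 5).
#' @param degree fractional-polynomial degree (default 2).
#' @param reference reference exposure (default 1 drink per week).
#' @param covariates,outcome_model passed to [stratum_lace()].
#' @param controls negative-control variables; `NULL` skips them.
#' @param seed tie-breaking seed for the stratification.
#' @return object of class `nlmr`: list with `stratification`, `estimates`,
#'   `curve`, `tests`, `negative_controls`.
#' @export
nlmr <- function(data, grs, exposure = NULL, K = 5L, degree = 2L,
                 reference = 1,
                 covariates = c("age", "sex", paste0("pc", 1:10)),
                 outcome_model = "logistic",
                 controls = c("age", "sex"), seed = NULL) {
  if (is.null(exposure)) {
    exposure <- if ("dpw_enrol" %in% names(data)) data$dpw_enrol else data$dpw
  }
  strat <- doubly_ranked_strata(grs, exposure, K = K, seed = seed)
  est <- stratum_lace(data, grs, strat, exposure, covariates = covariates,
                      outcome_model = outcome_model)
  curve <- fracpoly_fit(est, degree = degree, reference = reference)
  tests <- test_nonlinearity_and_trend(est)
  neg <- if (!is.null(controls))
    negative_control(data, grs, strat, controls = controls) else NULL
  structure(list(stratification = strat, estimates = est, curve = curve,
                 tests = tests, negative_controls = neg), class = "nlmr")
}

#' @export
print.nlmr <- function(x, ...) {
  cat("Nonlinear Mendelian randomization (doubly-ranked, fractional polynomial)\n")
  print(round_df(as.data.frame(
    x$estimates[c("stratum", "n", "mean_exposure", "lace", "lace_se", "weak")]), 4),
    row.names = FALSE)
  cat(sprintf("selected powers (%s); p_linearity=%.3g, p_trend=%.3g\n",
              paste(x$curve$powers, collapse = ", "),
              x$tests$p_linearity, x$tests$p_trend))
  invisible(x)
}

#' @export
summary.nlmr <- function(object, ...) {
  est <- object$estimates
  out <- list(
    lace = data.frame(est[c("stratum", "n", "mean_exposure")],
                      or = exp(est$lace),
                      ci_lower = exp(est$lace - 1.96 * est$lace_se),
                      ci_upper = exp(est$lace + 1.96 * est$lace_se),
                      weak = est$weak),
    powers = object$curve$powers,
    p_linearity = object$tests$p_linearity,
    p_trend = object$tests$p_trend,
    negative_controls = object$negative_controls)
  class(out) <- "summary.nlmr"
  out
}

#' @export
print.summary.nlmr <- function(x, ...) {
  cat("Per-stratum localized average causal effects (odds-ratio scale):\n")
  print(round_df(x$lace, 4), row.names = FALSE)
  cat(sprintf("fractional-polynomial powers: %s\n",
              paste(x$powers, collapse = ", ")))
  cat(sprintf("p_linearity=%.3g, p_trend=%.3g\n", x$p_linearity, x$p_trend))
  if (!is.null(x$negative_controls)) {
    covered <- with(x$negative_controls, ci_lower <= 0 & ci_upper >= 0)
    cat(sprintf("negative controls: %d/%d stratum CIs cover 0\n",
                sum(covered), length(covered)))
  }
  invisible(x)
}

#' @export
coef.nlmr <- function(object, ...) {
  stats::setNames(object$estimates$lace,
                  paste0("stratum", object$estimates$stratum))
}

#' @export
plot.nlmr <- function(x, log_y = TRUE, ...) {
  g <- x$curve$grid
  ylim <- range(g$ci_lower, g$ci_upper)
  graphics::plot(g$exposure, g$or, type = "n", ylim = ylim,
                 log = if (log_y) "y" else "",
                 xlab = "Drinks per week", ylab = "Odds ratio for dementia", ...)
  graphics::polygon(c(g$exposure, rev(g$exposure)),
                    c(g$ci_lower, rev(g$ci_upper)),
                    col = "grey85", border = NA)
  graphics::lines(g$exposure, g$or, lwd = 2)
  graphics::abline(h = 1, lty = 2)
  graphics::points(x$curve$reference, 1, col = "red", pch = 19)
  invisible(x)
}
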