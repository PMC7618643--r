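#' Pipeline configuration
#'
#' One structured object drives an end-to-end run: the simulation
#' configuration, the analysis parameters (instrument p-value thresholds,
#' number of strata, fractional-polynomial degree, reference exposure) and
#' stage toggles. Every default equals the printed convention of the
#' analyses the pipeline reproduces: K = 5 strata, genome-wide threshold
#' 5e-8 (fallback 5e-5), reference 1 drink per week.
#'
#' @param seed master seed; overrides `sim$seed`.
#' @param sim a [sim_config()].
#' @param stages named logical vector toggling `simulate`, `observational`,
#'   `trajectories`, `mr`, `nlmr`.
#' @param p_threshold,p_fallback instrument-selection thresholds.
#' @param K number of nonlinear-MR strata (>= 3).
#' @param degree fractional-polynomial degree.
#' @param reference reference exposure in drinks per week.
#' @param nagq quadrature setting for the trajectory model in pipeline runs
#'   (default 0, the fast profiled approximation, which keeps end-to-end
#'   runs at cohort scale quick; refit interactively with more nodes for
#'   final inference).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            stages = c(simulate = TRUE, observational = TRUE,
                                       trajectories = TRUE, mr = TRUE,
                                       nlmr = TRUE),
                            p_threshold = 5e-8, p_fallback = 5e-5,
                            K = 5L, degree = 2L, reference = 1,
                            nagq = 0L) {
  stage_names <- c("simulate", "observational", "trajectories", "mr", "nlmr")
  full <- stats::setNames(rep(TRUE, 5L), stage_names)
  full[names(stages)] <- stages
  if (K < 3L) stop("K must be >= 3 for nonlinear MR", call. = FALSE)
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim, stages = full,
                 p_threshold = p_threshold, p_fallback = p_fallback,
                 K = as.integer(K), degree = as.integer(degree),
                 reference = reference, nagq = as.integer(nagq)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys `seed`, `stages`, `analysis` (with `p_threshold`,
#' `p_fallback`, `K`, `degree`, `reference`, `nagq`) and `sim` (any
#' [sim_config()] argument) are recognised; everything omitted keeps its
#' default.
#'
#' @param path path to a YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  # YAML 1.1 parses a bare `n` key as a boolean; map it back.
  names(sim_args)[names(sim_args) %in% c("FALSE", "no")] <- "n"
  if (!is.null(y$seed)) sim_args$seed <- y$seed
  an <- y$analysis %||% list()
  args <- list(seed = y$seed %||% 1L,
               sim = do.call(sim_config, sim_args))
  if (!is.null(y$stages)) args$stages <- unlist(y$stages)
  for (nm in c("p_threshold", "p_fallback", "K", "degree", "reference", "nagq")) {
    if (!is.null(an[[nm]])) args[[nm]] <- an[[nm]]
  }
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Run the full triangulation pipeline
#'
#' Executes the toggled stages in order — simulate, observational,
#' trajectories, linear MR, nonlinear MR — writing machine-readable result
#' tables (TSV), intermediate data files (cohort and longitudinal CSV,
#' summary-statistics TSV) and a JSON run manifest recording the seed,
#' package and R versions and parameters. Later stages read the files the
#' simulate stage wrote, so a stage can be re-run against an existing
#' output directory. Re-running with the same configuration reproduces
#' every result table byte-identically. Any stage error aborts the run with
#' the stage named.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  path <- function(f) file.path(out_dir, f)
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (config$stages[["simulate"]]) {
    res$sim <- run_stage("simulate", function() {
      sim <- simulate_cohort(config$sim)
      stats <- generate_summary_stats(sim, scale = "log", method = "score")
      weights_est <- stats::setNames(pmax(stats$exposure$beta, 0),
                                     stats$exposure$variant_id)
      sim$cohort$grs <- as.numeric(compute_grs(sim$dosages, weights_est))
      write_cohort(sim$cohort, path("cohort.csv"))
      utils::write.table(sim$longitudinal, path("longitudinal.csv"), sep = ",",
                         quote = FALSE, row.names = FALSE)
      write_summary_stats(stats$exposure, path("sumstats_exposure.tsv"))
      write_summary_stats(stats$outcome, path("sumstats_outcome.tsv"))
      write_tsv(data.frame(variant_id = names(weights_est),
                           effect_allele = "A",
                           weight = as.numeric(weights_est)),
                path("weights.tsv"))
      sim
    })
  }

  read_results <- function() {
    ch <- read_cohort(path("cohort.csv"))
    ch$dpw_cat <- categorize_dpw(ch$dpw, ch$drinker)
    ch
  }

  if (config$stages[["observational"]]) {
    res$observational <- run_stage("observational", function() {
      ch <- read_results()
      # Two pseudo-cohorts (split halves) exercise the pooling step the way
      # a two-cohort analysis would.
      half <- ch$id %% 2L == 0L
      fml <- survival::Surv(followup, dementia) ~ dpw_cat + age + I(age^2) +
        I(age^3) + sex + age:sex + education + income + bmi + smoking
      fit_half <- function(dd) {
        dd$dpw_cat <- droplevels(dd$dpw_cat)
        fit_cox(dd, fml)
      }
      fit_all <- fit_cox(ch, fml)
      fit_a <- fit_half(ch[half, ])
      fit_b <- fit_half(ch[!half, ])
      cats <- grep("^dpw_cat", names(fit_all$coefficients), value = TRUE)
      pooled_cats <- intersect(intersect(cats, names(fit_a$coefficients)),
                               names(fit_b$coefficients))
      pooled <- do.call(rbind, lapply(pooled_cats, function(cc) {
        pe <- meta_analyze(c(fit_a$coefficients[[cc]], fit_b$coefficients[[cc]]),
                           c(fit_a$se[[cc]], fit_b$se[[cc]]))
        data.frame(term = cc, hr = exp(pe$beta),
                   ci_lower = exp(pe$ci_lower), ci_upper = exp(pe$ci_upper),
                   tau2 = pe$tau2)
      }))
      hr_tab <- data.frame(
        category = sub("^dpw_cat", "", cats),
        hr = fit_all$hr[cats],
        ci_lower = fit_all$ci_lower[cats], ci_upper = fit_all$ci_upper[cats],
        n = fit_all$n, events = fit_all$nevent, row.names = NULL)
      write_tsv(hr_tab, path("hr_table.tsv"))
      write_tsv(pooled, path("pooled_estimates.tsv"))
      ph <- schoenfeld_check(fit_all)
      write_tsv(ph, path("schoenfeld.tsv"))
      aj <- aalen_johansen(ch, "dementia")
      write_tsv(as.data.frame(aj)[seq(1, nrow(aj),
                                      length.out = min(200L, nrow(aj))), ],
                path("cif.tsv"))
      timing <- compare_timing(ch)
      write_tsv(timing$attenuation, path("timing_comparison.tsv"))
      list(fit = fit_all, hr_table = hr_tab, pooled = pooled, schoenfeld = ph,
           aj = aj, timing = timing)
    })
  }

  if (config$stages[["trajectories"]]) {
    res$trajectories <- run_stage("trajectories", function() {
      long <- utils::read.csv(path("longitudinal.csv"))
      drinkers <- long[long$risk_group != "non_occasional", ]
      drinkers$risk_group <- factor(drinkers$risk_group,
                                    levels = c("low", "high"))
      fit <- fit_trajectory_model(drinkers, nagq = config$nagq)
      coefs <- data.frame(term = names(fit$coef), estimate = fit$coef,
                          se = fit$se, row.names = NULL)
      write_tsv(coefs, path("trajectory_coefficients.tsv"))
      profile <- list(age = mean(drinkers$age), sex = 1L,
                      education = "mid", income = "mid",
                      bmi = mean(drinkers$bmi), smoking = "never")
      pred <- predict_trajectory(fit, profile,
                                 times = seq(min(drinkers$time), 0,
                                             length.out = 25L))
      write_tsv(pred, path("predicted_trajectories.tsv"))
      wald <- wald_interaction_test(fit, "^time:dementia", regex = TRUE)
      list(fit = fit, wald = wald, predictions = pred)
    })
  }

  if (config$stages[["mr"]]) {
    res$mr <- run_stage("mr", function() {
      expo <- read_summary_stats(path("sumstats_exposure.tsv"))
      outc <- read_summary_stats(path("sumstats_outcome.tsv"))
      inst <- select_instruments(expo, config$p_threshold, config$p_fallback)
      h <- harmonize(inst, outc)
      ivw <- mr_ivw(h, label = "log-DPW on dementia")
      het <- if (nrow(h) >= 2L) cochran_q(h) else NULL
      eg <- if (nrow(h) >= 3L) egger(h) else NULL
      rev <- tryCatch(reverse_mr(outc, expo, config$p_threshold,
                                 config$p_fallback),
                      error = function(e) NULL)
      rows <- data.frame(
        analysis = "IVW forward", n_variants = ivw$n_variants,
        beta = ivw$beta, se = ivw$se, or = ivw$or,
        ci_lower = ivw$or_ci[1], ci_upper = ivw$or_ci[2],
        Q = ivw$Q, df = ivw$df, p_het = ivw$p_het)
      if (!is.null(eg)) {
        rows <- rbind(rows, data.frame(
          analysis = "Egger slope", n_variants = eg$n_variants,
          beta = eg$slope, se = eg$slope_se, or = exp(eg$slope),
          ci_lower = exp(eg$slope - 1.96 * eg$slope_se),
          ci_upper = exp(eg$slope + 1.96 * eg$slope_se),
          Q = NA, df = NA, p_het = NA))
      }
      if (!is.null(rev)) {
        rows <- rbind(rows, data.frame(
          analysis = "IVW reverse", n_variants = rev$n_variants,
          beta = rev$beta, se = rev$se, or = rev$or,
          ci_lower = rev$or_ci[1], ci_upper = rev$or_ci[2],
          Q = rev$Q, df = rev$df, p_het = rev$p_het))
      }
      write_tsv(rows, path("mr_results.tsv"))
      list(ivw = ivw, heterogeneity = het, egger = eg, reverse = rev,
           harmonized = h, table = rows)
    })
  }

  if (config$stages[["nlmr"]]) {
    res$nlmr <- run_stage("nlmr", function() {
      ch <- read_results()
      fit <- nlmr(ch, grs = ch$grs, K = config$K, degree = config$degree,
                  reference = config$reference, seed = config$seed)
      write_tsv(as.data.frame(fit$estimates), path("stratum_estimates.tsv"))
      write_tsv(fit$curve$grid, path("causal_curve.tsv"))
      write_tsv(data.frame(p_linearity = fit$tests$p_linearity,
                           p_trend = fit$tests$p_trend),
                path("nlmr_tests.tsv"))
      write_tsv(fit$negative_controls, path("negative_controls.tsv"))
      fit
    })
  }

  manifest <- list(
    seed = config$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("alctri")),
    stages = as.list(config$stages),
    analysis = config[c("p_threshold", "p_fallback", "K", "degree",
                        "reference", "nagq")],
    sim = unclass(config$sim),
    files = sort(list.files(out_dir)))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(res)
}
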