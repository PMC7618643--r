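#' Individual-level cohort tables
#'
#' A cohort table holds one baseline record per participant: demographics
#' (`age` in years, `sex` coded 1 = male / 0 = female), covariates
#' (`education` and `income` as categorical labels, `bmi`, `smoking`),
#' ancestry principal-component columns (`pc1`..`pc10`), alcohol phenotypes
#' (`dpw` = earliest-recorded drinks per week, `dpw_enrol` = enrolment
#' drinks per week, `drinker` flag, `drink_status` in never/former/current),
#' an optional genetic risk score (`grs`), and time-to-event data:
#' `followup` (years, >= 0) with indicator columns `dementia` and `death`
#' (0/1, at most one of which is 1 — the first event observed).
#'
#' Columns whose name starts with a dot (e.g. `.u`, the latent frailty used
#' by the simulator) are hidden bookkeeping columns: they are stripped on
#' write and are never part of analysis-stage input files.
#'
#' @param x a data frame with at least the columns named in `required`.
#' @param required character vector of columns that must be present.
#' @return the validated cohort data frame (classed `cohort`).
#' @export
cohort <- function(x, required = c("id", "age", "sex", "followup",
                                   "dementia", "death")) {
  x <- as.data.frame(x)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fail <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad | is.na(bad))
      stop("invalid cohort: ", what, " in row(s) ",
           paste(utils::head(rows, 5L), collapse = ", "),
           if (length(rows) > 5L) sprintf(" (and %d more)", length(rows) - 5L),
           call. = FALSE)
    }
  }
  fail(is.na(x$followup) | x$followup < 0, "negative or missing follow-up time")
  fail(!x$dementia %in% c(0, 1), "dementia indicator must be 0/1")
  fail(!x$death %in% c(0, 1), "death indicator must be 0/1")
  fail(x$dementia + x$death > 1, "dementia and death both marked as first event")
  fail(!x$sex %in% c(0, 1), "sex must be coded 0/1")
  if ("dpw" %in% names(x)) fail(is.na(x$dpw) | x$dpw < 0, "negative drinks per week")
  if ("drink_status" %in% names(x)) {
    fail(!x$drink_status %in% c("never", "former", "current"),
         "unknown drink_status label")
  }
  if (anyDuplicated(x$id)) stop("duplicate participant id", call. = FALSE)
  rownames(x) <- NULL
  class(x) <- unique(c("cohort", class(x)))
  x
}

#' Read an individual-level cohort table
#'
#' Reads a headered CSV of baseline records and validates the event-time
#' invariants (non-negative follow-up, 0/1 indicators, at most one first
#' event, known category labels). Invalid rows abort with a row-numbered
#' message; nothing is silently coerced.
#'
#' @param path path to a CSV file.
#' @param column_map optional named character vector renaming file columns
#'   to canonical names, e.g. `c(followup = "time_at_risk")` to read the
#'   file column `time_at_risk` as `followup`.
#' @return a validated `cohort` data frame.
#' @export
read_cohort <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      src <- column_map[[canonical]]
      if (!src %in% names(x)) {
        stop("column_map names absent column '", src, "'", call. = FALSE)
      }
      names(x)[names(x) == src] <- canonical
    }
  }
  cohort(x)
}

#' Write a cohort table
#'
#' Writes the analysis-visible columns as a headered CSV. Hidden columns
#' (names starting with a dot) are stripped: ground-truth quantities known
#' only to the simulator never reach analysis-stage input files.
#'
#' @param x a `cohort` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  x <- as.data.frame(x)
  x <- x[!startsWith(names(x), ".")]
  utils::write.table(x, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Event factor for competing-risks analyses
#'
#' Collapses the `dementia`/`death` indicator pair into the multistate
#' factor expected by [survival::survfit()]: censor < dementia < death.
#'
#' @param x a `cohort` data frame.
#' @return a factor of length `nrow(x)`.
#' @export
cohort_event_factor <- function(x) {
  ev <- ifelse(x$dementia == 1, "dementia", ifelse(x$death == 1, "death", "censor"))
  factor(ev, levels = c("censor", "dementia", "death"))
}
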