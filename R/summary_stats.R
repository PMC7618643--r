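#' GWAS summary-statistics tables
#'
#' A `summary_stats` object is a validated data frame of per-variant
#' association records for one trait, in the dialect used throughout the
#' package: one row per variant with columns `variant_id`, `chrom`, `pos`
#' (1-based), `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`
#' and `n`. Alleles are upper-case single-or-multi-base strings on the
#' forward strand; `beta` is the per-allele effect of the effect allele on
#' the trait scale; `eaf` is the effect-allele frequency.
#'
#' @param x a data frame carrying (at least) the required columns in any
#'   order.
#' @return a `summary_stats` data frame with columns in canonical order.
#' @details Validation is strict: rows violating any invariant (non-positive
#'   `se`, `eaf` outside \[0,1\], `pval` outside (0,1\], identical alleles,
#'   duplicated `variant_id`, non-positive `n`) abort with a row-numbered
#'   message rather than being silently dropped or coerced.
#' @export
summary_stats <- function(x) {
  x <- as.data.frame(x)
  missing_cols <- setdiff(ss_columns(), names(x))
  if (length(missing_cols) > 0L) {
    stop("summary statistics are missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[ss_columns()]
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    if (!is.numeric(x[[col]])) {
      stop("column '", col, "' must be numeric", call. = FALSE)
    }
  }
  x$variant_id <- as.character(x$variant_id)
  x$chrom <- as.character(x$chrom)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  fail <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad | is.na(bad))
      stop("invalid summary statistics: ", what, " in row(s) ",
           paste(utils::head(rows, 5L), collapse = ", "),
           if (length(rows) > 5L) sprintf(" (and %d more)", length(rows) - 5L),
           call. = FALSE)
    }
  }
  fail(is.na(x$beta), "missing beta")
  fail(is.na(x$se) | x$se <= 0, "se must be > 0")
  fail(is.na(x$eaf) | x$eaf < 0 | x$eaf > 1, "eaf must lie in [0,1]")
  fail(is.na(x$pval) | x$pval <= 0 | x$pval > 1, "pval must lie in (0,1]")
  fail(is.na(x$n) | x$n <= 0, "n must be > 0")
  fail(x$effect_allele == x$other_allele, "effect and other allele identical")
  dup <- duplicated(x$variant_id)
  if (any(dup)) {
    stop("duplicate variant_id: ",
         paste(unique(x$variant_id[dup]), collapse = ", "), call. = FALSE)
  }
  rownames(x) <- NULL
  class(x) <- c("summary_stats", "data.frame")
  x
}

ss_columns <- function() {
  c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
    "eaf", "beta", "se", "pval", "n")
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated file with a header row naming the required columns
#' (order-free; extra columns are ignored) and returns a validated
#' [summary_stats] table.
#'
#' @param path path to a tab-separated text file.
#' @return a `summary_stats` data frame.
#' @seealso [write_summary_stats()]
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  summary_stats(x)
}

#' Write a GWAS summary-statistics table
#'
#' Writes in the canonical dialect: tab-separated, header row, columns in
#' canonical order. `write_summary_stats(read_summary_stats(path), path2)`
#' byte-reproduces a file already in canonical form.
#'
#' @param x a `summary_stats` table (or a data frame that validates as one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  x <- summary_stats(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %d variants\n", nrow(x)))
  print.data.frame(utils::head(x, 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
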