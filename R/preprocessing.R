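# Preprocessing: Z-standardization with stored training statistics,
# dichotomization for reporting, complete-case splitting, and derivation of
# the composite carotid ultrasound summaries.

#' Z-standardize variables, storing training statistics
#'
#' Each listed variable is transformed to `Z = (value - mean) / sd` using the
#' sample standard deviation (n - 1 denominator). The per-variable mean and
#' sd are stored so the same transform can be applied to a new cohort
#' (training statistics are reused, never refitted) and inverted.
#'
#' @param table A data frame.
#' @param variables Character vector of numeric columns to standardize.
#' @return A `zstd_tbl`: list with `data` (tibble of Z-scores; non-listed
#'   columns carried through unchanged) and `stats` (tibble with `variable`,
#'   `mean`, `sd`).
#' @examples
#' z <- z_standardize(data.frame(x = c(1, 2, 3)), "x")
#' z$data$x  # -1 0 1
#' @export
z_standardize <- function(table, variables) {
  stopifnot(is.data.frame(table))
  if (length(variables) == 0) abort_endo("`variables` must be non-empty.")
  missing_vars <- setdiff(variables, names(table))
  if (length(missing_vars) > 0) {
    abort_endo(paste0("Variables not in table: ",
                      paste(missing_vars, collapse = ", ")))
  }
  mu <- vapply(variables, function(v) mean(table[[v]]), numeric(1))
  sd_ <- vapply(variables, function(v) stats::sd(table[[v]]), numeric(1))
  bad <- variables[!is.finite(sd_) | sd_ <= 0]
  if (length(bad) > 0) {
    abort_endo(paste0("Zero-variance (or non-numeric/missing) variable(s): ",
                      paste(bad, collapse = ", ")),
               class = "endotyper_zero_variance")
  }
  stats_tbl <- tibble::tibble(variable = variables, mean = unname(mu),
                              sd = unname(sd_))
  out <- structure(list(data = NULL, stats = stats_tbl), class = "zstd_tbl")
  out$data <- zstd_apply(out, table)
  out
}

#' Apply stored standardization statistics to new data
#'
#' @param zstd A `zstd_tbl` from [z_standardize()].
#' @param table New data containing the standardized variables.
#' @return Tibble with the listed variables replaced by Z-scores computed
#'   from the stored training mean/sd.
#' @export
zstd_apply <- function(zstd, table) {
  stopifnot(inherits(zstd, "zstd_tbl"), is.data.frame(table))
  missing_vars <- setdiff(zstd$stats$variable, names(table))
  if (length(missing_vars) > 0) {
    abort_endo(paste0("New data lacks variable(s): ",
                      paste(missing_vars, collapse = ", ")))
  }
  out <- tibble::as_tibble(table)
  for (i in seq_len(nrow(zstd$stats))) {
    v <- zstd$stats$variable[i]
    out[[v]] <- (out[[v]] - zstd$stats$mean[i]) / zstd$stats$sd[i]
  }
  out
}

#' Invert a Z-standardization
#'
#' @param zstd A `zstd_tbl`.
#' @param table Data on the Z scale.
#' @return Tibble on the original scale.
#' @export
zstd_invert <- function(zstd, table) {
  stopifnot(inherits(zstd, "zstd_tbl"), is.data.frame(table))
  out <- tibble::as_tibble(table)
  for (i in seq_len(nrow(zstd$stats))) {
    v <- zstd$stats$variable[i]
    if (v %in% names(out)) {
      out[[v]] <- out[[v]] * zstd$stats$sd[i] + zstd$stats$mean[i]
    }
  }
  out
}

#' @export
print.zstd_tbl <- function(x, ...) {
  cat(sprintf("<zstd_tbl> %d variables standardized over %d rows\n",
              nrow(x$stats), nrow(x$data)))
  invisible(x)
}

#' Tidy the stored standardization statistics
#' @param x A `zstd_tbl`.
#' @param ... Unused.
#' @return Tibble with `variable`, `mean`, `sd`.
#' @method tidy zstd_tbl
#' @export
tidy.zstd_tbl <- function(x, ...) x$stats

#' Write/read standardization statistics as JSON
#' @param zstd A `zstd_tbl`.
#' @param path JSON path.
#' @return `path` invisibly, or the restored statistics tibble.
#' @export
write_zstd_stats <- function(zstd, path) {
  jsonlite::write_json(zstd$stats, path, digits = NA)
  invisible(path)
}

#' @rdname write_zstd_stats
#' @export
read_zstd_stats <- function(path) {
  stats_tbl <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  structure(list(data = NULL, stats = stats_tbl), class = "zstd_tbl")
}

#' Dichotomize Z-scores at the standardized mean
#'
#' Values below the standardized mean (Z < 0) are `low`; values at or above
#' it are `high` (the tie at exactly 0 is labelled `high`).
#'
#' @param z Numeric vector of finite Z-scores.
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize <- function(z) {
  if (length(z) > 0 && !all(is.finite(z))) {
    abort_endo("`z` must be finite.")
  }
  factor(ifelse(z < 0, "low", "high"), levels = c("low", "high"))
}

#' Split subjects into complete-case (derived) and incomplete (replicated) sets
#'
#' Subjects with no missing value among the listed analysis variables form
#' the derived set; subjects with at least one missing value among them form
#' the replicated set. Missingness in non-listed columns is ignored.
#'
#' @param table A data frame with a `subject_id` column.
#' @param variables Analysis variables to screen for missingness.
#' @return List with `derived` and `replicated` subject-id vectors.
#' @export
split_complete_cases <- function(table, variables) {
  stopifnot(is.data.frame(table))
  if (length(variables) == 0) abort_endo("`variables` must be non-empty.")
  missing_vars <- setdiff(variables, names(table))
  if (length(missing_vars) > 0) {
    abort_endo(paste0("Variables not in table: ",
                      paste(missing_vars, collapse = ", ")))
  }
  ids <- if ("subject_id" %in% names(table)) table$subject_id else seq_len(nrow(table))
  any_miss <- rowSums(is.na(table[, variables, drop = FALSE])) > 0
  list(derived = ids[!any_miss], replicated = ids[any_miss])
}

#' Derive composite carotid ultrasound summaries
#'
#' Per subject: `cimt_mean_max` is the average of the per-segment c-IMT
#' maxima over the whole carotid tree; `cimt_max` is the largest per-segment
#' maximum; `fastest_progr` is the annual change of the fastest progressing
#' segment (the max over per-segment changes); `log_fastest_progr` is
#' `log10(fastest_progr + 0.1)`.
#'
#' @param segments Data frame / matrix of per-segment baseline c-IMT maxima
#'   (one row per subject, one column per segment).
#' @param progression Optional per-segment annual change (same shape).
#' @return Tibble with `cimt_mean_max`, `cimt_max` and, when progression is
#'   supplied, `fastest_progr` and `log_fastest_progr`.
#' @export
derive_ultrasound_summaries <- function(segments, progression = NULL) {
  seg <- as.matrix(segments)
  if (ncol(seg) < 1 || nrow(seg) < 1) abort_endo("Need >= 1 segment per subject.")
  out <- tibble::tibble(
    cimt_mean_max = rowMeans(seg),
    cimt_max = apply(seg, 1, max)
  )
  if (!is.null(progression)) {
    prog <- as.matrix(progression)
    stopifnot(nrow(prog) == nrow(seg))
    fastest <- apply(prog, 1, max)
    if (any(fastest + 0.1 <= 0)) {
      abort_endo("`fastest_progr` + 0.1 must be > 0 for the log transform.")
    }
    out$fastest_progr <- fastest
    out$log_fastest_progr <- log10(fastest + 0.1)
  }
  out
}

#' Attach derived ultrasound summaries to a cohort table
#'
#' Convenience wrapper around [derive_ultrasound_summaries()] for cohort
#' tables produced by [generate_cohort()].
#'
#' @param cohort A `cohort_tbl`.
#' @return The cohort with `cimt_mean_max`, `cimt_max`, `fastest_progr` and
#'   `log_fastest_progr` columns appended (roles `ultrasound_baseline` /
#'   `ultrasound_progression`).
#' @export
add_ultrasound_summaries <- function(cohort) {
  seg_cols <- grep("^cimt_max_seg", names(cohort), value = TRUE)
  prog_cols <- grep("^cimt_progr_seg", names(cohort), value = TRUE)
  if (length(seg_cols) == 0) abort_endo("No per-segment c-IMT columns found.")
  der <- derive_ultrasound_summaries(cohort[, seg_cols, drop = FALSE],
                                     if (length(prog_cols) > 0)
                                       cohort[, prog_cols, drop = FALSE])
  roles <- attr(cohort, "roles")
  schema <- attr(cohort, "module_truth")
  cfg <- attr(cohort, "config")
  out <- dplyr::bind_cols(cohort, der)
  new_roles <- c(cimt_mean_max = "ultrasound_baseline",
                 cimt_max = "ultrasound_baseline",
                 fastest_progr = "ultrasound_progression",
                 log_fastest_progr = "ultrasound_progression")
  if (!is.null(roles)) {
    attr(out, "roles") <- c(roles, new_roles[intersect(names(new_roles), names(der))])
  }
  attr(out, "module_truth") <- schema
  attr(out, "config") <- cfg
  class(out) <- unique(c("cohort_tbl", class(out)))
  out
}
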