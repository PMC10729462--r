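#' Validate and normalise a cross-over trial data frame
#'
#' A trial data frame holds one row per subject x period x time point of a
#' two-treatment, two-period cross-over trial with four repeated measurements
#' per period.  Canonical columns: `subject_id` (character), `sequence`
#' (`"PV"` = placebo first, `"VP"` = verum first), `period` (1 or 2),
#' `treatment` (`"placebo"` / `"verum"`), `time` (1 = baseline,
#' 2 = on-treatment, 3 = post-treatment visit, 4 = follow-up visit),
#' `count` (non-negative integer outcome, e.g. blister count), `vas`
#' (ordinal 0-10 score on a half-point grid) and optionally `binary`
#' (0/1 responder indicator, usually derived via [dichotomize()]).
#'
#' Validation enforces the design invariants: treatment is determined by
#' (sequence, period); every (subject, period) contributes exactly the four
#' time points 1-4; each subject receives both treatments exactly once; no
#' missing values (the simulation machinery assumes complete cases).
#' Row order is normalised to (subject, period, time).
#'
#' An object already carrying the `trial_df` class is returned as is (it was
#' validated on construction, and the package's own transformations preserve
#' the invariants); pass `revalidate = TRUE` to force a full re-check, e.g.
#' after hand-editing columns.
#'
#' @param x A data frame with the columns described above.
#' @param revalidate Re-run validation even on a `trial_df` input.
#' @return A validated tibble of class `trial_df`.
#' @export
#' @examples
#' d <- generate_trial(seed = 1)
#' as_trial_data(d)
as_trial_data <- function(x, revalidate = FALSE) {
  if (inherits(x, "trial_df") && !revalidate) return(x)
  x <- tibble::as_tibble(x)
  required <- c("subject_id", "sequence", "period", "treatment", "time",
                "count", "vas")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("trial data is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- intersect(c(required, "binary"), names(x))
  x <- x[keep]
  x$subject_id <- as.character(x$subject_id)
  x$sequence <- as.character(x$sequence)
  x$treatment <- as.character(x$treatment)
  x$period <- .as_strict_integer(x$period, "period")
  x$time <- .as_strict_integer(x$time, "time")
  x$count <- .as_strict_integer(x$count, "count")
  x$vas <- as.double(x$vas)
  if ("binary" %in% names(x) && !all(is.na(x$binary))) {
    x$binary <- .as_strict_integer(x$binary, "binary")
  }

  if (nrow(x) == 0) {
    return(structure(x, class = c("trial_df", class(tibble::tibble()))))
  }

  core <- setdiff(names(x), "binary")
  if (anyNA(x[core])) {
    stop("trial data must be complete: missing values found", call. = FALSE)
  }
  if (!all(x$sequence %in% c("PV", "VP"))) {
    stop("sequence must be 'PV' (placebo first) or 'VP' (verum first)",
         call. = FALSE)
  }
  if (!all(x$period %in% 1:2)) stop("period must be 1 or 2", call. = FALSE)
  if (!all(x$time %in% 1:4)) stop("time must be in 1..4", call. = FALSE)
  if (!all(x$treatment %in% c("placebo", "verum"))) {
    stop("treatment must be 'placebo' or 'verum'", call. = FALSE)
  }
  expected <- ifelse(
    (x$sequence == "PV") == (x$period == 1), "placebo", "verum")
  if (!all(x$treatment == expected)) {
    stop("treatment labels inconsistent with (sequence, period)",
         call. = FALSE)
  }
  if (any(x$count < 0)) stop("count outcome must be non-negative",
                             call. = FALSE)
  if (any(x$vas < 0 | x$vas > 10) || any(abs(x$vas * 2 - round(x$vas * 2)) > 1e-8)) {
    stop("vas values must lie on the half-point grid {0, 0.5, ..., 10}",
         call. = FALSE)
  }
  if ("binary" %in% names(x) && !all(is.na(x$binary)) &&
      !all(x$binary %in% c(0L, 1L))) {
    stop("binary outcome must be 0/1", call. = FALSE)
  }

  key <- paste(x$subject_id, x$period, x$time)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicated (subject, period, time) record: ", dup, call. = FALSE)
  }
  tab <- table(x$subject_id, x$period)
  if (!all(dim(tab) == c(length(unique(x$subject_id)), 2L)) || !all(tab == 4L)) {
    stop("every (subject, period) pair must contribute exactly 4 time points",
         call. = FALSE)
  }
  trt_tab <- table(x$subject_id, x$treatment)
  if (!all(trt_tab == 4L)) {
    stop("each subject must receive both treatments exactly once",
         call. = FALSE)
  }

  x <- dplyr::arrange(x, .data$subject_id, .data$period, .data$time)
  structure(x, class = c("trial_df", class(tibble::tibble())))
}

.as_strict_integer <- function(v, what) {
  if (is.character(v)) v <- suppressWarnings(as.numeric(v))
  if (all(is.na(v))) return(as.integer(v))
  bad <- !is.na(v) & abs(v - round(v)) > 1e-8
  if (any(bad)) stop(what, " must be integer-valued", call. = FALSE)
  as.integer(round(v))
}

#' Read a cross-over trial dataset from CSV
#'
#' @param path Path to a comma-separated, UTF-8 file with one header row.
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(count = "blisters", subject_id = "patient")`.  Unmapped canonical
#'   names are looked up verbatim.
#' @return A validated [as_trial_data()] tibble.
#' @export
read_trial_csv <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    bad <- setdiff(unname(schema), names(raw))
    if (length(bad) > 0) {
      stop("schema maps to column(s) absent from file: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (canonical in names(schema)) {
      names(raw)[names(raw) == schema[[canonical]]] <- canonical
    }
  }
  as_trial_data(raw)
}

#' Write a trial dataset to CSV
#'
#' Round-trip stable: `read_trial_csv()` of the written file reproduces the
#' dataset field for field.  An empty dataset yields a header-only file.
#'
#' @param data A trial data frame (validated on the way out).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  data <- as_trial_data(data)
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' Derive the binary responder outcome from counts
#'
#' A subject-period is a responder at a post-baseline visit when the count
#' outcome has dropped strictly more than `threshold` (default 40%) below
#' that period's own baseline value.  Baseline rows are coded 0, and a
#' baseline count of zero admits no definable reduction, so all of that
#' block's rows are coded 0.  The headline responder status of the
#' motivating trial is this indicator read at the post-treatment visit
#' (time 3); the derived column is longitudinal so that every method sees
#' a binary outcome at each time point.
#'
#' @param data A trial data frame with a `count` column.
#' @param threshold Required fractional reduction from baseline
#'   (strict inequality), default 0.4.
#' @param baseline_time Time point acting as the within-period baseline,
#'   default 1.
#' @return The dataset with a `binary` column (existing values replaced);
#'   `count` and `vas` are untouched and the operation is idempotent.
#' @export
#' @examples
#' d <- dichotomize(generate_trial(seed = 1))
#' table(d$binary, d$time)
dichotomize <- function(data, threshold = 0.4, baseline_time = 1) {
  data <- as_trial_data(data)
  if (nrow(data) == 0) {
    data$binary <- integer(0)
    return(as_trial_data(data))
  }
  stopifnot(threshold > 0, threshold < 1)
  # rows are in canonical (subject, period, time) order: one baseline per block
  base <- data$count[data$time == baseline_time]
  if (length(base) != nrow(data) / 4L) {
    stop("missing baseline record for a (subject, period) block",
         call. = FALSE)
  }
  base <- rep(base, each = 4L)
  data$binary <- as.integer(
    data$time != baseline_time & base > 0L &
      data$count < (1 - threshold) * base)
  data
}

#' Extract subject-period blocks in wide form
#'
#' The unit of the block-permutation machinery: one subject-period's ordered
#' four measurements of a chosen outcome.  A valid dataset partitions exactly
#' into 2 x n blocks, with equal numbers of verum and placebo blocks.
#'
#' @param data A trial data frame.
#' @param outcome One of `"count"`, `"vas"`, `"binary"`.
#' @return A tibble with one row per (subject, period) and columns
#'   `subject_id`, `sequence`, `period`, `treatment`, `t1`-`t4`.
#' @export
period_blocks <- function(data, outcome = c("count", "vas", "binary")) {
  data <- as_trial_data(data)
  outcome <- match.arg(outcome)
  if (!outcome %in% names(data)) {
    stop("outcome column '", outcome, "' not present (run dichotomize()?)",
         call. = FALSE)
  }
  data |>
    dplyr::select("subject_id", "sequence", "period", "treatment", "time",
                  value = dplyr::all_of(outcome)) |>
    tidyr::pivot_wider(names_from = "time", values_from = "value",
                       names_prefix = "t") |>
    dplyr::arrange(.data$subject_id, .data$period)
}

#' Summarise each subject-period block to a scalar
#'
#' Used by the univariate pairwise-comparison variant, which compares one
#' summary measure per subject and treatment period.
#'
#' @inheritParams period_blocks
#' @param summary `"change_from_baseline_t3"` (value at time 3 minus value at
#'   time 1, the default, reflecting the clinical focus on the post-treatment
#'   visit), `"mean_post"` (mean of times 2-4) or `"total"` (sum of all four).
#' @return The [period_blocks()] tibble with an added `value` column.
#' @export
summarize_blocks <- function(data, outcome = c("count", "vas", "binary"),
                             summary = c("change_from_baseline_t3",
                                         "mean_post", "total")) {
  summary <- match.arg(summary)
  blocks <- period_blocks(data, outcome)
  m <- as.matrix(blocks[c("t1", "t2", "t3", "t4")])
  blocks$value <- block_summary(m, summary)
  blocks
}

#' @rdname summarize_blocks
#' @param values A length-4 vector ordered by time, or an n x 4 matrix of
#'   block rows.
#' @return For `block_summary()`: a scalar (or vector, one per row).
#' @export
block_summary <- function(values, summary = c("change_from_baseline_t3",
                                              "mean_post", "total")) {
  summary <- match.arg(summary)
  if (is.null(dim(values))) {
    stopifnot(length(values) == 4)
    values <- matrix(values, nrow = 1)
  }
  stopifnot(ncol(values) == 4)
  out <- switch(summary,
    change_from_baseline_t3 = values[, 3] - values[, 1],
    mean_post = rowMeans(values[, 2:4, drop = FALSE]),
    total = rowSums(values)
  )
  unname(out)
}

#' @export
print.trial_df <- function(x, ...) {
  n <- length(unique(x$subject_id))
  cat("<trial_df> 2x2 cross-over trial data: ", n, " subjects, ",
      nrow(x), " records\n", sep = "")
  NextMethod()
}
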