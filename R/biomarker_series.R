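#' One woman's serial CA-125 profile
#'
#' Constructs a validated `biomarker_series`: a time-ordered set of CA-125
#' measurements for a single subject, the unit every risk computation and
#' screening episode operates on.
#'
#' @param subject_id Opaque subject identifier (coerced to character).
#' @param times Sample times in years since cohort entry; strictly increasing.
#' @param values CA-125 concentrations in U/mL; strictly positive.
#' @param age_at_entry Age in years at cohort entry.
#'
#' @return An object of class `biomarker_series` with fields `subject_id`,
#'   `times`, `values`, `age_at_entry`.
#' @examples
#' s <- biomarker_series("W1", times = 0:3, values = c(20, 40, 80, 160))
#' s
#' @export
biomarker_series <- function(subject_id, times, values, age_at_entry = 60) {
  stop_if_not(length(times) == length(values),
              "`times` and `values` must have equal length")
  stop_if_not(length(times) >= 1L, "a biomarker series needs at least one sample")
  stop_if_not(all(is.finite(times)), "`times` must be finite")
  stop_if_not(all(diff(times) > 0), "`times` must be strictly increasing")
  stop_if_not(all(is.finite(values)) && all(values > 0),
              "CA-125 `values` must be positive and finite")
  structure(
    list(subject_id = as.character(subject_id)[1],
         times = as.numeric(times),
         values = as.numeric(values),
         age_at_entry = as.numeric(age_at_entry)[1]),
    class = "biomarker_series"
  )
}

#' @export
print.biomarker_series <- function(x, ...) {
  cat(sprintf("<biomarker_series> subject %s, %d samples over %.2f y, CA-125 %.1f-%.1f U/mL\n",
              x$subject_id, length(x$times), diff(range(x$times)),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.biomarker_series <- function(x) length(x$times)

# append one measurement, preserving invariants
series_append <- function(series, time, value) {
  biomarker_series(series$subject_id,
                   c(series$times, time),
                   c(series$values, value),
                   series$age_at_entry)
}

#' Read / write a screening cohort as delimited text
#'
#' The on-disk schema is one row per measurement:
#' `subject_id, t_years, ca125_u_ml, age_entry` (header required), plus an
#' optional truth table `subject_id, is_case, onset_time, clinical_dx_time,
#' type_label, stage`. `read_cohort()` validates monotone times and positive
#' CA-125 and reports offending row numbers.
#'
#' @param path Path to the series CSV.
#' @param truth_path Optional path to the truth CSV (`NA` fields allowed for
#'   controls).
#'
#' @return A list of class `roca_cohort` with elements `series` (named list of
#'   [biomarker_series()]) and `truth` (data frame or `NULL`).
#' @export
read_cohort <- function(path, truth_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "t_years", "ca125_u_ml", "age_entry")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("cohort file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df)) {
    bad <- which(!is.finite(df$ca125_u_ml) | df$ca125_u_ml <= 0)
    if (length(bad)) {
      stop("non-positive CA-125 at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
           " of ", path, call. = FALSE)
    }
  }
  series <- list()
  if (nrow(df)) {
    df$.row <- seq_len(nrow(df))
    for (sp in split(df, factor(df$subject_id, levels = unique(df$subject_id)))) {
      sp <- sp[order(sp$t_years), , drop = FALSE]
      if (any(diff(sp$t_years) <= 0)) {
        stop("non-increasing sample times for subject ", sp$subject_id[1],
             " near row ", sp$.row[which(diff(sp$t_years) <= 0)[1] + 1L],
             " of ", path, call. = FALSE)
      }
      series[[sp$subject_id[1]]] <-
        biomarker_series(sp$subject_id[1], sp$t_years, sp$ca125_u_ml, sp$age_entry[1])
    }
  }
  truth <- NULL
  if (!is.null(truth_path)) {
    truth <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
    tn <- c("subject_id", "is_case", "onset_time", "clinical_dx_time",
            "type_label", "stage")
    miss <- setdiff(tn, names(truth))
    if (length(miss)) {
      stop("truth file ", truth_path, " is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    truth$subject_id <- as.character(truth$subject_id)
    truth$is_case <- as.logical(truth$is_case)
    truth$onset_time <- as.numeric(truth$onset_time)
    truth$clinical_dx_time <- as.numeric(truth$clinical_dx_time)
  }
  structure(list(series = series, truth = truth), class = "roca_cohort")
}

#' @rdname read_cohort
#' @param cohort A `roca_cohort` (or list with `series` / `truth`).
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  rows <- lapply(cohort$series, function(s) {
    data.frame(subject_id = s$subject_id, t_years = s$times,
               ca125_u_ml = s$values, age_entry = s$age_at_entry,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) {
    df <- data.frame(subject_id = character(), t_years = numeric(),
                     ca125_u_ml = numeric(), age_entry = numeric())
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path) && !is.null(cohort$truth)) {
    utils::write.csv(cohort$truth, truth_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @export
print.roca_cohort <- function(x, ...) {
  n_case <- if (!is.null(x$truth)) sum(x$truth$is_case) else NA_integer_
  cat(sprintf("<roca_cohort> %d women, %s cases\n", length(x$series),
              ifelse(is.na(n_case), "?", n_case)))
  invisible(x)
}
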