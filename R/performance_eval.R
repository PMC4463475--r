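#' Classify trial outcomes into an outcome table
#'
#' Applies the trial's outcome definitions to an episode log and a truth
#' table. A screen is positive if it culminated in surgery; a
#' screen-detected cancer is one found at screen-positive surgery (the
#' woman is a case and her onset precedes the surgery); an interval
#' (screen-negative) cancer is one diagnosed clinically within
#' `window_years` of the last test of a screen that returned the woman to
#' annual screening. Every woman is censored at 1 year after her last test:
#' clinical diagnoses beyond the censoring window count neither as detected
#' nor as missed.
#'
#' @param trial A `trial_log` from [run_trial()], or a list with `episodes`
#'   and `truth` in the same schema.
#' @param truth Optional truth table overriding `trial$truth`.
#' @param window_years Diagnosis window after the last test (default 1).
#' @return An `outcome_table`: counts (`n_episodes`, `n_surgeries`,
#'   `screen_detected`, `interval`, `fp_surgeries`, `n_incomplete`,
#'   `stage_early_detected`, `repeat_episodes`) plus `per_episode`, a data
#'   frame with one row per episode (`annual_ca125`, `annual_risk`,
#'   `annual_triage`, `cancer_linked`) for ROC construction, and `per_case`
#'   with one row per diagnosed case (`detected`, `stage_early`,
#'   `dx_time`).
#' @export
classify_outcomes <- function(trial, truth = NULL, window_years = 1) {
  episodes <- trial$episodes
  if (is.null(truth)) truth <- trial$truth
  stop_if_not(is.data.frame(episodes) && nrow(episodes) > 0,
              "empty episode log")
  orphan <- setdiff(unique(episodes$subject_id), truth$subject_id)
  if (length(orphan)) {
    stop("episode log contains subject ids absent from truth: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  tr <- truth[match(episodes$subject_id, truth$subject_id), ]

  # per-woman censoring: 1 year after the last test of her last episode
  last_test <- tapply(episodes$last_event_time, episodes$subject_id, max)
  censor <- last_test + window_years

  is_surgery <- episodes$terminal == "Surgery"
  surgery_detected <- is_surgery & !is.na(tr$is_case) & tr$is_case &
    !is.na(tr$onset_time) & tr$onset_time <= episodes$surgery_time

  # interval cancers: clinical dx within the window of the last test of a
  # woman never surgically detected
  det_ids <- unique(episodes$subject_id[surgery_detected])
  wtruth <- truth[truth$subject_id %in% unique(episodes$subject_id), ]
  w_last <- as.numeric(last_test[wtruth$subject_id])
  w_cens <- as.numeric(censor[wtruth$subject_id])
  surg_any <- wtruth$subject_id %in% unique(episodes$subject_id[is_surgery])
  clin_dx <- wtruth$clinical_dx_time
  interval_case <- wtruth$is_case & !(wtruth$subject_id %in% det_ids) &
    !surg_any & !is.na(clin_dx) & is.finite(clin_dx) & clin_dx <= w_cens
  # diagnoses beyond censoring are excluded entirely

  # per-case record (screen-detected or interval within window)
  det_rows <- episodes[surgery_detected, , drop = FALSE]
  det_dx_time <- det_rows$surgery_time[match(det_ids, det_rows$subject_id)]
  det_onset <- truth$onset_time[match(det_ids, truth$subject_id)]
  int_ids <- wtruth$subject_id[interval_case]
  int_dx_time <- clin_dx[interval_case]
  int_onset <- wtruth$onset_time[interval_case]
  per_case <- data.frame(
    subject_id = c(det_ids, int_ids),
    detected = c(rep(TRUE, length(det_ids)), rep(FALSE, length(int_ids))),
    dx_time = c(det_dx_time, int_dx_time),
    stage_early = c(det_dx_time - det_onset <= 1, int_dx_time - int_onset <= 1),
    stringsAsFactors = FALSE)

  # episode-level scores for ROC: an episode is cancer-linked if the
  # woman's diagnosis falls within the window after its annual screen
  dx_time_all <- rep(NA_real_, nrow(episodes))
  m <- match(episodes$subject_id, per_case$subject_id)
  dx_time_all[!is.na(m)] <- per_case$dx_time[m[!is.na(m)]]
  cancer_linked <- !is.na(dx_time_all) & dx_time_all > episodes$anchor_time - 1e-9 &
    dx_time_all <= episodes$anchor_time + window_years
  per_episode <- data.frame(
    subject_id = episodes$subject_id,
    anchor_time = episodes$anchor_time,
    annual_ca125 = episodes$annual_ca125,
    annual_risk = episodes$annual_risk,
    annual_triage = episodes$annual_triage,
    terminal = episodes$terminal,
    cancer_linked = cancer_linked,
    stringsAsFactors = FALSE)

  structure(list(
    n_episodes = nrow(episodes),
    n_surgeries = sum(is_surgery),
    screen_detected = c(iEOC = length(det_ids)),
    interval = c(iEOC = length(int_ids)),
    fp_surgeries = sum(is_surgery) - length(det_ids),
    n_incomplete = sum(episodes$terminal == "Incomplete"),
    repeat_episodes = sum(episodes$n_events > 1),
    stage_early_detected = sum(per_case$stage_early[per_case$detected]),
    window_years = window_years,
    per_case = per_case,
    per_episode = per_episode), class = "outcome_table")
}

#' @export
print.outcome_table <- function(x, ...) {
  cat(sprintf(paste0("<outcome_table> %d episodes, %d surgeries, ",
                     "%d screen-detected, %d interval, %d FP surgeries\n"),
              x$n_episodes, x$n_surgeries, sum(x$screen_detected),
              sum(x$interval), x$fp_surgeries))
  invisible(x)
}

#' Performance metrics of a screening strategy
#'
#' Computes sensitivity `TP / (TP + FN)`, positive predictive value
#' `TP / surgeries`, specificity `1 - FP / (episodes - cancer-window
#' episodes)`, surgeries per detected cancer, and the repeat rate, each
#' with two-sided binomial confidence intervals from [binomial_ci()].
#' Denominators of zero yield `NA` with an `undefined` flag rather than an
#' error.
#'
#' @param table An `outcome_table` from [classify_outcomes()] (or a list
#'   with fields `n_episodes`, `n_surgeries`, `screen_detected`,
#'   `interval`, `fp_surgeries`).
#' @param conf_level Confidence level for the intervals.
#' @param ci_method Passed to [binomial_ci()].
#' @return A `performance_report` with elements `sensitivity`,
#'   `specificity`, `ppv` (each: `estimate`, `lower`, `upper`, `x`, `n`),
#'   `operations_per_cancer`, `repeat_rate`, `undefined` (character vector
#'   of metrics with empty denominators).
#' @export
compute_performance <- function(table, conf_level = 0.95,
                                ci_method = c("clopper-pearson", "wilson")) {
  ci_method <- match.arg(ci_method)
  tp <- sum(table$screen_detected)
  fn <- sum(table$interval)
  fp <- table$fp_surgeries
  n_surg <- table$n_surgeries
  n_ep <- table$n_episodes
  undefined <- character()
  prop <- function(x, n) {
    ci <- binomial_ci(x, n, level = conf_level, method = ci_method)
    list(estimate = x / n, lower = ci[1], upper = ci[2], x = x, n = n)
  }
  na_prop <- list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                  x = NA_integer_, n = 0L)
  sens <- if (tp + fn > 0) prop(tp, tp + fn) else {
    undefined <- c(undefined, "sensitivity"); na_prop
  }
  ppv <- if (n_surg > 0) prop(tp, n_surg) else {
    undefined <- c(undefined, "ppv"); na_prop
  }
  n_noncancer <- n_ep - (tp + fn)
  spec <- if (n_noncancer > 0) prop(n_noncancer - fp, n_noncancer) else {
    undefined <- c(undefined, "specificity"); na_prop
  }
  opc <- if (tp > 0) n_surg / tp else {
    undefined <- c(undefined, "operations_per_cancer"); NA_real_
  }
  rep_rate <- if (!is.null(table$repeat_episodes) && n_ep > 0) {
    table$repeat_episodes / n_ep
  } else NA_real_
  structure(list(sensitivity = sens, specificity = spec, ppv = ppv,
                 operations_per_cancer = opc, repeat_rate = rep_rate,
                 undefined = undefined, conf_level = conf_level),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, digits = 1, ...) {
  pct <- function(p) {
    if (is.na(p$estimate)) return("undefined")
    sprintf("%.1f%% (%.1f%% to %.1f%%)", 100 * p$estimate,
            100 * p$lower, 100 * p$upper)
  }
  cat("<performance_report>\n")
  cat("  sensitivity:", pct(x$sensitivity), "\n")
  cat("  specificity:", pct(x$specificity), "\n")
  cat("  PPV:        ", pct(x$ppv), "\n")
  cat("  operations per cancer:",
      ifelse(is.na(x$operations_per_cancer), "undefined",
             sprintf("%.1f", x$operations_per_cancer)), "\n")
  if (!is.na(x$repeat_rate)) {
    cat(sprintf("  repeat rate: %.1f%%\n", 100 * x$repeat_rate))
  }
  invisible(x)
}

#' Binomial confidence interval
#'
#' Clopper-Pearson exact interval (default), via beta quantiles, or the
#' Wilson score interval. The exact method reproduces the trial's printed
#' intervals (e.g. 20 complications of 441 benign surgeries: 2.8% to 6.9%).
#'
#' @param successes,n Counts with `0 <= successes <= n`, `n > 0`.
#' @param level Two-sided confidence level.
#' @param method `"clopper-pearson"` or `"wilson"`.
#' @return Numeric vector `c(lower, upper)` within `[0, 1]`.
#' @examples
#' binomial_ci(20, 441)           # c(0.0279, 0.0692)
#' binomial_ci(133, 155)          # sensitivity interval
#' @export
binomial_ci <- function(successes, n, level = 0.95,
                        method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  stop_if_not(n > 0 && successes >= 0 && successes <= n &&
                successes == round(successes) && n == round(n),
              "need integer counts with 0 <= successes <= n, n > 0")
  stop_if_not(level > 0 && level < 1, "`level` must be in (0, 1)")
  a <- 1 - level
  if (method == "clopper-pearson") {
    lo <- if (successes == 0) 0 else stats::qbeta(a / 2, successes, n - successes + 1)
    hi <- if (successes == n) 1 else stats::qbeta(1 - a / 2, successes + 1, n - successes)
  } else {
    z <- stats::qnorm(1 - a / 2)
    p <- successes / n
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lo <- max(0, ctr - hw)
    hi <- min(1, ctr + hw)
  }
  c(lo, hi)
}

.check_labels <- function(scores, labels) {
  stop_if_not(length(scores) == length(labels),
              "`scores` and `labels` must have equal length")
  labels <- as.logical(labels)
  stop_if_not(!anyNA(labels) && !anyNA(scores), "missing scores or labels")
  stop_if_not(any(labels) && any(!labels),
              "both classes must be present to build a ROC curve")
  labels
}

#' Empirical ROC curve
#'
#' One operating point per distinct score threshold (ties grouped), ordered
#' from (0, 0) to (1, 1); monotone nondecreasing in both coordinates. The
#' threshold column gives the score value at and above which a screen is
#' called positive.
#'
#' @param scores Numeric scores (higher = more suspicious).
#' @param labels Binary labels (`TRUE`/1 = cancer).
#' @return A `roc_points` data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- .check_labels(scores, labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  # group tied scores: cumulative counts at the last index of each tie block
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(l)[last]
  fppos <- cumsum(!l)[last]
  out <- data.frame(threshold = c(Inf, s[last]),
                    fpr = c(0, fppos / n_neg),
                    tpr = c(0, tp / n_pos))
  class(out) <- c("roc_points", "data.frame")
  out
}

#' @export
plot.roc_points <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False-positive rate", ylab = "True-positive rate", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

# trapezoidal area under an roc_points curve
trapezoid_auc <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

#' Area under the ROC curve
#'
#' Mann-Whitney estimator with half credit for ties: the probability that a
#' randomly chosen cancer score exceeds a randomly chosen non-cancer score.
#' Identical to the trapezoidal area of [roc_curve()].
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- .check_labels(scores, labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' DeLong test for the difference between two paired AUCs
#'
#' Nonparametric comparison of two ROC areas computed from the same
#' subjects, using the structural-components (midrank placement) estimator
#' of the covariance of the paired AUCs. The per-case component of score
#' vector `a` is the placement of that case among the controls; the
#' per-control component is its placement among cases; the variance of the
#' AUC difference combines the empirical covariance matrices of the two
#' component sets. With identical scores the difference and variance are
#' zero and `p = 1` by convention.
#'
#' @param scores_a,scores_b Two score vectors on the same subjects.
#' @param labels Binary labels (`TRUE`/1 = cancer), shared by both.
#' @return A `delong_test` list: `auc_a`, `auc_b`, `auc_difference`,
#'   `variance`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stop_if_not(length(scores_a) == length(scores_b),
              "paired score vectors must have equal length")
  labels <- .check_labels(scores_a, labels)
  m <- sum(labels)   # cases
  n <- sum(!labels)  # controls
  comp <- function(s) {
    x <- s[labels]
    y <- s[!labels]
    r_all <- rank(c(x, y), ties.method = "average")
    r_x <- rank(x, ties.method = "average")
    r_y <- rank(y, ties.method = "average")
    v10 <- (r_all[seq_len(m)] - r_x) / n          # placements of cases
    v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m  # placements of controls
    list(auc = sum(v10) / m, v10 = v10, v01 = v01)
  }
  ca <- comp(scores_a)
  cb <- comp(scores_b)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  if (var_diff <= .Machine$double.eps) {
    z <- if (abs(d) < sqrt(.Machine$double.eps)) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_diff)
  }
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
  structure(list(auc_a = ca$auc, auc_b = cb$auc, auc_difference = d,
                 variance = max(var_diff, 0), z = z, p_value = p),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("<delong_test> AUC %.3f vs %.3f, diff %.4f, z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$auc_difference, x$z, x$p_value))
  invisible(x)
}

#' Performance of fixed single-threshold CA-125 rules
#'
#' For each cutoff: the sensitivity (fraction of cancer-linked annual
#' screens whose CA-125 exceeds the cutoff) and the repeat rate (fraction
#' of all annual screens exceeding it — screens that a single-threshold
#' rule would have sent for repeat testing).
#'
#' @param annual_values CA-125 at the annual (level I) screen, one value
#'   per episode.
#' @param cancer_linked Logical, one per episode: diagnosis within the
#'   analysis window of this screen.
#' @param cutoffs CA-125 cutoffs in U/mL (trial comparators: >35, >30, >22).
#' @return Data frame with columns `cutoff`, `n_flagged_cases`,
#'   `sensitivity`, `repeat_rate`.
#' @export
fixed_cutoff_performance <- function(annual_values, cancer_linked,
                                     cutoffs = c(35, 30, 22)) {
  stop_if_not(length(annual_values) > 0, "no annual values supplied")
  stop_if_not(length(annual_values) == length(cancer_linked),
              "`annual_values` and `cancer_linked` must have equal length")
  cancer_linked <- as.logical(cancer_linked)
  n_cases <- sum(cancer_linked)
  out <- lapply(cutoffs, function(ct) {
    flagged <- annual_values > ct
    data.frame(cutoff = ct,
               n_flagged_cases = sum(flagged & cancer_linked),
               sensitivity = if (n_cases > 0) {
                 sum(flagged & cancer_linked) / n_cases
               } else NA_real_,
               repeat_rate = mean(flagged))
  })
  do.call(rbind, out)
}
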