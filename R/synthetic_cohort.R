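#' Configuration of the synthetic screening cohort
#'
#' Describes the generative model the risk algorithm assumes, plus the
#' clinical machinery needed for a screening trial: annual screens over
#' `years_of_screening` rounds (default 7, the trial's median number of
#' incidence screens) after an entry measurement at time 0; stable
#' lognormal control trajectories; a latent exponential waiting time to
#' tumour onset at the configured annual incidence; post-onset exponential
#' CA-125 rise at a per-case serum doubling time drawn log-uniformly
#' (default 3-24 months: slower than the few-months tumour-volume doubling
#' reported clinically, because under annual screening the printed case
#' CA-125 distribution at the relevant screen — median about 34 U/mL with
#' 41% above 35 — and the low interval-cancer fraction are only jointly
#' reproducible when the serum marker lingers in the 20-100 U/mL range for
#' a year or more); a marker-negative case fraction whose CA-125 never
#' rises;
#' clinical (symptomatic) presentation when the noise-free marker path
#' crosses `clinical_threshold`; and an imperfect transvaginal scan.
#'
#' @param n_women Number of women.
#' @param years_of_screening Annual incidence-screening rounds per woman.
#' @param annual_incidence Probability of tumour onset per woman-year
#'   (default 1/1,915, the trial's empirical cancer rate per screen).
#' @param control_params [healthy_model_params()] generating control (and
#'   pre-onset case) log CA-125.
#' @param doubling_time_months_range Range of the log-uniform CA-125
#'   doubling-time distribution for cases, in months.
#' @param preclinical_window_years Time from onset to clinical presentation
#'   for marker-negative cases (whose CA-125 carries no signal).
#' @param marker_negative_fraction Fraction of cases whose CA-125 stays
#'   flat (anchored to interval-cancer behaviour: almost all interval
#'   cancers had normal-range annual CA-125).
#' @param clinical_threshold CA-125 level (U/mL) at which a marker-positive
#'   case presents symptomatically; `Inf` = never presents.
#' @param tvs_sensitivity_early,tvs_sensitivity_late Probability an
#'   ultrasound scan is Abnormal for a case within / beyond 1 year of onset.
#' @param tvs_specificity Probability a scan is Normal for a woman without
#'   detectable disease.
#' @param tvs_unsat_rate Probability a scan is technically Unsatisfactory
#'   (drawn first, independently of disease).
#' @param entry_age Age at entry (the trial enrolled women aged >= 50).
#' @param seed Default seed used by [simulate_cohort()].
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_women = 1000,
                          years_of_screening = 7,
                          annual_incidence = 1 / 1915,
                          control_params = healthy_model_params(),
                          doubling_time_months_range = c(3, 24),
                          preclinical_window_years = 1.5,
                          marker_negative_fraction = 0.13,
                          clinical_threshold = 250,
                          tvs_sensitivity_early = 0.6,
                          tvs_sensitivity_late = 0.9,
                          tvs_specificity = 0.985,
                          tvs_unsat_rate = 0.03,
                          entry_age = 60,
                          seed = NULL) {
  stop_if_not(n_women >= 1, "`n_women` must be positive")
  stop_if_not(years_of_screening >= 1, "`years_of_screening` must be >= 1")
  stop_if_not(annual_incidence >= 0 && annual_incidence <= 1,
              "`annual_incidence` must be a probability")
  stop_if_not(all(doubling_time_months_range > 0) &&
                length(doubling_time_months_range) == 2,
              "`doubling_time_months_range` must be two positive values")
  for (p in c(marker_negative_fraction, tvs_sensitivity_early,
              tvs_sensitivity_late, tvs_specificity, tvs_unsat_rate)) {
    stop_if_not(p >= 0 && p <= 1, "probabilities must lie in [0, 1]")
  }
  structure(list(n_women = as.integer(n_women),
                 years_of_screening = as.integer(years_of_screening),
                 annual_incidence = annual_incidence,
                 control_params = control_params,
                 doubling_time_months_range = doubling_time_months_range,
                 preclinical_window_years = preclinical_window_years,
                 marker_negative_fraction = marker_negative_fraction,
                 clinical_threshold = clinical_threshold,
                 tvs_sensitivity_early = tvs_sensitivity_early,
                 tvs_sensitivity_late = tvs_sensitivity_late,
                 tvs_specificity = tvs_specificity,
                 tvs_unsat_rate = tvs_unsat_rate,
                 entry_age = entry_age,
                 seed = seed),
            class = "cohort_config")
}

#' Simulate a screening cohort of serial CA-125 trajectories
#'
#' Controls follow `y_ij = theta_i + eps_ij` on the log scale. Cases share
#' that baseline until a latent onset drawn from an exponential waiting
#' time (hazard `annual_incidence` per year), after which log CA-125 rises
#' linearly at a per-case slope drawn from the doubling-time distribution —
#' except for the marker-negative fraction, whose trajectories stay flat.
#' Women whose onset falls within the screening horizon plus one year are
#' labelled cases in the truth table; clinical presentation times come from
#' [clinical_presentation_time()]. Reproducible under `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Seed overriding `config$seed` (scoped).
#' @return A `roca_cohort` with `series` (one [biomarker_series()] per
#'   woman: entry sample at 0, annual screens at 1..R years), `truth`
#'   (subject_id, is_case, onset_time, clinical_dx_time, type_label,
#'   stage), `latent` (theta, slope, marker_negative — consumed by
#'   [run_trial()]'s samplers), and `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  with_seed(seed, .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(config) {
  n <- config$n_women
  R <- config$years_of_screening
  hp <- config$control_params
  ids <- sprintf("W%05d", seq_len(n))
  theta <- stats::rnorm(n, hp$mu0, sqrt(hp$tau2))
  onset <- if (config$annual_incidence > 0) {
    stats::rexp(n, rate = config$annual_incidence)
  } else rep(Inf, n)
  horizon <- R + 1
  is_case <- onset <= horizon
  dt_rng <- log(config$doubling_time_months_range)
  doubling_months <- exp(stats::runif(n, dt_rng[1], dt_rng[2]))
  slope <- 12 * log(2) / doubling_months          # log-units per year
  marker_negative <- stats::runif(n) < config$marker_negative_fraction
  slope[marker_negative] <- 0
  type2 <- stats::runif(n) < 0.82                 # observed type II share

  times <- 0:R
  eps <- matrix(stats::rnorm(n * (R + 1), 0, sqrt(hp$sigma2)), nrow = n)
  shift <- outer(-onset, times, `+`)  # t - onset
  shift[shift < 0] <- 0
  shift <- shift * slope              # (t - onset)+ * slope, per-woman slope
  shift[!is_case, ] <- 0
  logy <- theta + shift + eps
  vals <- exp(logy)

  latent <- data.frame(subject_id = ids, theta = theta, slope = slope,
                       marker_negative = marker_negative,
                       stringsAsFactors = FALSE)
  clinical_dx <- rep(NA_real_, n)
  stage <- rep(NA_character_, n)
  for (i in which(is_case)) {
    clinical_dx[i] <- clinical_presentation_time(
      list(is_case = TRUE, onset_time = onset[i]),
      list(theta = theta[i], slope = slope[i],
           marker_negative = marker_negative[i]),
      config)
    stage[i] <- if (is.finite(clinical_dx[i]) &&
                    clinical_dx[i] - onset[i] <= 1) "I-II" else "III-IV"
  }
  truth <- data.frame(
    subject_id = ids,
    is_case = is_case,
    onset_time = ifelse(is_case, onset, NA_real_),
    clinical_dx_time = clinical_dx,
    type_label = ifelse(is_case, ifelse(type2, "typeII", "typeI"),
                        NA_character_),
    stage = stage,
    stringsAsFactors = FALSE)

  series <- vector("list", n)
  for (i in seq_len(n)) {
    series[[i]] <- biomarker_series(ids[i], times, vals[i, ], config$entry_age)
  }
  names(series) <- ids
  structure(list(series = series, truth = truth, latent = latent,
                 config = config),
            class = "roca_cohort")
}

#' Clinical (symptomatic) presentation time of a case
#'
#' A marker-positive case presents when her noise-free log-marker path
#' `theta + slope * (t - onset)` crosses `log(clinical_threshold)`; a
#' marker-negative case presents `preclinical_window_years` after onset
#' regardless of CA-125. Returns `Inf` when the threshold is infinite
#' (never presents).
#'
#' @param truth List or row with `is_case` and `onset_time`.
#' @param latent List or row with `theta`, `slope`, `marker_negative`.
#' @param config A [cohort_config()].
#' @return Presentation time in years since entry, or `Inf`.
#' @export
clinical_presentation_time <- function(truth, latent, config = cohort_config()) {
  stop_if_not(isTRUE(truth$is_case),
              "clinical_presentation_time() is defined for cases only")
  if (isTRUE(latent$marker_negative) || latent$slope <= 0) {
    return(truth$onset_time + config$preclinical_window_years)
  }
  if (!is.finite(config$clinical_threshold)) return(Inf)
  gap <- log(config$clinical_threshold) - latent$theta
  truth$onset_time + max(0, gap) / latent$slope
}

#' Sample a transvaginal-scan result
#'
#' Unsatisfactory with probability `tvs_unsat_rate` (technical failure,
#' independent of disease); otherwise Abnormal with probability equal to
#' the scan sensitivity for cases past onset (lower within the first year
#' of onset, when disease is small) or `1 - tvs_specificity` for everyone
#' else.
#'
#' @param truth_state List with `is_case` and `onset_time`.
#' @param time Scan time (years since entry).
#' @param config A [cohort_config()].
#' @return `"Normal"`, `"Abnormal"`, or `"Unsatisfactory"`.
#' @export
scan_sampler <- function(truth_state, time, config = cohort_config()) {
  if (stats::runif(1) < config$tvs_unsat_rate) return("Unsatisfactory")
  diseased <- isTRUE(truth_state$is_case) &&
    is.finite(truth_state$onset_time) && truth_state$onset_time <= time
  p_abn <- if (diseased) {
    if (time - truth_state$onset_time < 1) config$tvs_sensitivity_early
    else config$tvs_sensitivity_late
  } else 1 - config$tvs_specificity
  if (stats::runif(1) < p_abn) "Abnormal" else "Normal"
}
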