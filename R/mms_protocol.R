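#' Configuration of the multimodal screening protocol
#'
#' Bundles the triage thresholds, repeat-test delays, repeat limits, the
#' risk-model parameters used at every (re)triage, and the per-episode
#' abandonment rate. Defaults follow the trial protocol: repeat level I
#' CA-125 in 12 weeks after an intermediate risk, level II (CA-125 +
#' transvaginal scan) in 6 weeks after an elevated risk, a single repeat
#' level II tier, and 1,085 abandoned episodes per 296,911.
#'
#' @param thresholds A [triage_thresholds()].
#' @param case_params A [case_model_params()] for risk computation.
#' @param prior_p Prior probability of cancer per annual screen.
#' @param repeat_l1_delay_weeks Delay of a repeat level I screen (weeks).
#' @param l2_delay_weeks,repeat_l2_delay_weeks Delays of level II and repeat
#'   level II screens (weeks).
#' @param max_repeat_l1 Repeat level I screens allowed before a persistent
#'   Intermediate result is returned to annual screening.
#' @param max_repeat_l2 Repeat level II screens allowed before forced
#'   disposition (clinical evaluation).
#' @param incomplete_rate Per-episode probability the episode is abandoned.
#' @param ce_surgery_prob Probability that a clinically evaluated woman with
#'   neither detectable disease nor an abnormal scan nevertheless proceeds
#'   to surgery (default 0: she returns to annual screening).
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(thresholds = triage_thresholds(),
                            case_params = case_model_params(),
                            prior_p = 1 / 2000,
                            repeat_l1_delay_weeks = 12,
                            l2_delay_weeks = 6,
                            repeat_l2_delay_weeks = 6,
                            max_repeat_l1 = 1,
                            max_repeat_l2 = 1,
                            incomplete_rate = 1085 / 296911,
                            ce_surgery_prob = 0) {
  stop_if_not(repeat_l1_delay_weeks > 0 && l2_delay_weeks > 0 &&
                repeat_l2_delay_weeks > 0, "delays must be positive")
  stop_if_not(incomplete_rate >= 0 && incomplete_rate <= 1,
              "`incomplete_rate` must be a probability")
  stop_if_not(ce_surgery_prob >= 0 && ce_surgery_prob <= 1,
              "`ce_surgery_prob` must be a probability")
  structure(list(thresholds = thresholds, case_params = case_params,
                 prior_p = prior_p,
                 repeat_l1_delay_weeks = repeat_l1_delay_weeks,
                 l2_delay_weeks = l2_delay_weeks,
                 repeat_l2_delay_weeks = repeat_l2_delay_weeks,
                 max_repeat_l1 = max_repeat_l1,
                 max_repeat_l2 = max_repeat_l2,
                 incomplete_rate = incomplete_rate,
                 ce_surgery_prob = ce_surgery_prob),
            class = "protocol_config")
}

.triage_of <- function(x) {
  if (inherits(x, "risk_result")) as.character(x$triage) else as.character(x)
}

#' Level I (annual CA-125) triage decision
#'
#' Normal risk returns the woman to annual screening; intermediate risk
#' schedules a repeat CA-125 (repeat level I) in 12 weeks; elevated risk
#' schedules CA-125 plus transvaginal scan (level II) in 6 weeks; severe
#' risk also goes to level II but carries a surgery recommendation
#' irrespective of scan findings.
#'
#' @param risk_result A `risk_result` (or a triage label).
#' @return One of `"ReturnToAnnual"`, `"RepeatLevelI"`, `"LevelII"`; for
#'   severe risk the `"LevelII"` result carries attribute `severe = TRUE`.
#' @export
level1_decision <- function(risk_result) {
  switch(.triage_of(risk_result),
         Normal = "ReturnToAnnual",
         Intermediate = "RepeatLevelI",
         Elevated = "LevelII",
         Severe = structure("LevelII", severe = TRUE),
         stop("unknown triage class", call. = FALSE))
}

#' Level II (CA-125 + transvaginal scan) triage decision
#'
#' Contract: severe risk goes to clinical evaluation with a surgery
#' recommendation irrespective of scan findings; an abnormal scan goes to
#' clinical evaluation irrespective of risk; an unsatisfactory scan leads to
#' a repeat level II screen (or clinical evaluation if this already is the
#' repeat); with a normal scan, normal/intermediate risk returns to annual
#' screening while elevated risk leads to a repeat level II screen (or
#' clinical evaluation at the repeat).
#'
#' @param risk_result A `risk_result` (or a triage label) from the level II
#'   CA-125 sample.
#' @param scan One of `"Normal"`, `"Abnormal"`, `"Unsatisfactory"`.
#' @param is_repeat Is this the repeat level II screen?
#' @return One of `"ReturnToAnnual"`, `"RepeatLevelII"`,
#'   `"ClinicalEvaluation"`; when surgery is recommended irrespective of
#'   scan (severe risk) the result carries attribute
#'   `surgery_recommended = TRUE`.
#' @export
level2_decision <- function(risk_result, scan, is_repeat = FALSE) {
  scan <- match.arg(scan, c("Normal", "Abnormal", "Unsatisfactory"))
  tri <- .triage_of(risk_result)
  if (tri == "Severe") {
    return(structure("ClinicalEvaluation", surgery_recommended = TRUE))
  }
  if (scan == "Abnormal") return("ClinicalEvaluation")
  if (scan == "Unsatisfactory") {
    return(if (is_repeat) "ClinicalEvaluation" else "RepeatLevelII")
  }
  # normal scan
  if (tri == "Elevated") {
    return(if (is_repeat) "ClinicalEvaluation" else "RepeatLevelII")
  }
  "ReturnToAnnual"
}

#' Run one screening episode
#'
#' Executes the multimodal protocol state machine for one annual screening
#' episode: the level I risk triage, scheduled repeat level I / level II /
#' repeat level II screens with risk recomputed on the full accumulated
#' series after every new sample, and clinical evaluation. Every episode
#' terminates in `ReturnToAnnual`, `Surgery`, or `Incomplete`.
#'
#' @param series_to_date A [biomarker_series()] whose last sample is the
#'   annual (level I) CA-125 of this episode.
#' @param truth_state List with `is_case` and `onset_time` (`Inf` for
#'   controls); drives the clinical-evaluation disposition and the scan
#'   sampler.
#' @param config A [protocol_config()].
#' @param marker_sampler `function(time)` returning a CA-125 value (U/mL)
#'   for a repeat draw at `time`.
#' @param scan_sampler `function(time)` returning a scan status
#'   (`"Normal"`, `"Abnormal"`, `"Unsatisfactory"`).
#' @param force_incomplete Override the Bernoulli abandonment draw
#'   (`NA` = draw from `incomplete_rate`).
#' @return A `screen_episode`: `subject_id`, `anchor_time`, `events` (data
#'   frame: `event_time`, `event_kind`, `ca125`, `risk`, `triage`,
#'   `scan_status`), `terminal`, `completed`, `series` (the accumulated
#'   series including repeat samples).
#' @export
run_episode <- function(series_to_date, truth_state, config = protocol_config(),
                        marker_sampler = NULL, scan_sampler = NULL,
                        force_incomplete = NA) {
  stop_if_not(inherits(series_to_date, "biomarker_series"),
              "`series_to_date` must be a biomarker_series")
  anchor <- series_to_date$times[length(series_to_date$times)]
  incomplete <- if (is.na(force_incomplete)) {
    stats::runif(1) < config$incomplete_rate
  } else isTRUE(force_incomplete)

  times <- series_to_date$times
  logvals <- log(series_to_date$values)
  ev_t <- ev_kind <- ev_ca <- ev_risk <- ev_tri <- ev_scan <- list()
  push <- function(t, kind, ca, risk, tri, scan) {
    i <- length(ev_t) + 1L
    ev_t[[i]] <<- t; ev_kind[[i]] <<- kind; ev_ca[[i]] <<- ca
    ev_risk[[i]] <<- risk; ev_tri[[i]] <<- tri; ev_scan[[i]] <<- scan
  }
  eval_risk <- function() {
    ll <- .case_loglik(times, logvals, config$case_params)
    r <- .posterior_risk(ll$flat, ll$case, config$prior_p)
    list(risk = r, triage = as.character(triage_class(r, config$thresholds)))
  }
  draw_marker <- function(t) {
    if (is.null(marker_sampler)) {
      stop("episode requires a repeat sample but no `marker_sampler` was given",
           call. = FALSE)
    }
    v <- marker_sampler(t)
    times <<- c(times, t); logvals <<- c(logvals, log(v))
    v
  }

  rr <- eval_risk()
  push(anchor, "LevelI", exp(logvals[length(logvals)]), rr$risk, rr$triage, NA)
  terminal <- NULL

  if (incomplete) {
    terminal <- "Incomplete"
  } else {
    action <- level1_decision(rr$triage)
    t_now <- anchor
    n_rep_l1 <- 0L
    # repeat level I loop
    while (identical(as.character(action), "RepeatLevelI")) {
      if (n_rep_l1 >= config$max_repeat_l1) { action <- "ReturnToAnnual"; break }
      n_rep_l1 <- n_rep_l1 + 1L
      t_now <- t_now + config$repeat_l1_delay_weeks / WEEKS_PER_YEAR
      v <- draw_marker(t_now)
      rr <- eval_risk()
      push(t_now, "RepeatLevelI", v, rr$risk, rr$triage, NA)
      action <- switch(rr$triage,
                       Normal = "ReturnToAnnual",
                       Intermediate = "RepeatLevelI",
                       level1_decision(rr$triage))  # Elevated/Severe -> LevelII
    }
    # level II tier
    if (identical(as.character(action), "LevelII")) {
      n_rep_l2 <- 0L
      is_rep <- FALSE
      delay <- config$l2_delay_weeks
      repeat {
        t_now <- t_now + delay / WEEKS_PER_YEAR
        v <- draw_marker(t_now)
        rr <- eval_risk()
        if (is.null(scan_sampler)) {
          stop("level II screen requires a `scan_sampler`", call. = FALSE)
        }
        scan <- scan_sampler(t_now)
        push(t_now, if (is_rep) "RepeatLevelII" else "LevelII",
             v, rr$risk, rr$triage, scan)
        action <- level2_decision(rr$triage, scan, is_repeat = is_rep)
        if (identical(as.character(action), "RepeatLevelII")) {
          if (n_rep_l2 >= config$max_repeat_l2) {
            action <- "ClinicalEvaluation"
          } else {
            n_rep_l2 <- n_rep_l2 + 1L
            is_rep <- TRUE
            delay <- config$repeat_l2_delay_weeks
            next
          }
        }
        break
      }
      if (identical(as.character(action), "ClinicalEvaluation")) {
        t_now <- t_now + 2 / WEEKS_PER_YEAR  # nominal 2-week work-up
        push(t_now, "ClinicalEvaluation", NA, rr$risk, rr$triage, scan)
        detectable <- isTRUE(truth_state$is_case) &&
          is.finite(truth_state$onset_time) && truth_state$onset_time <= t_now
        recommended <- isTRUE(attr(action, "surgery_recommended"))
        to_surgery <- detectable || identical(scan, "Abnormal") || recommended ||
          (config$ce_surgery_prob > 0 && stats::runif(1) < config$ce_surgery_prob)
        terminal <- if (to_surgery) "Surgery" else "ReturnToAnnual"
      }
    }
    if (is.null(terminal)) terminal <- "ReturnToAnnual"
  }

  events <- data.frame(
    event_time = unlist(ev_t), event_kind = unlist(ev_kind),
    ca125 = unlist(ev_ca), risk = unlist(ev_risk),
    triage = unlist(ev_tri), scan_status = as.character(unlist(ev_scan)),
    stringsAsFactors = FALSE)
  structure(list(subject_id = series_to_date$subject_id,
                 anchor_time = anchor,
                 events = events,
                 terminal = terminal,
                 completed = !identical(terminal, "Incomplete"),
                 series = biomarker_series(series_to_date$subject_id, times,
                                           exp(logvals),
                                           series_to_date$age_at_entry)),
            class = "screen_episode")
}

#' @export
print.screen_episode <- function(x, ...) {
  cat(sprintf("<screen_episode> subject %s @ %.2f y: %s -> %s (%d events)\n",
              x$subject_id, x$anchor_time,
              paste(x$events$event_kind, collapse = " > "), x$terminal,
              nrow(x$events)))
  invisible(x)
}

#' Run the full screening trial over a cohort
#'
#' Generates one screening episode per woman per annual round until
#' diagnosis (surgical or clinical), surgery for benign disease (screening
#' discontinued), or the end of the screening period. Risk at every screen
#' and repeat is recomputed on the woman's full accumulated serial profile,
#' including her entry (prevalence-round) sample and any repeat samples from
#' earlier episodes. Deterministic given `seed`.
#'
#' @param cohort A `roca_cohort` from [simulate_cohort()] (must carry the
#'   `latent` table so repeat CA-125 draws and scans can be sampled).
#' @param config A [protocol_config()].
#' @param seed Integer seed (scoped; the caller's RNG stream is restored).
#' @return A list of class `trial_log`: `episodes` (one row per episode:
#'   `subject_id`, `episode_index`, `anchor_time`, `terminal`,
#'   `annual_ca125`, `annual_risk`, `annual_triage`, `n_events`,
#'   `last_event_time`, `surgery_time`), `events` (full per-event log),
#'   `truth` (the cohort truth table), `config`.
#' @export
run_trial <- function(cohort, config = protocol_config(), seed = NULL) {
  stop_if_not(inherits(cohort, "roca_cohort"), "`cohort` must be a roca_cohort")
  stop_if_not(!is.null(cohort$latent),
              "`cohort` lacks the latent table needed to sample repeat screens")
  with_seed(seed, .run_trial_impl(cohort, config))
}

.run_trial_impl <- function(cohort, config) {
  truth <- cohort$truth
  latent <- cohort$latent
  hp <- config$case_params$healthy_component
  sdlog <- sqrt(hp$sigma2)
  ck <- cohort$config
  # preallocated typed column accumulators, indexed in this frame so writes
  # stay in place (no copy-on-write through closures/environments)
  n_ep_max <- length(cohort$series) * ck$years_of_screening
  n_ev_max <- n_ep_max * (4L + config$max_repeat_l1 + config$max_repeat_l2)
  ep_sid <- character(n_ep_max); ep_idx <- integer(n_ep_max)
  ep_anchor <- numeric(n_ep_max); ep_term <- character(n_ep_max)
  ep_ca <- numeric(n_ep_max); ep_risk <- numeric(n_ep_max)
  ep_tri <- character(n_ep_max); ep_nev <- integer(n_ep_max)
  ep_last <- numeric(n_ep_max); ep_surg <- rep(NA_real_, n_ep_max)
  ev_sid <- character(n_ev_max); ev_idx <- integer(n_ev_max)
  ev_time <- numeric(n_ev_max); ev_kind <- character(n_ev_max)
  ev_ca <- rep(NA_real_, n_ev_max); ev_risk <- numeric(n_ev_max)
  ev_tri <- character(n_ev_max); ev_scan <- rep(NA_character_, n_ev_max)
  i_ep <- 0L
  i_ev <- 0L

  for (i in seq_along(cohort$series)) {
    s <- cohort$series[[i]]
    sid <- s$subject_id
    theta_i <- latent$theta[i]
    slope_i <- latent$slope[i]
    mneg_i <- isTRUE(latent$marker_negative[i])
    tr_state <- list(is_case = isTRUE(truth$is_case[i]),
                     onset_time = if (isTRUE(truth$is_case[i]))
                       truth$onset_time[i] else Inf,
                     marker_negative = mneg_i)
    clinical_dx <- truth$clinical_dx_time[i]
    if (is.na(clinical_dx)) clinical_dx <- Inf
    marker_sampler <- function(t) {
      shift <- if (tr_state$is_case && !mneg_i) {
        slope_i * max(0, t - tr_state$onset_time)
      } else 0
      exp(theta_i + shift + stats::rnorm(1, 0, sdlog))
    }
    scan_fn <- function(t) scan_sampler(tr_state, t, ck)

    # annual screens are the samples after the entry (t = 0) measurement
    annual_idx <- which(s$times > 0)
    hist_times <- s$times[s$times <= 0]
    hist_vals <- s$values[s$times <= 0]
    for (r in seq_along(annual_idx)) {
      j <- annual_idx[r]
      t_r <- s$times[j]
      if (clinical_dx <= t_r) break
      hist_times <- c(hist_times, t_r)
      hist_vals <- c(hist_vals, s$values[j])
      # fast path: level I triage on the accumulated series
      ll <- .case_loglik(hist_times, log(hist_vals), config$case_params)
      risk1 <- .posterior_risk(ll$flat, ll$case, config$prior_p)
      tri1 <- as.character(triage_class(risk1, config$thresholds))
      incomplete <- stats::runif(1) < config$incomplete_rate
      if (incomplete || tri1 == "Normal") {
        term <- if (incomplete) "Incomplete" else "ReturnToAnnual"
        i_ep <- i_ep + 1L
        ep_sid[i_ep] <- sid; ep_idx[i_ep] <- r; ep_anchor[i_ep] <- t_r
        ep_term[i_ep] <- term; ep_ca[i_ep] <- hist_vals[length(hist_vals)]
        ep_risk[i_ep] <- risk1; ep_tri[i_ep] <- tri1; ep_nev[i_ep] <- 1L
        ep_last[i_ep] <- t_r
        i_ev <- i_ev + 1L
        ev_sid[i_ev] <- sid; ev_idx[i_ev] <- r; ev_time[i_ev] <- t_r
        ev_kind[i_ev] <- "LevelI"; ev_ca[i_ev] <- hist_vals[length(hist_vals)]
        ev_risk[i_ev] <- risk1; ev_tri[i_ev] <- tri1
        next
      }
      std <- biomarker_series(sid, hist_times, hist_vals, s$age_at_entry)
      ep <- run_episode(std, tr_state, config, marker_sampler, scan_fn,
                        force_incomplete = FALSE)
      hist_times <- ep$series$times
      hist_vals <- ep$series$values
      nev <- nrow(ep$events)
      t_last <- ep$events$event_time[nev]
      i_ep <- i_ep + 1L
      ep_sid[i_ep] <- sid; ep_idx[i_ep] <- r; ep_anchor[i_ep] <- t_r
      ep_term[i_ep] <- ep$terminal; ep_ca[i_ep] <- ep$events$ca125[1]
      ep_risk[i_ep] <- ep$events$risk[1]; ep_tri[i_ep] <- ep$events$triage[1]
      ep_nev[i_ep] <- nev; ep_last[i_ep] <- t_last
      if (identical(ep$terminal, "Surgery")) ep_surg[i_ep] <- t_last
      idx <- i_ev + seq_len(nev)
      ev_sid[idx] <- sid; ev_idx[idx] <- r
      ev_time[idx] <- ep$events$event_time; ev_kind[idx] <- ep$events$event_kind
      ev_ca[idx] <- ep$events$ca125; ev_risk[idx] <- ep$events$risk
      ev_tri[idx] <- ep$events$triage; ev_scan[idx] <- ep$events$scan_status
      i_ev <- i_ev + nev
      if (identical(ep$terminal, "Surgery")) break
      # a clinical presentation during the episode also ends screening
      if (clinical_dx <= t_last) break
    }
  }
  keep <- seq_len(i_ep)
  episodes <- data.frame(
    subject_id = ep_sid[keep], episode_index = ep_idx[keep],
    anchor_time = ep_anchor[keep], terminal = ep_term[keep],
    annual_ca125 = ep_ca[keep], annual_risk = ep_risk[keep],
    annual_triage = ep_tri[keep], n_events = ep_nev[keep],
    last_event_time = ep_last[keep], surgery_time = ep_surg[keep],
    stringsAsFactors = FALSE)
  keep <- seq_len(i_ev)
  events <- data.frame(
    subject_id = ev_sid[keep], episode_index = ev_idx[keep],
    event_time = ev_time[keep], event_kind = ev_kind[keep],
    ca125 = ev_ca[keep], risk = ev_risk[keep],
    triage = ev_tri[keep], scan_status = ev_scan[keep],
    stringsAsFactors = FALSE)
  structure(list(episodes = episodes, events = events, truth = truth,
                 config = config),
            class = "trial_log")
}

#' @export
print.trial_log <- function(x, ...) {
  cat(sprintf("<trial_log> %d episodes, %d women, %d surgeries, %d incomplete\n",
              nrow(x$episodes), length(unique(x$episodes$subject_id)),
              sum(x$episodes$terminal == "Surgery"),
              sum(x$episodes$terminal == "Incomplete")))
  invisible(x)
}
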