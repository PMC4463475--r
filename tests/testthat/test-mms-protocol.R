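# thresholds engineered to pin the triage class of any low-risk series,
# so episode paths can be forced without rigging the risk computation
force_class <- function(class) {
  switch(class,
    Normal = triage_thresholds(intermediate_cut = 0.9, elevated_cut = 0.99,
                               severe_cut = 0.999),
    Intermediate = triage_thresholds(intermediate_cut = 1e-12,
                                     elevated_cut = 0.99, severe_cut = 0.999),
    Elevated = triage_thresholds(intermediate_cut = 1e-13,
                                 elevated_cut = 1e-12, severe_cut = 0.999),
    Severe = triage_thresholds(intermediate_cut = 1e-14,
                               elevated_cut = 1e-13, severe_cut = 1e-12))
}
flat_series <- function() make_series(c(14, 15, 13, 14))
control_state <- list(is_case = FALSE, onset_time = Inf)
case_state <- list(is_case = TRUE, onset_time = 0)

test_that("level I triage maps to the protocol's next actions", {
  expect_identical(as.character(level1_decision("Normal")), "ReturnToAnnual")
  expect_identical(as.character(level1_decision("Intermediate")), "RepeatLevelI")
  expect_identical(as.character(level1_decision("Elevated")), "LevelII")
  l2 <- level1_decision("Severe")
  expect_identical(as.character(l2), "LevelII")
  expect_true(isTRUE(attr(l2, "severe")))
  rr <- roca_risk(flat_series(), thresholds = force_class("Intermediate"))
  expect_identical(as.character(level1_decision(rr)), "RepeatLevelI")
})

test_that("level II decisions match the protocol contract exhaustively", {
  expected <- function(tri, scan, rep) {
    if (tri == "Severe") return("ClinicalEvaluation")
    if (scan == "Abnormal") return("ClinicalEvaluation")
    if (scan == "Unsatisfactory") {
      return(if (rep) "ClinicalEvaluation" else "RepeatLevelII")
    }
    if (tri == "Elevated") {
      return(if (rep) "ClinicalEvaluation" else "RepeatLevelII")
    }
    "ReturnToAnnual"
  }
  for (tri in c("Normal", "Intermediate", "Elevated", "Severe")) {
    for (scan in c("Normal", "Abnormal", "Unsatisfactory")) {
      for (rep in c(FALSE, TRUE)) {
        got <- level2_decision(tri, scan, is_repeat = rep)
        expect_identical(as.character(got), expected(tri, scan, rep),
                         info = paste(tri, scan, rep))
        if (tri == "Severe") {
          expect_true(isTRUE(attr(got, "surgery_recommended")))
        }
      }
    }
  }
})

test_that("a normal-risk episode is a single level I event returning to annual", {
  ep <- run_episode(flat_series(), control_state,
                    protocol_config(thresholds = force_class("Normal")),
                    force_incomplete = FALSE)
  expect_identical(ep$terminal, "ReturnToAnnual")
  expect_identical(ep$events$event_kind, "LevelI")
  expect_identical(ep$events$event_time[1], ep$anchor_time)
  expect_true(ep$completed)
})

test_that("an abandoned episode terminates Incomplete without surgery", {
  ep <- run_episode(flat_series(), case_state,
                    protocol_config(thresholds = force_class("Severe")),
                    const_marker_sampler(14), const_scan_sampler("Abnormal"),
                    force_incomplete = TRUE)
  expect_identical(ep$terminal, "Incomplete")
  expect_false(ep$completed)
  expect_identical(nrow(ep$events), 1L)
})

test_that("elevated risk with an abnormal scan is referred and operated", {
  ep <- run_episode(flat_series(), case_state,
                    protocol_config(thresholds = force_class("Elevated")),
                    const_marker_sampler(14), const_scan_sampler("Abnormal"),
                    force_incomplete = FALSE)
  expect_identical(ep$events$event_kind,
                   c("LevelI", "LevelII", "ClinicalEvaluation"))
  expect_identical(ep$terminal, "Surgery")
  # level II is 6 weeks after the annual screen
  expect_equal(ep$events$event_time[2] - ep$events$event_time[1], 6 / 52.18,
               tolerance = 1e-6)
})

test_that("severe risk is recommended surgery irrespective of scan findings", {
  ep <- run_episode(flat_series(), control_state,
                    protocol_config(thresholds = force_class("Severe")),
                    const_marker_sampler(14), const_scan_sampler("Normal"),
                    force_incomplete = FALSE)
  expect_identical(ep$terminal, "Surgery")
  expect_identical(ep$events$event_kind,
                   c("LevelI", "LevelII", "ClinicalEvaluation"))
})

test_that("persistently elevated risk with normal scans exhausts one repeat tier", {
  ep <- run_episode(flat_series(), control_state,
                    protocol_config(thresholds = force_class("Elevated")),
                    const_marker_sampler(14), const_scan_sampler("Normal"),
                    force_incomplete = FALSE)
  expect_identical(ep$events$event_kind,
                   c("LevelI", "LevelII", "RepeatLevelII", "ClinicalEvaluation"))
  # control with a normal scan returns to annual screening after evaluation
  expect_identical(ep$terminal, "ReturnToAnnual")
  # repeat level II comes 6 weeks after level II
  expect_equal(ep$events$event_time[3] - ep$events$event_time[2], 6 / 52.18,
               tolerance = 1e-6)
})

test_that("intermediate risk triggers a 12-week repeat level I", {
  ep <- run_episode(flat_series(), control_state,
                    protocol_config(thresholds = force_class("Intermediate")),
                    const_marker_sampler(14), const_scan_sampler("Normal"),
                    force_incomplete = FALSE)
  expect_identical(ep$events$event_kind[1:2], c("LevelI", "RepeatLevelI"))
  expect_equal(ep$events$event_time[2] - ep$events$event_time[1], 12 / 52.18,
               tolerance = 1e-6)
  # still intermediate after the allowed repeat: returned to annual screening
  expect_identical(ep$terminal, "ReturnToAnnual")
})

test_that("every episode terminates within the repeat-bounded event budget", {
  cfg <- protocol_config()
  budget <- 4 + cfg$max_repeat_l1 + cfg$max_repeat_l2
  withr::with_seed(31, {
    for (i in 1:40) {
      vals <- exp(rnorm(4, log(14) + c(0, 0, 0.5, 1.5) * runif(1, 0, 2), 0.4))
      scan <- sample(c("Normal", "Abnormal", "Unsatisfactory"), 1)
      ep <- run_episode(make_series(vals),
                        list(is_case = runif(1) < 0.5, onset_time = 1),
                        cfg, const_marker_sampler(exp(rnorm(1, log(30), 0.5))),
                        const_scan_sampler(scan), force_incomplete = FALSE)
      expect_lte(nrow(ep$events), budget)
      expect_true(ep$terminal %in% c("ReturnToAnnual", "Surgery", "Incomplete"))
      expect_true(all(diff(ep$events$event_time) > 0))
    }
  })
})

test_that("surgery is only reached through clinical evaluation", {
  co <- small_cohort(n_women = 300, years = 4, seed = 21)
  tr <- run_trial(co, seed = 22)
  surg <- tr$episodes[tr$episodes$terminal == "Surgery", ]
  for (k in seq_len(nrow(surg))) {
    ev <- tr$events[tr$events$subject_id == surg$subject_id[k] &
                      tr$events$episode_index == surg$episode_index[k], ]
    expect_identical(ev$event_kind[nrow(ev)], "ClinicalEvaluation")
    expect_identical(ev$event_kind[1], "LevelI")
  }
})

test_that("a small all-control trial yields one episode per woman-year", {
  co <- small_cohort(n_women = 3, years = 2, seed = 5, annual_incidence = 0,
                     tvs_specificity = 1, tvs_unsat_rate = 0)
  cfg <- protocol_config(incomplete_rate = 0)
  tr <- run_trial(co, cfg, seed = 6)
  expect_identical(nrow(tr$episodes), 6L)
  expect_identical(sum(tr$episodes$terminal == "Surgery"), 0L)
  expect_true(all(table(tr$episodes$subject_id) == 2))
})

test_that("screening stops after diagnosis and episodes never overlap", {
  co <- small_cohort(n_women = 400, years = 5, seed = 41,
                     annual_incidence = 1 / 40)  # enriched for cases
  tr <- run_trial(co, seed = 42)
  # no episodes anchored after the clinical diagnosis
  for (i in which(co$truth$is_case)) {
    sid <- co$truth$subject_id[i]
    dx <- co$truth$clinical_dx_time[i]
    eps <- tr$episodes[tr$episodes$subject_id == sid, ]
    if (is.finite(dx) && nrow(eps)) expect_true(all(eps$anchor_time < dx))
  }
  # episodes of one woman are disjoint in time and ordered
  for (sid in unique(tr$episodes$subject_id)) {
    eps <- tr$episodes[tr$episodes$subject_id == sid, ]
    if (nrow(eps) > 1) {
      expect_true(all(utils::head(eps$last_event_time, -1) <
                        utils::tail(eps$anchor_time, -1)))
    }
  }
  # no screening after surgery
  surg_by <- tapply(tr$episodes$surgery_time, tr$episodes$subject_id,
                    function(x) if (all(is.na(x))) Inf else min(x, na.rm = TRUE))
  for (sid in names(surg_by)) {
    eps <- tr$episodes[tr$episodes$subject_id == sid, ]
    expect_true(all(eps$anchor_time <= surg_by[[sid]]))
  }
})

test_that("trial runs are deterministic under a fixed seed", {
  co1 <- small_cohort(n_women = 150, years = 3, seed = 9)
  co2 <- small_cohort(n_women = 150, years = 3, seed = 9)
  tr1 <- run_trial(co1, seed = 10)
  tr2 <- run_trial(co2, seed = 10)
  expect_identical(tr1$episodes, tr2$episodes)
  expect_identical(tr1$events, tr2$events)
})
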