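# hand-built episode logs exercise the outcome definitions without the
# stochastic protocol machinery
toy_trial <- function(episodes, truth) list(episodes = episodes, truth = truth)

toy_episode <- function(sid, idx, anchor, terminal, last = anchor,
                        surgery = NA_real_, ca = 14, risk = 1e-5,
                        triage = "Normal", nev = 1L) {
  data.frame(subject_id = sid, episode_index = idx, anchor_time = anchor,
             terminal = terminal, annual_ca125 = ca, annual_risk = risk,
             annual_triage = triage, n_events = nev, last_event_time = last,
             surgery_time = surgery, stringsAsFactors = FALSE)
}

toy_truth <- function(sid, is_case = FALSE, onset = NA, dx = NA) {
  data.frame(subject_id = sid, is_case = is_case, onset_time = onset,
             clinical_dx_time = dx, type_label = NA_character_,
             stage = NA_character_, stringsAsFactors = FALSE)
}

test_that("outcome classification applies the screen-positive and interval rules", {
  episodes <- rbind(
    toy_episode("A", 1, 1, "Surgery", last = 1.2, surgery = 1.2, ca = 60,
                risk = 0.01, triage = "Elevated", nev = 3L),  # detected case
    toy_episode("B", 1, 1, "ReturnToAnnual"),                 # interval case
    toy_episode("C", 1, 1, "ReturnToAnnual"),                 # dx past censor
    toy_episode("D", 1, 1, "Surgery", last = 1.1, surgery = 1.1, ca = 40,
                risk = 0.002, triage = "Elevated", nev = 3L), # FP surgery
    toy_episode("E", 1, 1, "ReturnToAnnual"))                 # control
  truth <- rbind(
    toy_truth("A", TRUE, onset = 0.5, dx = 2.4),
    toy_truth("B", TRUE, onset = 0.6, dx = 1 + 11 / 12),  # 11 months later
    toy_truth("C", TRUE, onset = 0.9, dx = 1 + 13 / 12),  # 13 months later
    toy_truth("D"), toy_truth("E"))
  tab <- classify_outcomes(toy_trial(episodes, truth))
  expect_identical(unname(tab$screen_detected["iEOC"]), 1L)
  expect_identical(unname(tab$interval["iEOC"]), 1L)   # B only; C censored
  expect_identical(tab$fp_surgeries, 1L)
  expect_identical(tab$n_surgeries, 2L)
  # episode-level labels: A's and B's screens are cancer-linked
  linked <- tab$per_episode$subject_id[tab$per_episode$cancer_linked]
  expect_setequal(linked, c("A", "B"))
  # orphan subject id is an integrity error
  expect_error(
    classify_outcomes(toy_trial(toy_episode("Z", 1, 1, "ReturnToAnnual"),
                                truth)), "absent from truth")
})

test_that("performance metrics reproduce the trial arithmetic on its counts", {
  tab <- structure(list(n_episodes = 296911L, n_surgeries = 640L,
                        screen_detected = c(iEOC = 133L),
                        interval = c(iEOC = 22L), fp_surgeries = 507L,
                        repeat_episodes = 29584L), class = "outcome_table")
  perf <- compute_performance(tab)
  expect_equal(round_half_up(100 * perf$sensitivity$estimate, 1), 85.8)
  expect_equal(round_half_up(100 * perf$sensitivity$lower, 1), 79.3)
  expect_equal(round_half_up(100 * perf$sensitivity$upper, 1), 90.9)
  expect_equal(round_half_up(100 * perf$ppv$estimate, 1), 20.8)
  expect_equal(round_half_up(perf$operations_per_cancer, 1), 4.8)
  expect_equal(round_half_up(100 * perf$specificity$estimate, 1), 99.8)
  expect_equal(round_half_up(100 * perf$repeat_rate, 1), 10.0)
  expect_length(perf$undefined, 0)
})

test_that("empty denominators flag metrics as undefined instead of erroring", {
  tab <- structure(list(n_episodes = 100L, n_surgeries = 0L,
                        screen_detected = c(iEOC = 0L),
                        interval = c(iEOC = 0L), fp_surgeries = 0L,
                        repeat_episodes = 0L), class = "outcome_table")
  perf <- compute_performance(tab)
  expect_true(all(c("sensitivity", "ppv", "operations_per_cancer") %in%
                    perf$undefined))
  expect_true(is.na(perf$sensitivity$estimate))
})

test_that("exact binomial intervals match the printed trial intervals", {
  expect_identical(binomial_ci(0, 50)[1], 0)
  expect_identical(binomial_ci(50, 50)[2], 1)
  expect_equal(round_half_up(100 * binomial_ci(20, 441), 1), c(2.8, 6.9))
  # independent oracle: stats::binom.test computes the same exact interval
  for (xn in list(c(133, 155), c(20, 441), c(1, 7), c(64, 155))) {
    expect_equal(binomial_ci(xn[1], xn[2]),
                 as.numeric(stats::binom.test(xn[1], xn[2])$conf.int),
                 tolerance = 1e-6)
  }
  w <- binomial_ci(20, 441, method = "wilson")
  expect_true(w[1] > 0 && w[2] < 1 && w[1] < 20 / 441 && w[2] > 20 / 441)
  expect_error(binomial_ci(5, 0), "counts")
  expect_error(binomial_ci(8, 5), "counts")
})

test_that("ROC curves enumerate thresholds and bound the unit square", {
  # perfect separation passes through (0, 1)
  rc <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_true(any(rc$fpr == 0 & rc$tpr == 1))
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # constant scores collapse to the diagonal
  rc0 <- roc_curve(rep(2, 6), c(1, 0, 1, 0, 0, 1))
  expect_equal(rc0$fpr, c(0, 1))
  expect_equal(rc0$tpr, c(0, 1))
  expect_equal(auc(rep(2, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  # six-point toy set against exhaustive threshold enumeration
  s <- c(3, 1, 2, 2, 5, 4)
  l <- c(1, 0, 0, 1, 1, 0)
  rc6 <- roc_curve(s, l)
  for (k in seq_len(nrow(rc6))) {
    thr <- rc6$threshold[k]
    expect_equal(rc6$tpr[k], mean(s[l == 1] >= thr))
    expect_equal(rc6$fpr[k], mean(s[l == 0] >= thr))
  }
  expect_true(all(diff(rc6$fpr) >= 0) && all(diff(rc6$tpr) >= 0))
  expect_equal(unlist(rc6[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(rc6[nrow(rc6), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC equals the Mann-Whitney statistic and the trapezoid area", {
  allpairs_auc <- function(s, l) {
    x <- s[l == 1]; y <- s[l == 0]
    mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  withr::with_seed(61, {
    for (i in 1:20) {
      n <- sample(6:30, 1)
      s <- sample(1:8, n, replace = TRUE)  # heavy ties
      l <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
      expect_equal(auc(s, l), allpairs_auc(s, l))
      expect_equal(auc(s, l),
                   rocascreen:::trapezoid_auc(roc_curve(s, l)),
                   tolerance = 1e-12)
      expect_equal(auc(s, 1 - l), 1 - auc(s, l))
    }
  })
})

test_that("DeLong test is degenerate on identical scores and detects large effects", {
  withr::with_seed(71, {
    s <- rnorm(60)
    l <- rep(c(1, 0), 30)
    d0 <- delong_test(s, s, l)
    expect_identical(d0$auc_difference, 0)
    expect_identical(d0$p_value, 1)
    expect_equal(d0$auc_a, auc(s, l))
    # strongly informative vs pure-noise scores at n = 200/200
    l2 <- rep(c(1, 0), each = 200)
    good <- l2 * 2 + rnorm(400)
    noise <- rnorm(400)
    expect_lt(delong_test(good, noise, l2)$p_value, 1e-3)
  })
})

test_that("DeLong agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(73, {
    l <- rep(c(1, 0), c(40, 60))
    a <- l + rnorm(100)
    b <- 0.5 * l + rnorm(100)
    mine <- delong_test(a, b, l)
    ref <- pROC::roc.test(pROC::roc(l, a, quiet = TRUE, direction = "<"),
                          pROC::roc(l, b, quiet = TRUE, direction = "<"),
                          method = "delong", paired = TRUE)
    expect_equal(mine$auc_a, as.numeric(pROC::auc(pROC::roc(l, a, quiet = TRUE,
                                                            direction = "<"))))
    expect_equal(mine$p_value, as.numeric(ref$p.value), tolerance = 1e-10)
    expect_equal(unname(mine$z), unname(as.numeric(ref$statistic)),
                 tolerance = 1e-10)
  })
})

test_that("fixed-cutoff screening rules are enumerated correctly", {
  vals <- c(10, 12, 20, 25, 34, 36, 40, 80, 15, 22)
  linked <- c(F, F, T, F, T, F, T, T, F, F)
  fc <- fixed_cutoff_performance(vals, linked, cutoffs = c(35, 0, 60))
  expect_equal(fc$sensitivity[fc$cutoff == 0], 1)
  expect_equal(fc$repeat_rate[fc$cutoff == 0], 1)
  # cutoff between the two largest distinct values flags only the maximum
  expect_equal(fc$repeat_rate[fc$cutoff == 60], 1 / 10)
  expect_equal(fc$n_flagged_cases[fc$cutoff == 60], 1L)
  expect_equal(fc$n_flagged_cases[fc$cutoff == 35], 2L)
  expect_equal(fc$sensitivity[fc$cutoff == 35], 0.5)
  expect_error(fixed_cutoff_performance(numeric(), logical()), "no annual")
})
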