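#' Load the bundled trial outcome-count fixture
#'
#' Returns the published incidence-screening outcome counts of the
#' multimodal arm of the UK ovarian-cancer screening trial (296,911 annual
#' screening episodes in 46,237 volunteers) as a validated list. Internal
#' consistency is asserted at load time: the screen-positive
#' ovarian-or-tubal malignancies sum to 154 (133 invasive epithelial + 17
#' borderline + 4 nonepithelial), and the 1-year invasive epithelial total
#' is 155 (133 screen-detected + 22 interval).
#'
#' @return A `trial_fixture` list with elements `counts` and `printed`
#'   (the published rounded percentages, for cross-checks).
#' @examples
#' fx <- load_trial_fixture()
#' fx$counts$screen_detected$iEOC  # 133
#' @export
load_trial_fixture <- function() {
  path <- system.file("extdata", "trial_outcome_counts.json",
                      package = "rocascreen", mustWork = TRUE)
  fx <- jsonlite::read_json(path, simplifyVector = TRUE)
  ct <- fx$counts
  stop_if_not(ct$screen_detected$iEOC + ct$screen_detected$borderline +
                ct$screen_detected$nonepithelial == 154,
              "fixture inconsistent: screen-positive ovary/tube total != 154")
  stop_if_not(ct$screen_detected$iEOC + ct$interval$iEOC == 155,
              "fixture inconsistent: 1-year invasive epithelial total != 155")
  stop_if_not(ct$type1_ieoc_detected + ct$type2_ieoc_detected <=
                ct$screen_detected$iEOC,
              "fixture inconsistent: typed cancers exceed detected total")
  stop_if_not(ct$benign_or_normal_surgeries <= ct$surgeries,
              "fixture inconsistent: benign surgeries exceed surgeries")
  structure(fx, class = "trial_fixture")
}

#' Recompute the trial's worked-example performance arithmetic
#'
#' Derives every headline performance figure from the raw fixture counts —
#' sensitivities of the multimodal strategy, of the risk algorithm alone,
#' and of the fixed CA-125 cutoffs; PPV including primary peritoneal
#' cancer; surgeries per cancer; repeat rates; early-stage and type II
#' fractions; and the surgical complication rate with its exact binomial
#' interval — and compares each (after half-up rounding to one decimal,
#' the convention of the published tables) against the published value.
#'
#' @param fixture A `trial_fixture`; loaded automatically by default.
#' @return A data frame with one row per quantity: `quantity`,
#'   `numerator`, `denominator`, `value` (computed, on the printed scale),
#'   `printed`, `pass`.
#' @export
reproduce_fixture <- function(fixture = load_trial_fixture()) {
  ct <- fixture$counts
  pr <- fixture$printed
  ieoc_1yr <- ct$screen_detected$iEOC + ct$interval$iEOC  # 155
  rows <- list(
    list("mms_sensitivity_pct", ct$screen_detected$iEOC, ieoc_1yr,
         100 * ct$screen_detected$iEOC / ieoc_1yr, pr$mms_sensitivity_pct),
    list("roca_alone_sensitivity_pct", ct$roca_flagged_ieoc, ieoc_1yr,
         100 * ct$roca_flagged_ieoc / ieoc_1yr, pr$roca_alone_sensitivity_pct),
    list("cutoff35_sensitivity_pct", ct$cutoff_flagged_ieoc[["35"]], ieoc_1yr,
         100 * ct$cutoff_flagged_ieoc[["35"]] / ieoc_1yr,
         pr$cutoff35_sensitivity_pct),
    list("cutoff30_sensitivity_pct", ct$cutoff_flagged_ieoc[["30"]], ieoc_1yr,
         100 * ct$cutoff_flagged_ieoc[["30"]] / ieoc_1yr,
         pr$cutoff30_sensitivity_pct),
    list("cutoff22_sensitivity_pct", ct$cutoff_flagged_ieoc[["22"]], ieoc_1yr,
         100 * ct$cutoff_flagged_ieoc[["22"]] / ieoc_1yr,
         pr$cutoff22_sensitivity_pct),
    list("ppv_with_ppc_pct",
         ct$screen_detected$iEOC + ct$screen_detected$PPC, ct$surgeries,
         100 * (ct$screen_detected$iEOC + ct$screen_detected$PPC) / ct$surgeries,
         pr$ppv_with_ppc_pct),
    list("ppv_ieoc_pct", ct$screen_detected$iEOC, ct$surgeries,
         100 * ct$screen_detected$iEOC / ct$surgeries, pr$ppv_ieoc_pct),
    list("surgeries_per_ieoc", ct$surgeries, ct$screen_detected$iEOC,
         ct$surgeries / ct$screen_detected$iEOC, pr$surgeries_per_ieoc),
    list("roca_repeat_rate_pct", ct$repeat_recommendations$roca, ct$episodes,
         100 * ct$repeat_recommendations$roca / ct$episodes,
         pr$roca_repeat_rate_pct),
    list("cutoff35_repeat_rate_pct", ct$repeat_recommendations$cutoff35,
         ct$episodes,
         100 * ct$repeat_recommendations$cutoff35 / ct$episodes,
         pr$cutoff35_repeat_rate_pct),
    list("early_stage_fraction_pct", ct$stage_early_ieoc_detected,
         ct$screen_detected$iEOC,
         100 * ct$stage_early_ieoc_detected / ct$screen_detected$iEOC,
         pr$early_stage_fraction_pct),
    list("type2_fraction_pct", ct$type2_ieoc_detected, ct$screen_detected$iEOC,
         100 * ct$type2_ieoc_detected / ct$screen_detected$iEOC,
         pr$type2_fraction_pct),
    list("complication_rate_pct", ct$surgical_complications,
         ct$benign_or_normal_surgeries,
         100 * ct$surgical_complications / ct$benign_or_normal_surgeries,
         pr$complication_rate_pct)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(quantity = r[[1]], numerator = r[[2]], denominator = r[[3]],
               value = round_half_up(r[[4]], 1), printed = r[[5]],
               stringsAsFactors = FALSE)
  }))
  # the complication interval validates the exact CI method as a bonus row
  ci <- 100 * binomial_ci(ct$surgical_complications,
                          ct$benign_or_normal_surgeries)
  out <- rbind(out,
    data.frame(quantity = c("complication_ci_lower_pct",
                            "complication_ci_upper_pct"),
               numerator = ct$surgical_complications,
               denominator = ct$benign_or_normal_surgeries,
               value = round_half_up(ci, 1),
               printed = pr$complication_ci_pct,
               stringsAsFactors = FALSE))
  out$pass <- out$value == out$printed
  out
}
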