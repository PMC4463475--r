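#' Hyperparameters of the healthy (flat) serial CA-125 model
#'
#' Under the healthy model a woman's log CA-125 values are exchangeable
#' around a stable personal baseline:
#' \deqn{y_{ij} = \theta_i + \epsilon_{ij},\quad
#'       \theta_i \sim N(\mu_0, \tau^2),\quad
#'       \epsilon_{ij} \sim N(0, \sigma^2),}
#' where \eqn{y_{ij}} is the log marker value of woman \eqn{i} at sample
#' \eqn{j}. Between-woman spread of the personal baseline is `tau2`;
#' within-woman assay-plus-biological noise is `sigma2`.
#'
#' Defaults place the population median CA-125 at 14 U/mL
#' (`mu0 = log(14)`), matching the observed screen-negative median of
#' 13.6 U/mL, with `tau2 = 0.25` and `sigma2 = 0.09` giving a plausible
#' between/within-woman scatter on the log scale.
#'
#' @param mu0 Population mean of log CA-125.
#' @param tau2 Between-woman variance of the log baseline (>= 0).
#' @param sigma2 Within-woman variance of log values (> 0).
#' @return A `healthy_model_params` list.
#' @export
healthy_model_params <- function(mu0 = log(14), tau2 = 0.25, sigma2 = 0.09) {
  stop_if_not(is.finite(mu0), "`mu0` must be finite")
  stop_if_not(is.finite(tau2) && tau2 >= 0, "`tau2` must be >= 0")
  stop_if_not(is.finite(sigma2) && sigma2 > 0, "`sigma2` must be > 0")
  structure(list(mu0 = mu0, tau2 = tau2, sigma2 = sigma2),
            class = "healthy_model_params")
}

#' Case (change-point) model: flat baseline then exponential marker rise
#'
#' Under the case model the log marker follows the healthy baseline until a
#' latent change point \eqn{\tau} (tumour onset), after which it rises
#' linearly on the log scale (exponentially in U/mL) at slope \eqn{\gamma}:
#' \deqn{y_{ij} = \theta_i + \gamma \max(0, t_{ij} - \tau) + \epsilon_{ij}.}
#' Neither \eqn{\tau} nor \eqn{\gamma} is known, so the marginal case
#' likelihood is a weighted mixture over a grid of candidate change points
#' and slopes.
#'
#' Change-point candidates are expressed as offsets (years) relative to the
#' *last* sample of the series being scored: the default is a monthly grid
#' over the 5 years preceding the last sample, plus one "beyond window"
#' cell (`+Inf`) in which the change point falls after every sample, so that
#' cell's likelihood equals the flat model's exactly. Slopes default to a
#' log-spaced grid corresponding to CA-125 doubling times between 1.5 and 48
#' months: fast cells reflect clinically observed ovarian-tumour kinetics of
#' a few months per doubling, while the slow tail calibrates the control
#' triage fractions to the trial's stated operating point (about 15% of
#' annual screens intermediate and 2% elevated). Weights are uniform.
#'
#' @param healthy_component A [healthy_model_params()] describing pre-change
#'   baseline behaviour.
#' @param changepoint_offsets Candidate change points, in years relative to
#'   the last sample (non-positive values are inside the observation window;
#'   `Inf` marks the beyond-window cell).
#' @param slope_grid Candidate post-change slopes of log CA-125 per year
#'   (all > 0).
#' @param changepoint_weights,slope_weights Prior weights; each set must sum
#'   to 1 (tolerance 1e-9). Default uniform.
#' @return A `case_model_params` list.
#' @export
case_model_params <- function(healthy_component = healthy_model_params(),
                              changepoint_offsets = c(-(60:1) / 12, Inf),
                              slope_grid = 12 * log(2) /
                                exp(seq(log(1.5), log(48), length.out = 8)),
                              changepoint_weights = NULL,
                              slope_weights = NULL) {
  stop_if_not(inherits(healthy_component, "healthy_model_params"),
              "`healthy_component` must be a healthy_model_params object")
  stop_if_not(length(changepoint_offsets) >= 1L, "change-point grid is empty")
  stop_if_not(length(slope_grid) >= 1L, "slope grid is empty")
  stop_if_not(all(slope_grid > 0), "all slopes must be positive")
  if (is.null(changepoint_weights)) {
    changepoint_weights <- rep(1 / length(changepoint_offsets),
                               length(changepoint_offsets))
  }
  if (is.null(slope_weights)) {
    slope_weights <- rep(1 / length(slope_grid), length(slope_grid))
  }
  stop_if_not(length(changepoint_weights) == length(changepoint_offsets),
              "change-point weights/grid length mismatch")
  stop_if_not(length(slope_weights) == length(slope_grid),
              "slope weights/grid length mismatch")
  stop_if_not(all(changepoint_weights >= 0) && all(slope_weights >= 0),
              "weights must be nonnegative")
  stop_if_not(abs(sum(changepoint_weights) - 1) < 1e-9,
              "change-point weights must sum to 1")
  stop_if_not(abs(sum(slope_weights) - 1) < 1e-9,
              "slope weights must sum to 1")
  structure(list(healthy_component = healthy_component,
                 changepoint_offsets = as.numeric(changepoint_offsets),
                 slope_grid = as.numeric(slope_grid),
                 changepoint_weights = as.numeric(changepoint_weights),
                 slope_weights = as.numeric(slope_weights)),
            class = "case_model_params")
}

# ---- closed-form marginal likelihood machinery -------------------------------
#
# With theta_i integrated out, y ~ MVN(m, sigma2*I + tau2*J) whose
# compound-symmetry structure gives
#   |Sigma|      = sigma2^(n-1) * (sigma2 + n*tau2)
#   r' Sigma^-1 r = (S2 - k*S1^2)/sigma2,  k = tau2/(sigma2 + n*tau2)
# with r = y - m, S1 = sum(r), S2 = sum(r^2). Every grid cell differs from
# the flat model only through the deterministic mean shift gamma*max(0,t-tau),
# so per-cell sums reduce to scalar updates of S1, S2 — the whole grid is a
# pair of small matrix operations.

.flat_suffstats <- function(times, logvals, hp) {
  n <- length(logvals)
  c0 <- logvals - hp$mu0
  list(n = n, Sc = sum(c0), SSc = sum(c0^2), c0 = c0,
       k = hp$tau2 / (hp$sigma2 + n * hp$tau2),
       logdet = (n - 1) * log(hp$sigma2) + log(hp$sigma2 + n * hp$tau2),
       const = -0.5 * n * log(2 * pi))
}

.loglik_from_sums <- function(st, S1, S2, sigma2) {
  st$const - 0.5 * st$logdet - 0.5 * (S2 - st$k * S1^2) / sigma2
}

#' Log marginal likelihood of a serial profile under the flat (healthy) model
#'
#' Integrates the personal baseline \eqn{\theta_i} out analytically: the log
#' values are jointly multivariate normal with compound-symmetry covariance
#' \eqn{\sigma^2 I + \tau^2 J}.
#'
#' @param series A [biomarker_series()].
#' @param params A [healthy_model_params()].
#' @return The log marginal density (natural log) of the log-transformed
#'   values; a finite scalar.
#' @examples
#' s <- biomarker_series("w", 0:2, c(12, 15, 13))
#' log_marginal_flat(s, healthy_model_params())
#' @export
log_marginal_flat <- function(series, params) {
  stop_if_not(inherits(series, "biomarker_series"),
              "`series` must be a biomarker_series")
  stop_if_not(inherits(params, "healthy_model_params"),
              "`params` must be a healthy_model_params object")
  st <- .flat_suffstats(series$times, log(series$values), params)
  .loglik_from_sums(st, st$Sc, st$SSc, params$sigma2)
}

#' Log marginal likelihood under the change-point (case) model
#'
#' Weighted mixture, over the (change point, slope) grid of
#' [case_model_params()], of per-cell marginal densities with the baseline
#' integrated out analytically; accumulated by log-sum-exp. The
#' beyond-window cell (`Inf` offset) reproduces [log_marginal_flat()]
#' exactly, so the mixture always contains the healthy trajectory shape as
#' one component.
#'
#' @inheritParams log_marginal_flat
#' @param params A [case_model_params()].
#' @return Log marginal density (natural log); finite scalar.
#' @export
log_marginal_changepoint <- function(series, params) {
  stop_if_not(inherits(series, "biomarker_series"),
              "`series` must be a biomarker_series")
  stop_if_not(inherits(params, "case_model_params"),
              "`params` must be a case_model_params object")
  .case_loglik(series$times, log(series$values), params)$case
}

# core grid computation on raw vectors; returns flat and case log-likelihoods
.case_loglik <- function(times, logvals, cp) {
  hp <- cp$healthy_component
  st <- .flat_suffstats(times, logvals, hp)
  flat <- .loglik_from_sums(st, st$Sc, st$SSc, hp$sigma2)

  taus <- max(times) + cp$changepoint_offsets
  # per-tau shift profiles u_j = max(0, t_j - tau); Inf offset => u = 0
  U <- outer(-taus, times, `+`)
  U[U < 0] <- 0
  A <- rowSums(U)                 # sum(u)
  B <- as.numeric(U %*% st$c0)    # sum(u * centered y)
  C <- rowSums(U * U)             # sum(u^2)
  g <- cp$slope_grid
  S1 <- st$Sc - outer(A, g)                       # T x S
  S2 <- st$SSc - 2 * outer(B, g) + outer(C, g^2)  # T x S
  cell <- st$const - 0.5 * st$logdet - 0.5 * (S2 - st$k * S1^2) / hp$sigma2
  lw <- outer(log(cp$changepoint_weights), log(cp$slope_weights), `+`)
  keep <- is.finite(lw)  # zero-weight cells contribute nothing
  list(flat = flat, case = logsumexp(cell[keep] + lw[keep]))
}

#' Triage thresholds for the risk-of-ovarian-cancer scale
#'
#' Risk bands governing the multimodal protocol: Normal (return to annual
#' screening), Intermediate (repeat CA-125 in 12 weeks), Elevated (CA-125 +
#' transvaginal scan in 6 weeks), Severe (surgery recommended irrespective
#' of scan). Post-April-2005 cutoffs are 1/3,500 and 1/1,000; the original
#' design used 1/1,818 and 1/500. The severe cut is 1/5 in both eras. The
#' cutoffs were set (and in 2005 recalibrated) to triage roughly 15% of
#' annual screens as intermediate and 2% as elevated.
#'
#' @param era `"post2005"` (default) or `"pre2005"`.
#' @param intermediate_cut,elevated_cut,severe_cut Optional overrides.
#' @return A `triage_thresholds` list.
#' @export
triage_thresholds <- function(era = c("post2005", "pre2005"),
                              intermediate_cut = NULL, elevated_cut = NULL,
                              severe_cut = 1 / 5) {
  era <- match.arg(era)
  if (is.null(intermediate_cut)) {
    intermediate_cut <- if (era == "post2005") 1 / 3500 else 1 / 1818
  }
  if (is.null(elevated_cut)) {
    elevated_cut <- if (era == "post2005") 1 / 1000 else 1 / 500
  }
  stop_if_not(0 < intermediate_cut && intermediate_cut < elevated_cut &&
                elevated_cut < severe_cut && severe_cut < 1,
              "thresholds must satisfy 0 < intermediate < elevated < severe < 1")
  structure(list(intermediate_cut = intermediate_cut,
                 elevated_cut = elevated_cut,
                 severe_cut = severe_cut, era = era),
            class = "triage_thresholds")
}

TRIAGE_LEVELS <- c("Normal", "Intermediate", "Elevated", "Severe")

#' Map a risk value to its triage class
#'
#' Step function over `[0, 1]`: risk `< intermediate_cut` is Normal;
#' `[intermediate_cut, elevated_cut)` Intermediate;
#' `[elevated_cut, severe_cut]` Elevated; `> severe_cut` Severe.
#'
#' @param risk Posterior risk(s) in `[0, 1]` (vectorised).
#' @param thresholds A [triage_thresholds()].
#' @return Factor with levels Normal, Intermediate, Elevated, Severe.
#' @export
triage_class <- function(risk, thresholds = triage_thresholds()) {
  stop_if_not(all(risk >= 0 & risk <= 1), "`risk` must lie in [0, 1]")
  out <- ifelse(risk > thresholds$severe_cut, "Severe",
         ifelse(risk >= thresholds$elevated_cut, "Elevated",
         ifelse(risk >= thresholds$intermediate_cut, "Intermediate", "Normal")))
  factor(out, levels = TRIAGE_LEVELS)
}

#' Posterior risk of ovarian cancer from a serial CA-125 profile
#'
#' Bayes' rule over the two trajectory models:
#' \deqn{ROC = \frac{p\,L_{case}}{p\,L_{case} + (1-p)\,L_{healthy}}}
#' computed entirely in log space, where \eqn{p} is the prior probability
#' of (preclinical) ovarian cancer at an annual screen. The trial's
#' empirical rate was about 155 cancers in 296,911 woman-years, hence the
#' default prior of 1/2,000.
#'
#' @inheritParams log_marginal_flat
#' @param case_params A [case_model_params()].
#' @param prior_p Prior probability of cancer, in `[0, 1]`.
#' @param thresholds A [triage_thresholds()] used to attach the triage class.
#' @return A `risk_result` list: `risk`, `log_lik_healthy`, `log_lik_case`,
#'   `triage`.
#' @examples
#' riser <- biomarker_series("w", 0:3, c(20, 40, 80, 160))
#' roca_risk(riser, case_model_params(), prior_p = 1 / 2000)
#' @export
roca_risk <- function(series, case_params = case_model_params(),
                      prior_p = 1 / 2000,
                      thresholds = triage_thresholds()) {
  stop_if_not(inherits(series, "biomarker_series"),
              "`series` must be a biomarker_series")
  stop_if_not(is.finite(prior_p) && prior_p >= 0 && prior_p <= 1,
              "`prior_p` must lie in [0, 1]")
  ll <- .case_loglik(series$times, log(series$values), case_params)
  risk <- .posterior_risk(ll$flat, ll$case, prior_p)
  structure(list(risk = risk,
                 log_lik_healthy = ll$flat,
                 log_lik_case = ll$case,
                 triage = triage_class(risk, thresholds)),
            class = "risk_result")
}

.posterior_risk <- function(ll_flat, ll_case, prior_p) {
  if (prior_p == 0) return(0)
  if (prior_p == 1) return(1)
  # logit(risk) = logit(prior) + log Bayes factor
  stats::plogis(log(prior_p) - log1p(-prior_p) + ll_case - ll_flat)
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("<risk_result> risk %.3g (1 in %s), triage %s\n", x$risk,
              format(round(1 / max(x$risk, .Machine$double.xmin)), big.mark = ","),
              as.character(x$triage)))
  invisible(x)
}
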