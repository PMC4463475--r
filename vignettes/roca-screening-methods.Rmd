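---
title: "Serial CA-125 risk screening: models, protocol, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial CA-125 risk screening: models, protocol, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rocascreen)
```

## The problem

Ovarian cancer screening with a single CA-125 threshold (classically
35 U/mL) discards most of the information in a woman's serial profile: a
stable personal baseline of 10 U/mL that doubles to 25 U/mL is alarming,
while a stable 40 U/mL may be entirely benign. The multimodal screening
strategy evaluated in the UK ovarian-cancer screening trial instead
interprets each annual CA-125 against the woman's own history through a
risk-of-ovarian-cancer calculation, triages her into risk bands, and
escalates through repeat testing and transvaginal ultrasound to surgery.
`rocascreen` implements that pipeline end to end: the serial risk model,
the triage state machine, a synthetic screening cohort with realistic
case kinetics, and the performance arithmetic (sensitivity, specificity,
PPV, ROC/AUC, DeLong comparison) used to judge it.

## The two-trajectory risk model

Log CA-125 for woman $i$ at time $t_{ij}$ is modelled as

* **healthy (flat)**: $y_{ij} = \theta_i + \varepsilon_{ij}$, with a
  personal baseline $\theta_i \sim N(\mu_0, \tau^2)$ and noise
  $\varepsilon_{ij} \sim N(0, \sigma^2)$;
* **case (change point)**: $y_{ij} = \theta_i + \gamma \,(t_{ij}-\tau)_+
  + \varepsilon_{ij}$ — the same baseline until onset $\tau$, then a
  linear rise of slope $\gamma$ on the log scale (exponential in U/mL).

The baseline integrates out analytically: the joint density of a series
is multivariate normal with compound-symmetry covariance
$\sigma^2 I + \tau^2 J$, whose determinant and inverse have closed
forms, so each likelihood costs a handful of scalar operations. The case
likelihood is a mixture over a grid of $(\tau, \gamma)$ cells with
uniform weights, accumulated by log-sum-exp; one cell places the change
point beyond the last sample and therefore reproduces the flat
likelihood exactly, so the mixture always contains the null shape. The
posterior risk is Bayes' rule over the two marginal likelihoods with a
prior probability of preclinical cancer per annual screen.

### Defaults and why

| parameter | default | rationale |
|---|---|---|
| $\mu_0$ | $\log 14$ | reproduces the observed screen-negative median CA-125 of about 13.6 U/mL |
| $\tau^2$ | 0.25 | between-woman spread of the log baseline; gives a control scatter with a right tail reaching the 40–100 U/mL range, as seen in screened populations |
| $\sigma^2$ | 0.09 | within-woman (assay + biological) variation, about a 30% coefficient of variation |
| prior $p$ | 1/2,000 | the trial's empirical rate, about 155 cancers in 296,911 woman-years |
| $\tau$ grid | monthly over the 5 years before the last sample, plus a beyond-window cell | covers plausible preclinical lead times at the resolution of the repeat-testing schedule |
| $\gamma$ grid | 8 log-spaced slopes, CA-125 doubling times 1.5–48 months | see below |
| triage cuts | 1/3,500, 1/1,000, 1/5 | the trial's post-April-2005 cutoffs; the pre-2005 values (1/1,818, 1/500) are available via `triage_thresholds("pre2005")` |

Two grid choices deserve comment because they were genuinely open.

**Slope grid extent.** The trial states that its risk cutoffs were set —
and in 2005 recalibrated — so that roughly 15% of annual screens are
triaged intermediate and 2% elevated. Those proportions are a property of
the Bayes-factor distribution in *healthy* women, which depends on how
much of the mixture sits in "almost flat" cells. With slopes confined to
doubling times of 1.5–18 months the intermediate fraction collapses to
about 6%; extending the grid to 48-month doubling times reproduces the
intended operating point (about 12% of episodes trigger repeat testing
and 2% reach level II in our simulations) at the published cutoffs. We
therefore treat the slow-slope tail as part of the calibration, exactly
as the trial treated its cutoff revision.

**Risk-band boundaries.** Cuts are inclusive on the lower side of each
band (a risk exactly 1/3,500 is Intermediate); the severe band is open
below (risk strictly greater than 1/5). Boundaries have measure zero in
practice; the convention only matters for tests.

All likelihood work is done in natural-log space; CA-125 values from 1
to $10^5$ U/mL produce finite risks with no further guards.

## The screening protocol state machine

An annual screening episode starts with the level I CA-125 and its risk:

* **Normal** risk: return to annual screening.
* **Intermediate**: repeat CA-125 (repeat level I) in 12 weeks.
* **Elevated**: CA-125 + transvaginal scan (level II) in 6 weeks.
* **Severe** (risk > 1/5): level II, with surgery recommended
  irrespective of scan findings.

At level II, an abnormal scan sends the woman to clinical evaluation
irrespective of risk; an unsatisfactory scan leads to one repeat level II
in 6 weeks (then clinical evaluation); a normal scan returns
normal/intermediate risk to annual screening and sends elevated risk to
the repeat tier. Risk is recomputed on the full accumulated series —
entry sample, all previous annual screens, and any repeat samples — after
every new draw.

Decisions that the published algorithm leaves open, and what we chose:

* **Repeat level I bound.** The trial text does not bound consecutive
  intermediate results (one narrated case had two repeat level I screens).
  We allow `max_repeat_l1 = 1` repeat and then return a persistently
  intermediate woman to annual screening, mirroring the single repeat
  tier the algorithm diagram shows for level II. Configurable.
* **Clinical-evaluation disposition.** Clinical assessment in the trial
  was physician judgement (507 of 3,329 evaluations were desk reviews
  returning the woman to screening). In simulation, an evaluated woman
  proceeds to surgery if she has simulated detectable disease, an
  abnormal scan, or a severe-risk recommendation; otherwise she returns
  to annual screening (a `ce_surgery_prob` knob allows a stochastic
  disposition).
* **Incomplete episodes** are drawn per episode at the trial's empirical
  rate 1,085/296,911, without subdividing reasons.
* **Time bookkeeping** is in weeks converted at 52.18 weeks/year;
  episodes anchor on exact anniversaries (no jitter).

Protocol deviations the trial recorded (early referral at CA-125 ≥ 50,
patient anxiety, one severe-risk woman managed conservatively) are not
simulated; they exist only as context for the bundled outcome counts.

## The synthetic cohort

Each woman gets an entry measurement at time 0 (the prevalence round)
and annual screens at years 1..7 (the trial's median number of incidence
screens). Controls follow the flat model with the same hyperparameters
the risk model assumes, so model-vs-data mismatch is not silently doing
calibration work. Tumour onset is an exponential waiting time with
hazard 1/1,915 per year; cases rise log-linearly after onset at a
per-case slope; 13% of cases are marker-negative (flat CA-125 despite
disease), anchoring the observation that almost all interval cancers had
normal-range annual CA-125. A marker-positive case presents
symptomatically when her noise-free path crosses `clinical_threshold`
(250 U/mL); a marker-negative case presents 1.5 years after onset.

**Case kinetics.** The serum doubling time is drawn log-uniformly on
3–24 months. This is slower than the "ovarian tumours double every two
and a half months" volume-doubling remark, deliberately: under annual
screening, the printed case CA-125 distribution at the relevant screen
(median 33.6 U/mL, only 41% above 35) and the small interval-cancer
fraction (22 of 155) are jointly reproducible only if the serum marker
lingers in the 20–100 U/mL range for a year or more, so that the risk
algorithm catches the first rising screen while the single-threshold
rule still sees a normal value. Serum CA-125 lags tumour volume, so a
slower effective marker doubling is also biologically defensible. With
these defaults a 20,000-woman cohort yields a median case CA-125 at the
relevant screen of 33–42 U/mL, 13–19% interval cancers, and a
risk-vs-cutoff-35 detection ratio of 1.6–2.0 across seeds.

**Scan model.** Transvaginal ultrasound is Unsatisfactory with
probability 0.03 (independent of disease), otherwise Abnormal with
probability 0.6 within the first year of onset and 0.9 later for
diseased women (the trial reports 41% of small-volume cancers had no
abnormality on the initial level II scan), and with probability 0.015
for everyone else.

**Stage proxy.** A case diagnosed within 1 year of onset is labelled
stage I–II, later III–IV. This reproduces the qualitative
"earlier detection, earlier stage" pattern only; it is not a tumour
growth model.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: benign CA-125 elevations (endometriosis,
diverticulitis) that produce *rising* false positives; age- and
menopause-dependence of the baseline; assay drift and batch effects;
borderline/nonepithelial/peritoneal subtypes as distinct kinetic
classes; healthy-volunteer selection; and competing mortality. Interval
cancers in the simulator arise only from marker-negative disease and
fast risers, not from reading errors.

## Outcome classification and performance arithmetic

A screen is positive if the episode culminated in surgery. A
screen-detected cancer is a case whose onset precedes her screen-positive
surgery; an interval cancer is a clinical diagnosis within 12 months of
the last test of an episode that returned the woman to annual screening.
Every woman is censored 1 year after her last test; later diagnoses count
neither way. Specificity uses cancer-free episodes (woman-years) as the
denominator — with 507 non-cancer surgeries over roughly 296,756
cancer-free episodes this reproduces the trial's 99.8%, and it is the
only denominator consistent with the published woman-years row.

Confidence intervals are Clopper–Pearson exact by default (the method
that reproduces the published complication interval 2.8%–6.9% on 20 of
441) with Wilson available. ROC curves are built with one score per
woman-year episode — the annual risk for the algorithm, the annual
CA-125 for the threshold rule — with cancer episodes those linked to a
diagnosis within 1 year; AUC is the Mann–Whitney statistic with half tie
credit; the paired AUC comparison uses the DeLong
structural-components variance. Percentages are rounded half-up to one
decimal before comparison with published values, matching the tables'
convention.

## Numerical and testing notes

* The compound-symmetry closed form makes one risk evaluation about
  0.2 ms at the default 61 × 8 grid, so a full 20,000-woman, 7-round
  protocol simulation (about 140,000 episodes) runs in roughly half a
  minute; the test suite and the acceptance script use that scale for
  the end-to-end comparison and smaller cohorts (hundreds to thousands
  of women) for protocol-level properties.
* Likelihood correctness is tested against a Monte-Carlo oracle that
  integrates the baseline by simulation (10^6 draws, 3-standard-error
  tolerance), per grid cell and for the flat model; the beyond-window
  cell must equal the flat model exactly, not approximately.
* The DeLong variance is validated against a 10,000-replicate stratified
  bootstrap and an independent implementation (`pROC`); the binomial
  interval against `stats::binom.test` and direct beta quantiles.
* Degenerate inputs: a single measurement is a valid series; `tau2 = 0`
  collapses to independent lognormal noise; zero-weight grid cells and
  subject identifiers never change a risk; `prior_p` of 0 or 1 returns
  exactly 0 or 1.
* Known limitations: risks are *not* the proprietary trial algorithm's
  numerical values (its hyperparameters were never published) — only the
  model family and the triage semantics are reconstructed; the simulator
  under-produces benign surgeries (operations per detected cancer lands
  near 2.5–3 rather than the published 4.8) because false positives
  arise only through scan error, not through benign adnexal disease.
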