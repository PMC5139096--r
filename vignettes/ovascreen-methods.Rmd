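---
title: "Methods: modelling the cost-effectiveness of ovarian cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the cost-effectiveness of ovarian cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ovascreen` evaluates three strategies for postmenopausal ovarian cancer
screening — no screening, multimodal screening (MMS) and ultrasound
screening (USS) — over a lifetime, from reconstructed trial survival data
through a six-state Markov cohort model to probabilistic and
value-of-information analysis. This vignette is the package's own account
of the model, its assumptions, its defaults and its known limitations.
Everything quantitative stated here is computed by the test suite or by
`scripts/acceptance.R`; nothing is quoted from elsewhere.

## The decision problem

Screening for a rare but lethal cancer trades an immediate, certain burden
(screening costs, false positives treated surgically, earlier treatment of
women whose prognosis is unchanged) against a delayed, uncertain mortality
benefit. Within an 11-year trial window the burden dominates; over a
lifetime the benefit may dominate, but only under assumptions about how the
late screening effect continues beyond the data. The package therefore
treats *extrapolation method* as a first-class structural choice with four
regimes, and quantifies the value of resolving the residual uncertainty.

## Synthetic trial cohort

No individual-patient trial data are public, so the package ships a
simulator whose defaults encode the trial-scale study conditions:

* **Arms**: 101,359 / 50,640 / 50,639 women (none / MMS / USS); 11 years
  of follow-up; entry at an average age of 60.
* **Ovarian-cancer mortality** (no-screening arm): a piecewise-constant
  annual hazard with the shape of a discretised log-normal (`meanlog` 3.2,
  `sdlog` 0.8) — rising through the trial window and flattening near its
  end, the typical mortality pattern for an initially latent cancer — with
  a single scale factor solved so the 11-year cumulative mortality is
  exactly 0.34%. A log-normal-shaped truth also lets the family-selection
  machinery be tested against a known answer.
* **Screening effect**: annual hazard ratios of 1 for years 1–7, a linear
  transition in year 8, and 0.77 (MMS) / 0.80 (USS) from year 9 — a
  delayed effect anchored to a 23% late-trial mortality reduction.
* **Incidence**: constant latent diagnosis hazards per arm, calibrated so
  that 0.62% / 0.67% / 0.62% of women are diagnosed by year 11. A woman
  who dies of ovarian cancer is recorded as diagnosed no later than her
  death; arm-level mortality is specified directly and is *not* gated by
  the diagnosis process (the trial reports arm-level mortality, not
  post-diagnosis survival).
* **Other causes**: a constant hazard of 13,296 / 2,194,447 deaths per
  woman-year (0.61%/year, pooled across arms). Censoring is administrative
  at 11 years; loss to follow-up defaults to zero (mortality in the trial
  was ascertained through registries).
* **Stage at diagnosis**: the underlying trial did not publish per-arm
  stage distributions, so the per-arm mixes over
  {borderline, I, II, III, IV} are explicit placeholders
  (no screening 10/20/10/40/20%, MMS 15/30/12/32/11%, USS 13/27/12/35/13%),
  with an earlier-stage shift in the screened arms. They are configuration,
  not evidence.

Competing risks are resolved by sampling each cause's latent time and
taking the minimum, with exact ties (measure zero in practice) broken
toward ovarian-cancer death, then other-cause death, then censoring.
`scenario_event_fractions()` computes the analytic event fractions implied
by the mechanism (exact per-year decomposition for deaths, fine-grid
integration for the diagnosis probability), which both calibration and the
convergence tests use.

What the generator deliberately does *not* emulate: natural history of
pre-clinical disease, age- or stage-specific incidence and mortality,
screening-round attendance dynamics, or lead-time bias. A passing test
suite therefore demonstrates that the pipeline recovers the truth of *this*
mechanism at trial scale — not that the published trial's own numbers are
recoverable, which would require the digitized curves the original
analysis used.

## Reconstruction and survival fitting

`digitize_curve()` evaluates the exact Kaplan-Meier estimator on a monthly
grid, optionally adds Gaussian noise in probability units (manual
digitization error) and re-monotonises by a decreasing isotonic
projection. `reconstruct_ipd()` implements the iterative numbers-at-risk
algorithm of Guyot and colleagues: censoring counts per risk-table
interval are adjusted until the implied number at risk matches the
published count, events at each digitized step are recovered from survival
ratios, censor times are spread evenly within intervals, and subjects
remaining after the last risk time are censored at the end of the curve.
The risk-table-only variant is the default (a published figure shows no
per-interval event totals); a reported total event count can be supplied.
On exact inputs the round trip reproduces the curve to within 0.005
survival everywhere at trial scale.

Mortality is fitted with a Royston-Parmar spline: log cumulative hazard as
a restricted cubic spline in log time with, by default, 2 internal knots
at tertiles of uncensored log event times (the conventional default; the
knot count is exposed as configuration since no canonical value exists for
this problem). Arm enters the intercept, and the screening arms
additionally shift the linear log-time coefficient, giving time-varying
log hazard ratios; constraining those terms recovers proportional
hazards and can only lose likelihood (tested). Fitting is by
`flexsurv::flexsurvspline()` on weight-aggregated data — reconstructed
times are heavily tied (events on the digitization grid, censoring at
follow-up end), which turns ~200,000 rows into a few hundred and makes
the fit essentially instant without changing the likelihood.

The five standard parametric families are fitted per arm with
`flexsurv::flexsurvreg()`; BIC is computed as `k·ln(n) − 2·logLik` with
`n` the number of subjects, and `select_family()` minimises it either per
arm or summed across arms. Incidence is always extrapolated
parametrically, with the *same* family across arms (combined BIC):
per-arm selection can hand different arms structurally different
long-run incidence, which distorts incremental costs and can even leave an
arm with fewer lifetime diagnoses than deaths.

## Extrapolation

Annual hazards are cumulative-hazard increments `H(t) − H(t−1)`,
converted to probabilities as `1 − exp(−ΔH)` throughout.

* **Base case ("smoothing")**: within-trial annual hazards (no-screening
  arm) and hazard ratios (screening arms) come from the spline fit;
  beyond year 11 they are forecast by additive damped-trend exponential
  smoothing — on the log-hazard and log-hazard-ratio scales respectively —
  with weights estimated by least squares (α ∈ [0.01, 1], β ∈ [0, α],
  damping φ ∈ [0.8, 0.98]) and the standard innovations-state-space
  forecast variance. The smoothing model is written in the package because
  no installed library provides damped-trend forecasting with forecast
  variances; it is validated against a literal recursion oracle.
* **Parametric regimes**: the BIC-selected family (separately per arm, or
  shared) is evaluated across the whole horizon. The spline basis is
  linear in log time beyond the boundary knots, so spline extrapolation is
  its natural linear extension. Negative increments (improper tails, e.g.
  negative-rate Gompertz) are floored at zero and flagged.
* **Model discrepancy**: in each extrapolated year the screening *effect*
  (1 − HR; the effect-size scale is the default since the attenuation
  scale is not canonically defined — log-HR is available) is multiplied by
  an independent log-normal factor with mean 0.95 and sd 0.05, giving a
  cumulative mean attenuation of 0.95^t after t years and extra
  uncertainty. The deterministic run uses the mean multipliers.
* **Other-cause mortality**: the pooled trial rate as an annual
  probability for the first 12 cycles (entry at 60, so the trial window
  ends with women about 72), then life-table probabilities at the attained
  age, *unscaled* at the splice by default — national tables applied
  directly imply a healthy-volunteer jump, which is the conventional
  choice; continuity rescaling is available. The packaged life table is
  synthetic (Gompertz-Makeham, `μ(x) = 5e-4 + 4.5e-3·e^{0.108(x−60)}`,
  resembling contemporary UK female mortality: q₆₀ ≈ 0.5%, q₈₅ ≈ 6.5%,
  q₉₅ ≈ 18%) and is labelled as such; any `(age, qx)` CSV can be
  substituted.

The horizon is 40 annual cycles (to age 100). Extending to 45 moves
discounted QALYs by under 0.25% and incremental cost and QALYs by under
1% on the packaged fixture; absolute costs move by about 1% because the
fitted Gompertz incidence keeps rising at very old ages (see
Limitations).

## The Markov cohort model

Six states: well-screened, well-unscreened, ovarian cancer in the first
year after diagnosis, ovarian cancer in later years, dead of ovarian
cancer, dead of other causes. Annual cycles; incidence and other-cause
death compete as constant hazards within a cycle; survivors of the
first cancer year move to the later-years state; at the end of the
screening programme (7 annual rounds by default, consistent with a
per-woman screening cost of about £400) the screened population moves to
the unscreened well state.

The trial evidence is arm-level mortality, so the OC-death transition is
*calibrated*: a deterministic forward pass solves, cycle by cycle, the
conditional death probability of the diagnosed states such that
cohort-level ovarian-cancer deaths match the arm's marginal mortality
trajectory (capped when the diagnosed occupancy cannot support the target;
the cap count is reported). `run_cohort()` then re-validates every
transition matrix (row sums within 1e−12) and propagates the trace.

Payoffs: utility 0.900 while cancer-free (and again in the later cancer
years — the first-year disutility is treatment-related and lasts one
year); stage-mix-weighted first-year disutility, diagnosis and treatment
costs; £7,080 end-of-life cost at ovarian-cancer death; invitation £2.09
plus the completion-mix screen cost per screening round (completion 0.8 by
default — a placeholder in the absence of published compliance splits);
false positives arise as diagnoses-during-screening × the per-cancer ratio
(2.302 MMS, 9.963 USS), each costing one Stage-1 treatment (placeholder
for an unpublished value) and one year of Stage-1 disutility. Borderline
tumours carry the Stage-1 disutility.

Accrual: state payoffs use the half-cycle (trapezoidal) correction;
one-off costs attach to transition flows uncorrected; everything in cycle
t is discounted by (1 + 0.035)^−t. Costs are in 2013/14 pounds. These
conventions make results bit-reproducible; they are not the only
defensible choices (discounting at t − ½ would raise all absolute QALYs
slightly and cancel almost exactly in incrementals).

Sensitivity toggles mirror the univariate analyses of interest: an annual
screening disutility (0.01 or 0.005), a per-screen risk-algorithm cost for
MMS (£20 placeholder), high/low MMS screen costs (the CI bounds £83/£37),
a primary-care false-positive rate applied to the no-screening arm, and
removal of the false-positive load.

## Probabilistic analysis

Every cost, utility and false-positive parameter is drawn from a
distribution fitted to its published mean and 95% CI: the mean is matched
exactly (gamma: rate tied to shape; beta: precision free; values with
support beyond [0,1], like false positives per cancer, use a scaled beta)
and the percentiles are matched by relative least squares. The "hybrid"
rows are a gamma + scaled-beta mixture with both component means pinned
and the beta support fitted. Six rows of the published table print
intervals that are offset from their means by more than the stated family
allows once the mean is pinned (e.g. a gamma with mean £112 cannot reach
both 102 and 152 at the 2.5/97.5 percentiles); these are fitted
best-effort and flagged, and the reproduction test covers the other 17
rows. Parameters are drawn independently — only marginal distributions are
published.

Effectiveness uncertainty is propagated by multivariate-normal draws of
the spline and parametric coefficients (asymptotic covariance), a single
standard-normal deviate per forecast series that shifts the whole
extrapolated path by that many forecast standard deviations (keeping
sampled hazard paths smooth rather than independently jagged), and fresh
discrepancy multipliers per draw. Draws yielding non-finite results are
rejected, resampled and counted. 5000 draws with percentile 2.5/97.5
intervals are the base case; the packaged tests use 1000–3000 for runtime.
Draw-wise ICER intervals use the percentile method with draws showing no
QALY gain ranked as "dominated".

The efficiency frontier applies strict dominance, then removes extended
dominance by the increasing-ICER rule; it is verified against a
brute-force net-benefit oracle on 1,000 random instances. One textbook
note: the *most effective* strategy can never be extendedly dominated —
it is optimal for a high enough willingness to pay however steep its
ICER.

## Value of information

EVPI is the mean of per-draw maximum net benefit minus the maximum mean
net benefit; population scaling multiplies by 1,045,914 affected women
(7,121,000 in the eligible age range, adjusted for uptake and compliance)
over a one-year decision horizon. EVPPI uses the single-loop regression
estimator: each strategy's net benefit is regressed on the parameter
subset with a penalized smooth (`mgcv::gam`; a univariate spline for one
parameter, tensor-product smooths with dimension-guarded bases for 2–4),
and the estimator is applied to fitted values. A Monte Carlo standard
error from resampling the fitted rows accompanies every estimate so the
0 ≤ EVPPI ≤ EVPI bound is assessed statistically. The regression estimator
is validated against a closed form and a two-level nested Monte Carlo
oracle on a toy decision model, and the PSA output carries derived
long-term-effectiveness summaries (mean extrapolated hazard ratios per
arm) so decision uncertainty can be decomposed into effectiveness versus
valuation groups.

## Numerical choices

* Tied survival rows are aggregated into case weights before ML fitting;
  BIC uses subject counts.
* Time zero is floored at 1e−8 years for parametric likelihoods; hazards
  at 1e−10 before log-smoothing (with a warning); hazard ratios at 1e−6.
* The conditional OC-death hazard solves
  `(1 − e^{−(h+o)})·h/(h+o) = target` by `uniroot` to 1e−12, target capped
  at 0.98.
* Covariance factorisations add escalating jitter (from 1e−12) if a
  Cholesky fails.
* Optimisation of smoothing weights uses Nelder-Mead from
  moment-style starts; parametric fits inherit `flexsurv` defaults;
  distribution fitting uses multiple starts for the mixture.
* Problem sizes in the tests: trial-scale fixture (202,638 women) for
  round-trip and qualitative checks; 100,000-woman microsimulations for
  engine equivalence; 1000–3000 PSA draws; 100 replicates for selection
  consistency — sizes chosen so the full suite stays in the minutes range
  while keeping Monte Carlo error well inside the tested tolerances.

## Limitations

* The published headline results (ICER £8,864, EVPI ≈ £90M, and the rest)
  were produced from digitized trial curves that are not public; the
  packaged fixture reproduces the *qualitative* findings (screening
  dominated at 11 years; USS dominated by MMS over a lifetime; parametric
  extrapolation and model discrepancy raising the MMS ICER; a rising MMS
  acceptability curve) and the in-table arithmetic, not those exact
  values.
* The diagnosis-at-death convention makes the late-trial diagnosis hazard
  accelerate, so the BIC-selected (Gompertz) incidence overstates
  lifetime diagnoses in all arms symmetrically; incremental results are
  barely affected, absolute costs carry it.
* The fixture's population EVPI curve keeps rising toward high
  willingness-to-pay values rather than peaking near £9,000: with
  near-equal MMS/USS effectiveness in the synthetic truth, QALY
  uncertainty keeps growing in value as λ grows.
* Average-age (not age-structured) other-cause mortality; no
  natural-history model, so alternative screening intervals or age ranges
  cannot be evaluated — the same boundary the original evaluation faced.
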