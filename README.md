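# ovascreen

Model-based economic evaluation of population screening for ovarian cancer
among postmenopausal women.

The United Kingdom Collaborative Trial of Ovarian Cancer Screening
(UKCTOCS) randomised 202,638 women to no screening, multimodal screening
(MMS: CA-125 with a risk algorithm, ultrasound second line) or ultrasound
screening (USS), and reported a non-significant ovarian-cancer mortality
reduction with a possible *delayed* effect — little benefit in the first
seven years, a larger reduction in the last trial years. Whether screening
is worth funding therefore hinges on how that late effect is extrapolated
beyond the trial window. `ovascreen` implements the full evaluation
pipeline for this decision problem, end to end:

1. **Synthetic trial cohort** (`trial_scenario()`, `generate_ipd()`) — a
   competing-risks piecewise-exponential simulator calibrated to the
   trial-scale 11-year outcomes (0.34% / 0.29% / 0.30% cumulative
   ovarian-cancer mortality; 0.62% / 0.67% / 0.62% diagnosed; pooled
   other-cause mortality 0.61%/year; a delayed hazard-ratio profile
   reaching a 23% late reduction for MMS), so every downstream stage can be
   tested against known truth without access to trial data.
2. **Curve digitization and pseudo-IPD reconstruction**
   (`digitize_curve()`, `reconstruct_ipd()`) — Kaplan-Meier coordinates
   plus numbers-at-risk tables are turned back into per-subject
   event/censor times with the iterative algorithm of Guyot et al.
3. **Survival fitting** (`fit_spline_hr()`, `fit_parametric()`,
   `select_family()`) — Royston-Parmar spline models (log cumulative hazard
   as a restricted cubic spline in log time) with time-varying arm effects,
   plus the five standard parametric families (exponential, Weibull,
   Gompertz, log-logistic, log-normal) selected by BIC either per arm or
   jointly across arms.
4. **Lifetime extrapolation** (`forecast_smoothing()`,
   `extrapolate_parametric()`, `apply_discrepancy()`,
   `build_other_cause()`) — damped-trend exponential smoothing of annual
   log hazards and log hazard ratios (base case), parametric extension
   (structural variants), an explicit *model discrepancy* that attenuates
   the extrapolated screening effect by 5%/year (sd 0.05), and other-cause
   mortality spliced onto a life table at age 72.
5. **Six-state Markov cohort model** (`build_schedule()`, `run_cohort()`) —
   annual cycles over a lifetime horizon (to age 100), half-cycle
   correction, 3.5% discounting of costs and QALYs, screening costs and
   false-positive load (2.302 false positives per cancer for MMS, 9.963 for
   USS, each costing one Stage-1 treatment and one year of Stage-1
   disutility).
6. **Probabilistic sensitivity analysis** (`run_psa()`,
   `incremental_analysis()`, `ceac()`) — 5000-draw Monte Carlo over all
   cost/utility/false-positive distributions (fitted to published means and
   95% CIs) and over survival-model and forecast uncertainty; efficiency
   frontier with dominance and extended dominance; cost-effectiveness
   acceptability curves.
7. **Value of information** (`evpi()`, `evppi_regression()`,
   `population_scale()`) — expected value of perfect information and
   regression-based (GAM) per-parameter-group EVPPI, scaled to the affected
   population of 1,045,914 women.

The core quantities are the standard ones of cost-effectiveness analysis:
incremental cost-effectiveness ratio ICER = ΔC/ΔE (pounds per QALY
gained), net benefit NB(λ) = λ·E − C at willingness to pay λ, per-person
EVPI = E[maxₛ NBₛ] − maxₛ E[NBₛ], and EVPPI(θ) = E_θ[maxₛ E[NBₛ|θ]] −
maxₛ E[NBₛ].

## Worked example

Build the trial-scale synthetic cohort, reconstruct and fit the evidence,
and run the probabilistic base case (about two minutes):

```r
library(ovascreen)

scenario <- trial_scenario()          # UKCTOCS-like three-arm design
inputs   <- build_model_inputs(scenario)
psa      <- run_psa(inputs, n_draws = 1000, seed = 42,
                    stage_mix = scenario$stage_mix)
summary(psa)
```

```
PSA summary (smoothing regime; 0 rejected draws)
    measure strategy        mean      ci_low     ci_high
       cost     none 464.3100000 2.58552e+02 8.32949e+02
       cost      MMS 712.0670000 5.19073e+02 9.81926e+02
       cost      USS 847.4750000 6.10943e+02 1.15568e+03
       qaly     none  14.5671000 5.91470e+00 1.63012e+01
       qaly      MMS  14.6007000 5.92395e+00 1.63079e+01
       qaly      USS  14.5975000 5.91674e+00 1.63052e+01
 ...
Incremental analysis (mean costs and QALYs)
 strategy cost   qaly     label  icer
     none  464 14.567  frontier     -
      MMS  712 14.601  frontier £7371
      USS  847 14.598 dominated     -
```

Reading the output: screening with MMS costs £248 more than no screening
per woman over a lifetime and gains 0.034 QALYs, an ICER of roughly £7,400
per QALY — below the conventional £20,000 willingness-to-pay threshold —
while USS is *dominated* by MMS (more expensive and less effective). At
the 11-year trial horizon the ordering reverses: run
`run_psa(..., settings = econ_settings(horizon = 11))` and both screening
strategies produce fewer QALYs at greater cost, because the false-positive
burden arrives immediately while the mortality benefit is delayed.

The acceptability curve and value of information follow directly:

```r
ceac(psa, c(10000, 20000, 30000))
#     wtp  none   MMS   USS
#   10000 0.545 0.317 0.138
#   20000 0.365 0.438 0.197
#   30000 0.263 0.515 0.222
evpi_curve(psa, seq(0, 40000, 500), pop = population_settings())
```

Whole experiments (regime, horizon, sensitivity toggles, CSV reports) are
driven by `run_experiment(run_config(...))`; see the methods vignette
(`vignettes/ovascreen-methods.Rmd`) for the model, its assumptions and
every numerical choice.

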