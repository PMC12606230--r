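---
title: "Models and methods behind memmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind memmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(memmeta)
```

memmeta implements, end to end, a pre-registered analysis pipeline for a
partial-report experiment that compares metacognitive sensitivity between
iconic memory (IM; probe 250 ms after stimulus offset) and working memory
(WM; probe after 8 s), together with a generative simulator rich enough to
exercise every stage. This vignette documents the models, the tunable
parameters, the numerical choices, and what the simulator does and does not
emulate.

## The experimental design being modelled

Each subject completes two sessions of 270 trials: 10 practice trials
followed by 130 experimental trials per memory condition, interleaved in a
random order. A circular array of colored letters (radius 8.81 degrees of
visual angle; equidistant CIELAB colors 149.2975 units apart, four colors
in general and five whenever a four-color cyclic assignment would make the
first and last letters clash, i.e. at 5, 9 and 13 items) is shown for
250 ms; after the retention interval the subject clicks the position of a
probed letter (4 s deadline) and rates confidence on a 4-point scale (3 s
deadline). One 1-up/1-down staircase per condition adjusts the set size —
plus one item after a correct response, minus one after an error, frozen on
a missed decision — between 1 and 16 items, clamping accuracy near 50%.

The registered exclusion rules drop practice trials, the first 30
experimental trials of each condition in each session (staircase
stabilization; the session arithmetic 270 − 10 − 60 = 200 valid trials
fixes this per-session reading), trials with any response faster than
150 ms, trials with a missed decision or confidence deadline, and trials
with fewer than 4 items. A subject is discarded when either condition
retains fewer than 180 of its 200 possible trials. On clean data this
leaves exactly 400 analysis trials per subject.

## The generative observer

The simulator (`observer_params()`, `simulate_experiment()`) makes three
structural choices, each the simplest mechanism with the required
signature:

**Accuracy: a slot model.** On a trial with $N$ items,
$\min(K, N)$ items are stored. If the probed item is stored the response is
correct up to a lapse rate $\varepsilon$; otherwise the position is guessed
uniformly:
$$p(N) = \frac{\min(K,N)}{N}(1-\varepsilon) + \Big(1-\frac{\min(K,N)}{N}\Big)\frac{1}{N}.$$
$p(N)$ is non-increasing in $N$, so the staircase has a unique 50% fixed
point that increases with capacity $K$ — the mechanism that turns a
capacity difference into a measurable set-size difference. The defaults
$K_{IM} = 6$, $K_{WM} = 3$ put the two fixed points near 13 and 7 items,
inside the staircase range. Note the converse limitation: an observer whose
50% point exceeds the 16-item ceiling (roughly $K \gtrsim 6.5$ at
$\varepsilon = 0.02$) saturates the staircase and stabilizes above 50%.

**Confidence: a cumulative-probit process.** A latent variable
$$\eta = \beta_{IM}\,[IM] + \beta_{n}\,N + \beta_{acc}\,[correct] + u_s + \epsilon$$
is cut at thresholds $\tau_1 < \tau_2 < \tau_3$ into the four rating
levels, with one random intercept $u_s \sim N(0, \sigma_u^2)$ per subject
shared across sessions. Defaults use the fitted coefficients of the
registered model ($\beta_{IM} = -0.08$, $\beta_{n} = -0.12$,
$\beta_{acc} = 1.28$), $\sigma_u = 0.5$, and thresholds
$(-2.3, -1.1, 0.2)$, chosen once so that all four confidence levels are
populated at the typical linear predictor ($\eta \approx -1.4$ at $N = 8$).

**Metacognition: condition-specific latent noise.** The noise SD is
$1 + m_c$ with $m_{WM} = 0$ (reference) and $m_{IM} = 0.3$. Inflating the
latent noise in one condition degrades the coupling between confidence and
correctness there — lowering AUROC-2 — without touching accuracy, which
the staircase controls independently. This was chosen over a
condition-specific $\beta_{acc}$ because it corresponds to the "noisier
percepts" mechanism discussed for pre-attentive vision; either
parameterization produces the same qualitative contrast. A consequence
worth knowing: data generated with unequal meta-noise are heteroskedastic
on the latent scale, so the homoskedastic fitted model recovers an
attenuated/shifted $\beta_{IM}$; exact parameter recovery is therefore
always tested with equal meta-noise.

**Response times** are lognormal (decision: meanlog $\log 1.1$, sdlog
0.45; confidence: $\log 0.7$, 0.40), contaminated with fast guesses
(< 150 ms, probability 0.03, answered at chance) and deadline timeouts
(probability 0.005 each; a decision draw past 4 s also times out). The
defaults produce roughly 2–5% fast-guess trials so the exclusion rules do
real work without discarding subjects en masse. RTs carry no information
beyond exercising the exclusions — no speed–accuracy coupling is modelled.

Unstated design details were fixed once: staircases start at 8 items
(mid-range) and reset at each session; practice trials run the staircase
too but are flagged and dropped; the staircase floor is 1 item, because the
design *excludes* sub-4-item trials rather than preventing them; condition
order is uniformly random subject to the exact per-session counts; the
color wheel's angular phase relative to the letters is a free parameter
(`phase`), with phase 0 reproducing the published coordinate tables.

On serialization precision: wheel coordinates are kept in full floating
precision. The published four-color table corresponds to *truncation* at
four decimals (105.5692 from 105.56930), while the five-color values match
ordinary rounding — the two conventions differ by one unit in the fourth
decimal. `format_lab()` implements the truncating convention used by the
four-color table.

## The analysis pipeline

`run_study()` chains the registered stages: exclusions
(`preprocess_trials()`), per subject-and-condition summaries
(`subject_summaries()`), the four confirmatory analyses, optionally the
exploratory suite, then a token-based interpretation.

**AUROC-2** (`type2_roc()`, `auroc2()`). All three splits of the 4-point
scale into high/low confidence give a type-2 hit and false-alarm rate;
the trapezoidal area under the piecewise-linear curve through these points
plus the (0,0) and (1,1) endpoints is used raw (no bias correction,
matching the registered analysis). The trapezoid is *identically* the
tie-corrected pairwise probability $P(c^+ > c^-) + \tfrac12 P(c^+ = c^-)$,
which the tests verify by exhaustive enumeration; it is therefore invariant
under strictly increasing relabelings of the scale. A subject whose
condition has no errors (or no correct trials) has an undefined curve: the
value is flagged missing with a warning and the subject drops out of the
affected comparison — no imputation. The staircase keeps this rare by
construction.

**Paired t and TOST** (`paired_t()`, `tost_paired()`). Effect sizes use
the within-subject convention $d = |t|/\sqrt{n}$. The TOST runs two
one-sided paired t-tests against the bounds; standardized bounds are
interpreted on the paired-differences SD scale (the same $d_z$ scale as the
effect-size convention) and converted via the sample SD; the reported
p-value is the larger one-sided p and the reported statistic the one
attaining it. RQ1's two tests both run at $\alpha = 0.025$ (two tests on
the same data); the capacity test and the performance control run at
$\alpha = 0.05$, the control with raw bounds $\pm 0.05$ on the accuracy
difference.

**Cumulative-probit mixed models** (`fit_cumulative_probit()`). Three
specifications: the registered random-intercept model (`model1`), the
interaction model `IM*accuracy + nItems + (1|subject)` (`model2`), and the
full-random-effects model (`model3`), read as the model-2 fixed effects
plus a correlated 5-dimensional random effect (intercept and all slopes) —
the literal printed formula has no fixed-effect terms, which would force
the population-mean slopes to zero; the conventional reading was
implemented. Identification is the standard cumulative-link one: no global
intercept, three free thresholds; `nItems` enters raw (the registered model
gives no transformation; `center_items` toggles centring). Estimation
maximizes the approximate marginal likelihood in C++:

* models 1–2: adaptive Gauss–Hermite quadrature. The per-subject integrand
  is re-centred at the conditional mode with curvature-matched scaling;
  within a round the nodes are held fixed so the analytic gradient is exact,
  and rounds of re-adaptation repeat until the estimate moves less than
  1e-4 on the parameter scale (standard errors are two orders of magnitude
  larger). The default 15 nodes are conservative: with hundreds of trials
  per subject the integrand is nearly Gaussian and the log-likelihood
  changes by < 1e-4 per observation between 20 and 50 nodes (a tested
  diagnostic, `cumprobit_loglik()`); the simulation studies use 5–7 nodes.
* model 3: a Laplace approximation with per-subject Newton mode finding;
  the covariance is optimized on the log-Cholesky scale.

Standard errors come from the inverse observed information of the marginal
likelihood (central differences of the analytic gradient for models 1–2, a
full numerical Hessian for model 3); p-values are Wald, matching the
coefficient/SE/p reporting style of the analysis. A variance estimate at
its lower boundary ($\sigma_u \le 1.5\times10^{-3}$) is flagged, not an
error; `sigma_fixed` can pin the variance, in which limit the fit
coincides with the pooled maximum-likelihood ordered probit (tested against
an independent pooled fit). AIC is $2k - 2\ell$ with $k$ counting
thresholds, fixed effects and variance components, and `compare_aic()`
refuses fits on different observation sets. Fits tolerate strong
IM-by-set-size correlation (tested up to 0.77) because both predictors
enter the same linear predictor.

**Per-subject coefficients** (`subject_coefficient_test()`). The analysis
of "the distribution of beta values" under model 3 is ambiguous between
empirical-Bayes conditional modes and per-subject separate fits; the
implementation uses fixed effect + conditional mode (the shrinkage
estimator), one-sample t against zero with $df = n-1$. The alternative was
not implemented as it requires per-subject identifiability of all
thresholds; neither is asserted to be the original authors' procedure.

**Exploratory set-size controls** (`setsize_variability_analysis()`).
(a) paired t on the per-subject SD of set size; (b) OLS — deliberately not
mixed, two rows per subject, as a plain linear regression — of AUROC-2 on
the z-scored set-size SD, a WM indicator, and their interaction, the
z-scoring making the WM coefficient the metacognition gap at the average
variability; (c) AUROC-2 recomputed on each cell's modal set size only
(ties resolved to the smaller set size, logged), compared by paired t and
TOST at $\alpha = 0.025$.

**Interpretation** (`interpret_results()`). The registered decision table
is encoded as a pure function over the test outcomes, so every branch is
unit-testable: RQ1 yields `higher_WM_meta_nonequivalent`, `equivalent`,
`higher_IM_meta` or `inconclusive`; a significantly *positive* IM
confidence coefficient reads as `inflation` only when RQ1 did not find
equal-or-higher IM metacognition; and rich-view-supporting RQ1 outcomes are
conditioned on RQ3 preserving the higher IM capacity
(`conditional_not_met` otherwise). Ambiguous combinations map to
`inconclusive`.

## Power analytics

`power_paired_t()`, `required_n_paired_t()` and `sensitivity_d_paired_t()`
use the exact noncentral-t distribution ($df = n-1$, $ncp = d\sqrt n$),
with $\alpha$ read as the *total* two-sided error — the reading that
reproduces the design's printed 93-subject requirement and 83.7% achieved
power at $n = 101$ exactly, and the 0.325 sensitivity d to within rounding.
`power_tost_paired()` computes the exact probability that both one-sided
tests reject by integrating the joint rejection region over the sampling
distribution of the paired-differences SD (the Owen's-Q formulation). A
deliberate consequence: the exact required n for the standardized
$\pm 0.325$ TOST at $\alpha = 0.025$ and 80% power is **102**
(power at 101 is 0.7976, confirmed by $2\times10^5$ Monte-Carlo
replicates), one subject above the published 101, which follows from a
large-sample approximation. The package reports the exact value.

`simulate_ordinal_power()` reproduces the simulation-based power procedure
for the IM coefficient: generate confidence datasets from the ordered
probit process on a grid of $\beta_{IM}$ (all other coefficients fixed),
fit the registered model, and count Wald rejections; each replicate's
statistic is also converted to $d = |t|/\sqrt n$. Predictor streams are
generated directly (balanced conditions; set sizes from a rounded clamped
normal, with an optional mean split inducing a target IM-by-set-size
correlation) rather than re-running the staircase per replicate, which is
what "simulating confidence responses" requires and keeps a 100-replicate
grid tractable. The pilot-derived coefficients behind the published
detectable-coefficient value live in an electronic supplement and are not
asserted; the procedure and its monotonicity are.

## What the simulator does not emulate

Letter identities and positions, gaze, ISI timing beyond the condition
label, practice-trial feedback, learning or fatigue across sessions,
speed–accuracy coupling, and any departure of real confidence from the
probit form (e.g. response styles beyond an intercept shift). Passing tests
therefore demonstrate that the *pipeline* is correct and well-calibrated
under its assumed data-generating process — not that the scientific
conclusions hold for real observers.

## Problem sizes used by the test suite

Simulation-based checks were sized to be informative while keeping the
suite reproducible on a single CPU: parameter recovery at the study scale
(100 subjects × 400 trials, 100 replicates, 7 quadrature nodes, half the
replicates at IM-by-set-size correlation 0.77); calibration checks (Wald
size, TOST boundary size) at 100–10,000 replicates of reduced designs;
model-recovery and subject-coefficient checks on 20–30-subject cohorts;
and end-to-end pipeline runs at the full 101-subject design.
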