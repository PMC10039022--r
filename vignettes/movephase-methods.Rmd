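---
title: "Methods: space-use phases and step selection after translocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: space-use phases and step selection after translocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`movephase` analyses how animals translocated into a novel landscape shift
from *exploration* (wide-ranging information gathering) to *exploitation*
(settled use of known resources), and how their habitat selection changes
across that switch. The pipeline has four stages: trajectory
preprocessing, moving-window space-use metrics built on a dynamic Brownian
bridge movement model (dBBMM), a group-level phase-switch criterion, and
phase-stratified step-selection functions (SSFs). A seeded agent-based
simulator provides generative ground truth, so every stage is validated by
recovery experiments rather than against any particular field data set.

## Trajectory preprocessing

GPS tables are split per animal, time-sorted, and cleaned by three rules:

* **Quality filter.** Fixes with PDOP strictly greater than 9 are removed.
  Missing PDOP is retained: absence of the diagnostic is not evidence of a
  bad fix.
* **Interval subsampling.** Mixed collar schedules (15-min, 1-h, 2-h) are
  thinned to a common 2-h cadence by greedy forward selection: keep the
  first fix, then repeatedly the fix nearest to (last kept + 2 h) within a
  ±15-min tolerance. The tolerance is chosen so that 15-min and 1-h
  schedules thin cleanly onto the 2-h grid. Nothing is ever interpolated;
  gaps are preserved and the clock restarts after them.
* **Homing and censoring.** A translocated animal that re-enters 1.6 km of
  its capture site (the radius of a circle with the 8.3 km² mean resident
  home-range area) within 10 days of release is reclassified as a resident
  of its original range, with the pre-return fixes censored.
  Analyst-supplied censor windows are honoured, and every series is
  truncated at 90 days from its (possibly re-based) start.

Day boundaries are local midnights in a configurable time zone; at a 2-h
cadence each full day holds 12 fixes.

## Dynamic Brownian bridge movement model

Between consecutive fixes $a$ and $b$ separated by $T$ seconds, the
position at fraction $\alpha$ is bivariate normal with mean
$a + \alpha(b - a)$ and per-coordinate variance

$$T\,\alpha(1-\alpha)\,\sigma_m^2 \;+\; (1-\alpha)^2\delta^2 \;+\;
\alpha^2\delta^2,$$

where $\sigma_m^2$ (m²/s) is the Brownian motion variance and $\delta$
(default 15 m) the telemetry error SD. $\sigma_m^2$ is estimated by the
leave-one-out likelihood of the odd interior fixes, each scored under the
bridge between its temporal neighbours. One numerical point matters here:
the *scored* fix is itself observed with error, so its likelihood variance
carries an additional $+\delta^2$ beyond the bridge variance above (which
only propagates the endpoints' error). Omitting that term inflates
$\hat\sigma_m^2$ by $\delta^2/(T\alpha(1-\alpha))$ — at a 2-h cadence with
$\delta = 15$ m that is a bias of ≈ 0.06 m²/s, which is why the package
includes it. The estimator maximises over $\log \sigma_m^2$ by bounded 1-D
search with lower bound 0.

The *dynamic* model slides a window of 11 fixes (22 h) with a 5-fix margin
along the path. In each window a single-variance model is compared by BIC
(1 vs 2 variance parameters) against a variance change at each candidate
breakpoint at least `margin` fixes from both edges — for the 11/5 defaults
exactly one candidate, the window's centre fix. Both models are scored on
the same leave-one-out points (the odd interiors of the two candidate
parts), so their likelihoods are comparable; when no break is selected the
reported variance is refit on all of the window's leave-one-out points.
Each window assigns its selected variances to the steps adjacent to its
core fix; a step's final $\sigma_m^2$ averages all windows covering it,
and uncovered edge steps inherit the nearest covered value.

The utilisation distribution integrates each bridge's bivariate normal
over 10 equally spaced fractions, weights bridges by duration, evaluates
density at cell centres (30 m default, NLCD-like) times cell area, and
normalises to total mass 1. Cell-centre evaluation instead of exact cell
integration is documented and bounded by a grid-refinement test. One
degenerate case is handled specially: a zero-displacement bridge uses the
full $\delta^2$ at every fraction, so a motionless animal's UD is exactly
the telemetry-error Gaussian — without this the two identical observations
would be treated as independent evidence shrinking the variance below its
physical floor. Isopleths take cells in decreasing mass order (ties broken
by row-major index) until the target mass is reached; 50% is the core
area, 95% the range area, reported in hectares.

A reference-bandwidth kernel density home range
($h = \hat\sigma n^{-1/6}$) supports release-site assessment: release
sites are buffered by a disc of the mean resident home-range area
(8.3 km², radius ≈ 1.63 km) and the landcover composition tabulated.

## Moving-window metrics and the phase switch

For each day $d$ the 7-day window spans days $d-3$ to $d+3$, truncated at
the series edges (so day 4 summarises days 1–7, and day 1 is defined
rather than dropped). The motion-variance profile is estimated once over
the entire monitoring period; each day's UD is then built from the bridges
inside that day's window. Days whose window holds fewer fixes than the
dBBMM window size yield missing values. Alongside the windowed core and
range areas the suite reports daily mean distance from the release site,
daily distance travelled (sum of step lengths ending that day), and net
squared displacement, with per-day fix counts logged. Group series are
means over animals per day with between-animal standard errors, reported
only when at least two animals contribute.

A translocated group switches from exploration to exploitation on the
first day its mean 95% range area reaches (drops to or below) the resident
reference — by default the grand mean of the habitat-matched resident
group's daily range areas over the horizon, with a day-matched variant
available. The crossing day is the *last exploration day*; exploitation
starts the following day. If the reference is never reached the group
stays in exploration and the result is flagged.

## Step-selection functions

Every used step with a defined previous heading is compared to 20 random
steps drawn from empirical movement kernels: one pooled kernel for
residents regardless of habitat, and one per release habitat × phase for
translocated animals, always excluding the focal animal's own steps.
Random steps resample step length and turning angle independently (the
standard marginal construction) and are anchored at the used step's origin
and previous heading. Endpoints are annotated with the landcover class on
a half-open cell convention; endpoints in excluded classes (developed,
cultivated, open water, barren) or off the raster invalidate the
alternative, and a stratum whose used step is invalid is dropped.

The conditional logit maximises
$\sum_s \left[x_{\text{used}}\beta - \log \sum_{\text{alt}}
e^{x_{\text{alt}}\beta}\right]$ via `survival::clogit` (with one used step
per stratum all partial-likelihood tie methods coincide); an independent
enumeration evaluator of the same likelihood backs the tests. Four
candidate models are ranked by AIC with a 2-unit equivalence band: habitat
only; habitat × status; habitat × release habitat; and habitat × (status +
release habitat); status and release-habitat main effects are absorbed by
the strata. A post-hoc model adds diel interactions to every habitat term
of the winner. Diel period is classified by solar altitude at the study
latitude (33.3°N) by default, with a fixed clock window available for
controlled tests. The weekly analysis fits, per group, week-specific
bottomland coefficients (week interacting with the bottomland dummy,
nocturnal strata only, 13 release-relative weeks).

Two deliberate substitutions: the per-animal random effect sometimes added
to such models is replaced by cluster-robust (sandwich) standard errors by
animal — a true mixed conditional logit is heavy and no variance estimates
exist to match — and the weekly model's autocorrelation term is replaced
by the week-interaction conditional logit just described. Both are design
choices of this package, stated here so users know what the standard
errors do and do not absorb. Confidence intervals in the recovery
experiments use the $t_{G-1}$ critical value, the standard few-cluster
correction when only $G$ animals contribute clusters.

## The simulator and what passing tests mean

`simulate_cohort()` is a first-class module, not a fixture: a smooth
Gaussian random field thresholded at class-fraction quantiles gives
contiguous habitat patches whose realised fractions match their targets
(defaults 26% bottomland / 44% upland pine, the composition of a
bottomland release area); agents walk by discrete choice, picking among
200 candidate steps with probability $\propto e^{\beta_{\text{class}} +
\text{attraction}}$. Exploration uses long, directionally persistent steps
with no attraction; exploitation uses short, weakly persistent steps with
attraction to a range centre set at settlement. Residents start settled;
translocated agents switch on day 25 (between the two empirically
reported group switch days); a configurable fraction (default 0.2, i.e.
roughly 3 in 14) walks home instead, exercising the homing rule. Observed
fixes add isotropic 15 m telemetry noise and lognormal PDOP values.

Calibration was fixed before the recovery experiments were run: resident
attraction is set so a resident's 95% KDE home range is ≈ 8 km²
(matching the 8.3 km² mean that also defines the homing radius), dispersal
reaches ≈ 5 km by day 5 and settles ≈ 8–10 km from release on a 24 km
domain (a deliberately scaled-down stage relative to the 17.1 km mean
translocation distance of the motivating study), and settled translocated
ranges are modestly tighter than resident ones, consistent with
translocated animals using smaller areas than residents once settled. The
candidate count K = 200 matters: at K = 50 the discrete-choice walk is a
visibly biased approximation of the multinomial selection model (fitted
bottomland selection attenuated ≈ 7% with inflated dispersion), so the
larger value is the default.

Problem sizes in the shipped experiments are chosen for tight, fast
inference: coefficient coverage uses 8 translocated agents over 60 days ×
20 replicates; model-selection recovery 12 agents over 40 days × 20 runs;
phase recovery 7 agents over 45 days × 10 cohorts; the weekly trend 5
agents over 90 days. The demonstration pipeline runs 8 agents over 90
days and completes in about a minute.

Two honest caveats. First, the coverage experiment draws availability
from the generative kernels and uses a small telemetry error, because it
measures *estimator calibration*: under the full study conditions — 15 m
error on a 30 m raster — endpoint-habitat misclassification attenuates all
selection coefficients by roughly 10–15%, and empirical-kernel
availability adds further systematic distortion when selection reshapes
realised movement. Those effects are properties of the SSF design itself,
not of this implementation; the pipeline-level tests (model ranking,
weekly trend, phase recovery, demo) all run at the full 15 m error with
empirical kernels, where ranking and trends are robust even though
coefficient magnitudes are conservative. Second, the simulator omits
social dynamics, mortality, fix failure and habitat-dependent movement
speed, so passing tests demonstrate internal consistency of the method
chain, not fidelity to any particular field system.

## Reproducing the numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json` reruns the
core computations — the worked bridge variance, the motionless-animal
isopleth against its closed form, motion-variance recovery, the
conditional-logit enumeration check, the simulator's resident home-range
scale, and the phase, coefficient, model-selection and weekly-trend
recovery experiments — and writes each value with the problem size used.
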