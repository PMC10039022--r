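# movephase

Movement-ecology tools for the question every translocation program faces:
after an animal is dropped into a novel landscape, when does it stop
*exploring* and start *exploiting* — and does its habitat selection change
across that switch? The package was built for GPS-collar studies of
translocated ungulates and wild pigs (2-h fixes over ~90 days, residents
as reference animals) but the machinery is general.

## What it computes

**Space use.** A dynamic Brownian bridge movement model (dBBMM): between
consecutive fixes the position at fraction α is normal with mean
`a + α(b − a)` and variance `Tα(1−α)σ²_m + (1−α)²δ² + α²δ²`, with the
Brownian motion variance σ²_m estimated by leave-one-out likelihood in a
sliding window (11 fixes, 5-fix margin, BIC breakpoint test) so it tracks
behavioural changes along the path. Utilisation distributions are
summarised by 50% ("core area") and 95% ("range area") isopleths inside a
7-day moving window (day *d* ± 3 days), alongside daily distance from the
release site, daily distance travelled, and net squared displacement.

**The phase switch.** A translocated group leaves exploration on the first
day its mean 95% range area reaches the resident average — the crossing
day is the last exploration day.

**Habitat selection.** Phase-stratified step-selection functions: each
used step is compared to 20 random steps drawn from empirical step-length
and turning-angle kernels (stratified by phase and release habitat,
excluding the focal animal), endpoints annotated on a 3-class landcover
raster (bottomland / upland pine / grassland, other classes excluded),
and conditional logistic regression fitted with cluster-robust SEs by
animal. Four candidate models are ranked by AIC (habitat; × status; ×
release habitat; × status + release habitat) plus a diel post-hoc, and
weekly nocturnal bottomland selection coefficients trace selection through
time.

**Ground truth.** A seeded agent-based simulator (patchy Gaussian-field
landscapes, discrete-choice walkers with known β, programmed settlement
day, optional homing) generates every input format the pipeline reads, so
all of the above is validated by recovery experiments.

## Worked example

```r
library(movephase)

# one command: simulate a cohort (2 animals per status x habitat group,
# 90 days), write its GPS/metadata/landcover files, run the full pipeline
res <- run_demo("demo_out", seed = 1, n_per_group = 2)

res$phases$upland_pine
#> <phase_assignment> upland_pine group: reached resident level on day 28
#>   (exploitation from day 29)

res$ranking$table
#>                     model k    logLik      AIC      dAIC equivalent
#> 1 habitat_x_status_x_diel 9 -24919.01 49856.01  0.000000       TRUE
#> 2        habitat_x_status 5 -24926.90 49863.79  7.779026      FALSE
#> 3 habitat_x_status_release 7 -24926.64 49867.27 11.260000      FALSE
#> 4                 habitat 3 -24931.11 49868.22 12.203451      FALSE
#> 5       habitat_x_release 5 -24930.17 49870.34 14.330146      FALSE
```

Reading this output: the simulated translocated-to-upland group's mean
95% range area fell to the resident average on day 28 (its settlement was
programmed on day 25; the 7-day window lags by design), so days 1–28 are
exploration and days 29–90 exploitation for that group's selection
kernels. The AIC table ranks the diel post-hoc model first, meaning
day/night selection differences earn their 4 extra parameters on these
data; `res$weekly` holds the 13-week nocturnal bottomland series per
group, and `demo_out/results/` the CSV artifacts plus a `manifest.json`
whose hash is identical on rerun with the same seed.

Lower-level entry points mirror the analysis stages:
`preprocess_trajectory()`, `dynamic_variance_profile()`, `compute_ud()`,
`isopleth_area()`, `windowed_ud_areas()`, `group_series()`,
`detect_phase_transition()`, `build_kernels()`, `assemble_choice_sets()`,
`rank_models_aic()`, `weekly_selection_series()`. A thin command-line
front-end lives at `inst/cli/movephase.R` (`demo`, `simulate`, `run`).

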