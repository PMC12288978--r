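# stratpower

Simulation-based power analysis for biomarker-stratified clinical trials
in traumatic optic neuropathy (TON).

TON trials are notoriously underpowered: enrolled patients range from
near-normal to complete optic-nerve degeneration, and the within-arm
variance of any outcome swamps moderate treatment effects. Ganglion cell
complex (GCC) thickness from OCT — expressed as the percentage loss of
the injured eye relative to the healthy contralateral eye — is a
structural severity biomarker that can be used to stratify patients into
mild (<10%), moderate (10–20%) and severe (>20%) bands at enrolment.
`stratpower` is for trial statisticians and translational researchers who
want to quantify, by Monte Carlo, how much power such stratification buys
and how that gain depends on biomarker quality.

## What it computes

* **Calibration with uncertainty** — the linear link from GCC thickness
  loss *x* to retinal ganglion cell (RGC) somata loss,
  `Ŷ = 2.697·x − 2.445` (95% CI slope 2.130–3.265, intercept −11.00 to
  6.110, R² = 0.87), ships as the packaged default. Predictions are
  sampled from a normal density truncated to the envelope spanned by the
  coefficient confidence limits, then clamped to [0, 100] — so each GCC
  loss maps to a distribution of RGC losses, not a point.
* **Trial power with and without stratification** — each simulated round
  draws 2m patients from a GCC-loss pool, converts losses to RGC-loss
  samples, multiplies the treated arm by a rescue ratio ρ (fraction of
  loss remaining; smaller = stronger therapy), and tests treated vs
  control with a Shapiro-Wilk-gated t / Wilcoxon rank-sum test. A
  stratified round tests within each severity band and is effective if
  any band rejects. Power = proportion of effective rounds out of
  10,000, with binomial Monte-Carlo SE; `minimal_sample_size()` walks
  m = 20, 30, …, 90 to the smallest adequate trial.
* **Progression detection rates** — for longitudinal cohorts (GCC / VFI /
  MD), the probability that a random subset of n patients shows a
  significant decline between visits, with GCC age-adjusted for normal
  thinning (−0.2%/year) and rates compared across parameters by exact
  McNemar on shared subsets.
* **Stratified outcome validation** — pre/post paired analysis of a
  treated cohort, pooled and within baseline-GCC or baseline-acuity
  strata (qualitative acuity levels NLP/LP/HM/FC mapped through a
  configurable numeric scale).
* **Synthetic cohort generators** — seeded generators reproduce the
  statistical structure of the clinical cohorts (a quantile-matched
  skewed GCC-loss pool; latent RGC loss at realized R² ≈ 0.87;
  glaucoma-like longitudinal decline; a treated cohort whose improvement
  is confined to the mild stratum), so the whole pipeline runs and is
  tested without any patient-level data.

## Worked example

```r
library(stratpower)

# 264-patient synthetic GCC-loss pool (median loss 13.3%)
pool <- generate_gcc_pool(synthetic_config(n_patients = 264, seed = 7))

# unstratified trial: m = 40 per arm, rescue ratio 0.7
un <- trial_design(m_per_arm = 40, rescue_ratio = 0.7, reps = 2000, seed = 3)
estimate_power(pool, un)
#> Estimated power 0.3810 (MC SE 0.0109, 2000 reps) | m = 40, rescue = 0.70, biomarker = none

# same trial stratified by GCC severity band
st <- trial_design(m_per_arm = 40, rescue_ratio = 0.7, reps = 2000, seed = 3,
                   scheme = stratum_scheme(), biomarker = "gcc")
estimate_power(pool, st)
#> Estimated power 0.9870 (MC SE 0.0025, 2000 reps) | m = 40, rescue = 0.70, biomarker = gcc
#>   per-stratum rejection: mild 0.166, moderate 0.715, severe 0.946
```

At identical sample size and effect, stratification lifts power from
0.38 to 0.99: within a severity band the RGC-loss distribution is far
narrower, and the severe band (largest absolute effects) rejects in 95%
of rounds. Equivalently, the minimal adequate trial shrinks severalfold —
the unstratified design needs ~80 patients per arm for power 0.6 at this
effect size, the GCC-stratified design 20:

```r
minimal_sample_size(pool, trial_design(20, 0.7, reps = 2000, seed = 3),
                    target_power = 0.6)$m
#> [1] 80
```

The stratified validation stage recovers a planted mild-stratum-only
treatment response that the pooled analysis misses:

```r
co <- generate_treated_cohort(synthetic_config(seed = 3))
stratified_outcome_table(co, by = "gcc", outcome = "va")
#>    stratum  n mean_change      p_value   test_used significant
#> 1     mild 11  0.48410749 0.0005625379    paired t        TRUE
#> 2 moderate  5 -0.18848382 0.1851005048    paired t       FALSE
#> 3   severe  5 -0.78063771 0.0625000000 signed-rank       FALSE
#> 4      all 21  0.02283689 0.8636953980    paired t       FALSE
```

Mean change is in log-acuity units (positive = improvement): the 11
mild patients improve by ~0.48 log units (p < 0.001) while the cohort
as a whole is flat (p = 0.86) — the signature pattern that motivates
biomarker stratification.

See `vignettes/biomarker-stratified-power.Rmd` for the models, the
generator defaults and the reasoning behind every numerical choice.

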