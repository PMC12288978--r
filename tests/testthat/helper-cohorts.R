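# Longitudinal cohort with deterministic worsening structure: every patient
# declines in GCC, exactly n_vfi_worse decline in VFI and n_md_worse in MD.
# Intervals are zero so GCC age adjustment is the identity.
make_counting_cohort <- function(n = 25, n_vfi_worse = 17, n_md_worse = 21) {
  data.frame(
    patient_id = seq_len(n),
    interval_years = rep(0, n),
    age_years = rep(60, n),
    param_gcc_base = rep(100, n),
    param_gcc_follow = rep(100, n) - 2,
    param_vfi_base = rep(80, n),
    param_vfi_follow = 80 + ifelse(seq_len(n) <= n_vfi_worse, -3, +1),
    param_md_base = rep(-5, n),
    param_md_follow = -5 + ifelse(seq_len(n) <= n_md_worse, -1, +0.5))
}

# Null longitudinal cohort: no systematic change, pure measurement noise.
null_longitudinal_config <- function(n = 25, seed = 1) {
  synthetic_config(
    n_patients = n, seed = seed,
    decline_effects = list(gcc = c(0, 1), vfi = c(0, 2), md = c(0, 1)),
    interval_range = c(0, 0))
}

point_model <- function(slope = 1, intercept = 0) {
  calibration_model(slope = slope, intercept = intercept)
}
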