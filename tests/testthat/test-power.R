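test_that("stratum assignment follows the clinical boundary convention", {
  sch <- stratum_scheme()
  got <- assign_strata(c(-3, 0, 9.99, 10, 15, 20, 20.01, 45), sch)
  expect_equal(as.character(got),
               c("mild", "mild", "mild", "moderate", "moderate",
                 "moderate", "severe", "severe"))
  expect_error(stratum_scheme(c(20, 10)), "increasing")
  expect_error(stratum_scheme(c(10, 20), c("a", "b")), "label")
})

test_that("trial design invariants are enforced", {
  expect_error(trial_design(1, 0.7), "m_per_arm")
  expect_error(trial_design(20, 0), "rescue_ratio")
  expect_error(trial_design(20, 1.2), "rescue_ratio")
  expect_error(trial_design(20, 0.7, alpha = 1), "alpha")
  expect_error(trial_design(20, 0.7, biomarker = "surrogate"),
               "surrogate_r2")
})

test_that("power estimation is seed-deterministic and mc_se is binomial", {
  pool <- generate_gcc_pool(synthetic_config(n_patients = 264, seed = 7))
  d <- trial_design(20, 0.7, reps = 200, seed = 31)
  e1 <- estimate_power(pool, d)
  e2 <- estimate_power(pool, d)
  expect_identical(e1$effective_flags, e2$effective_flags)
  expect_equal(e1$power, e2$power)
  expect_equal(e1$mc_se, sqrt(e1$power * (1 - e1$power) / 200))
  d2 <- trial_design(20, 0.7, reps = 200, seed = 32)
  expect_false(identical(e1$effective_flags,
                         estimate_power(pool, d2)$effective_flags))
})

test_that("a single-stratum stratified design collapses to unstratified", {
  pool <- generate_gcc_pool(synthetic_config(n_patients = 264, seed = 7))
  un <- trial_design(25, 0.7, reps = 150, seed = 41)
  one <- trial_design(25, 0.7, reps = 150, seed = 41,
                      scheme = stratum_scheme(numeric(0), "all"),
                      biomarker = "gcc")
  e_un <- estimate_power(pool, un)
  e_one <- estimate_power_stratified(pool, one)
  expect_identical(e_un$effective_flags, e_one$effective_flags)
  expect_equal(e_un$power, e_one$power)
})

test_that("an extreme therapeutic effect is detected almost surely", {
  pool <- generate_gcc_pool(synthetic_config(n_patients = 264, seed = 7))
  d <- trial_design(30, 0.1, reps = 300, seed = 51)
  expect_gte(estimate_power(pool, d)$power, 0.99)
})

test_that("power grows with sample size and with effect size", {
  pool <- generate_gcc_pool(synthetic_config(n_patients = 264, seed = 7))
  p_small <- estimate_power(pool, trial_design(20, 0.7, reps = 600,
                                               seed = 61))
  p_large <- estimate_power(pool, trial_design(90, 0.7, reps = 600,
                                               seed = 61))
  slack <- 3 * sqrt(p_small$mc_se^2 + p_large$mc_se^2)
  expect_gte(p_large$power, p_small$power - slack)
  p_weak <- estimate_power(pool, trial_design(40, 0.9, reps = 600,
                                              seed = 62))
  p_strong <- estimate_power(pool, trial_design(40, 0.5, reps = 600,
                                                seed = 62))
  expect_gte(p_strong$power, p_weak$power - slack)
})

test_that("stratified estimation requires a scheme and a biomarker", {
  pool <- generate_gcc_pool(synthetic_config(n_patients = 100, seed = 7))
  d <- trial_design(10, 0.7, reps = 10, seed = 1)
  expect_error(estimate_power_stratified(pool, d), "scheme")
  d2 <- trial_design(10, 0.7, reps = 10, seed = 1,
                     scheme = stratum_scheme())
  expect_error(estimate_power_stratified(pool, d2), "biomarker")
})

test_that("run_trial errors when the pool cannot fill two disjoint arms", {
  expect_error({
    set.seed(1)
    run_trial(rnorm(10, 20, 5), trial_design(10, 0.7, reps = 1, seed = 1))
  }, "pool exhausted")
  # bootstrap mode lifts the restriction
  set.seed(1)
  tr <- run_trial(rnorm(10, 20, 5),
                  trial_design(10, 0.7, reps = 1, seed = 1, replace = TRUE))
  expect_type(tr$effective, "logical")
})

test_that("minimal sample size search handles trivial targets and nulls", {
  pool <- generate_gcc_pool(synthetic_config(n_patients = 264, seed = 7))
  d <- trial_design(20, 0.7, reps = 100, seed = 71)
  res0 <- minimal_sample_size(pool, d, target_power = 0,
                              m_grid = c(20L, 30L))
  expect_equal(res0$m, 20L)
  expect_equal(nrow(res0$powers), 1L)
  dn <- trial_design(20, 1, reps = 150, seed = 72)
  resn <- minimal_sample_size(pool, dn, target_power = 0.6,
                              m_grid = c(20L, 40L))
  expect_false(resn$reached)
  expect_true(is.na(resn$m))
  expect_error(minimal_sample_size(pool, d, m_grid = integer(0)),
               "non-empty")
  expect_error(minimal_sample_size(pool, d, m_grid = c(30L, 20L)),
               "ascending")
})

test_that("a 1x1 power surface equals a single estimate under its cell seed", {
  pool <- generate_gcc_pool(synthetic_config(n_patients = 264, seed = 7))
  surf <- power_surface(pool, m_grid = 25L, rescue_grid = 0.7,
                        scenarios = "none", reps = 150, seed = 81)
  expect_equal(nrow(surf), 1L)
  d <- trial_design(25, 0.7, reps = 150, seed = surf$seed[1])
  expect_equal(surf$power[1], estimate_power(pool, d)$power)
  expect_error(power_surface(pool, m_grid = numeric(0)), "non-empty")
  expect_error(power_surface(pool, scenarios = "psychic"), "unknown")
})

test_that("rescue-convention flag flips the effect direction", {
  pool <- generate_gcc_pool(synthetic_config(n_patients = 264, seed = 7))
  d_rem <- trial_design(30, 0.2, reps = 300, seed = 91)
  d_res <- trial_design(30, 0.2, reps = 300, seed = 91,
                        rescue_convention = "rescued")
  p_rem <- estimate_power(pool, d_rem)$power  # strong effect
  p_res <- estimate_power(pool, d_res)$power  # weak effect (20% rescued)
  expect_gt(p_rem, p_res)
})
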