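test_that("GCC age adjustment credits back normal thinning exactly", {
  expect_equal(age_adjust_gcc(95, 0), 95)
  # a decline of exactly 0.2%/yr adjusts to zero change
  expect_equal(age_adjust_gcc(99.8, 1) - 100, 0, tolerance = 1e-10)
  expect_equal(age_adjust_gcc(95, 5) - 100, 95 / 0.99 - 100,
               tolerance = 1e-12)
  expect_lt(abs((age_adjust_gcc(95, 5) - 100) - (-4.0404)), 0.001)
  # exact inverse: applying normal thinning to a constant eye, then
  # adjusting, restores the baseline
  base <- 87
  thinned <- base * (1 - 0.002 * 3)
  expect_equal(age_adjust_gcc(thinned, 3), base, tolerance = 1e-12)
  expect_error(age_adjust_gcc(95, 600), "interval too large")
  expect_error(age_adjust_gcc(95, -1), "interval_years")
})

test_that("worsening proportions count decliners deterministically", {
  co <- make_counting_cohort(25, n_vfi_worse = 17, n_md_worse = 21)
  wp <- worsening_proportions(co)
  expect_equal(wp$proportion_worsened[wp$parameter == "gcc"], 1.0)
  expect_equal(wp$proportion_worsened[wp$parameter == "vfi"], 0.68)
  expect_equal(wp$proportion_worsened[wp$parameter == "md"], 0.84)
  # zero-change cohort: strict inequality, nothing worsens
  co0 <- co
  co0$param_gcc_follow <- co0$param_gcc_base
  co0$param_vfi_follow <- co0$param_vfi_base
  co0$param_md_follow <- co0$param_md_base
  wp0 <- worsening_proportions(co0)
  expect_equal(wp0$proportion_worsened, c(0, 0, 0))
  expect_error(worsening_proportions(co[0, ]), "empty")
  # records with missing values are excluded and counted
  co_na <- co
  co_na$param_vfi_follow[1:2] <- NA
  wp_na <- worsening_proportions(co_na)
  expect_equal(wp_na$n_excluded[wp_na$parameter == "vfi"], 2)
  expect_equal(wp_na$n_used[wp_na$parameter == "vfi"], 23)
})

test_that("GCC worsening is judged after age adjustment", {
  # decline exactly at the normal aging rate over 2 years: not progression
  co <- data.frame(patient_id = 1:5, interval_years = 2, age_years = 60,
                   param_gcc_base = 100,
                   param_gcc_follow = 100 * (1 - 0.002 * 2),
                   param_vfi_base = 80, param_vfi_follow = 80,
                   param_md_base = -5, param_md_follow = -5)
  wp <- worsening_proportions(co)
  expect_equal(wp$proportion_worsened[wp$parameter == "gcc"], 0)
})

test_that("detection rate is near alpha for a null cohort and 1 for strong decline", {
  # cohort large enough that small subsets behave as independent null draws
  null_co <- generate_longitudinal_cohort(null_longitudinal_config(500, 1))
  for (n in c(5, 12, 20)) {
    r <- detection_rate(null_co, "gcc", n, reps = 500, seed = 3)
    expect_lt(abs(r$rate - 0.05), 0.035)
  }
  strong <- generate_longitudinal_cohort(synthetic_config(
    n_patients = 25, seed = 2,
    decline_effects = list(gcc = c(-3, 0.3), vfi = c(0, 2), md = c(0, 1))))
  r <- detection_rate(strong, "gcc", 20, reps = 200, seed = 4)
  expect_gte(r$rate, 0.99)
})

test_that("detection rate is non-decreasing in subset size for a real effect", {
  co <- generate_longitudinal_cohort(synthetic_config(
    n_patients = 25, seed = 5,
    decline_effects = list(gcc = c(-1, 1.4), vfi = c(0, 2), md = c(0, 1))))
  rates <- vapply(c(5, 10, 15, 20), function(n)
    detection_rate(co, "gcc", n, reps = 400, seed = 6)$rate, numeric(1))
  mc <- 3 * sqrt(0.25 / 400)
  expect_true(all(diff(rates) > -2 * mc))
  expect_gt(rates[4], rates[1])
})

test_that("subset draws are seed-deterministic and size-checked", {
  co <- generate_longitudinal_cohort(null_longitudinal_config(20, 7))
  r1 <- detection_rate(co, "vfi", 8, reps = 50, seed = 9)
  r2 <- detection_rate(co, "vfi", 8, reps = 50, seed = 9)
  expect_identical(r1$significant_flags, r2$significant_flags)
  expect_error(detection_rate(co, "vfi", 21, reps = 10), "exceeds")
  expect_error(detection_rate(co, "vfi", 2, reps = 10), ">= 3")
})

test_that("McNemar comparison matches its binomial closed form", {
  mk <- function(flags, seed = 1, n = 10) structure(
    list(parameter = "x", n = n, rate = mean(flags), reps = length(flags),
         alpha = 0.05, significant_flags = flags, seed = seed),
    class = "detection_rate_result")
  f <- rep(c(TRUE, FALSE), 50)
  expect_equal(compare_detection_rates(mk(f), mk(f))$p_value, 1)
  # discordant counts b = 10, c = 0: exact p = 2 * 0.5^10
  a <- c(rep(TRUE, 10), rep(FALSE, 90))
  b <- rep(FALSE, 100)
  res <- compare_detection_rates(mk(a), mk(b))
  expect_equal(res$method, "mcnemar")
  expect_equal(res$p_value, 2 * 0.5^10, tolerance = 1e-12)
  # unpaired results fall back to Fisher's exact test
  res_f <- compare_detection_rates(mk(a, seed = 1), mk(b, seed = 2))
  expect_equal(res_f$method, "fisher")
  tab <- rbind(c(10, 90), c(0, 100))
  expect_equal(res_f$p_value, fisher.test(tab)$p.value, tolerance = 1e-12)
  expect_error(compare_detection_rates(mk(a), mk(b, n = 12)), "subset size")
})

test_that("parameters sharing a seed share subsets (pairable rates)", {
  co <- generate_longitudinal_cohort(synthetic_config(
    n_patients = 25, seed = 11,
    decline_effects = list(gcc = c(-2, 0.5), vfi = c(-2, 6), md = c(-1, 2))))
  r_gcc <- detection_rate(co, "gcc", 10, reps = 300, seed = 13)
  r_vfi <- detection_rate(co, "vfi", 10, reps = 300, seed = 13)
  cmp <- compare_detection_rates(r_gcc, r_vfi)
  expect_equal(cmp$method, "mcnemar")
  expect_gt(r_gcc$rate, r_vfi$rate)
})
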