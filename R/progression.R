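#' Age-adjust follow-up GCC thickness
#'
#' Credits back the expected normal age-related GCC thinning of 0.2% per
#' year: `adjusted_follow = follow / (1 - 0.002 * interval_years)`. A
#' decline exactly equal to normal aging therefore adjusts to zero change,
#' so only disease-attributable thinning counts as progression.
#'
#' @param gcc_follow Observed follow-up GCC thickness (µm).
#' @param interval_years Years between baseline and follow-up, >= 0.
#' @param rate_per_year Normal thinning rate as a fraction per year
#'   (default 0.002, i.e. 0.2%/year).
#' @return Adjusted follow-up GCC thickness (µm).
#' @export
age_adjust_gcc <- function(gcc_follow, interval_years, rate_per_year = 0.002) {
  if (any(interval_years < 0)) stop("interval_years must be >= 0")
  divisor <- 1 - rate_per_year * interval_years
  if (any(divisor <= 0))
    stop("interval too large: expected normal thinning exceeds the eye")
  gcc_follow / divisor
}

# Baseline / follow-up columns for a longitudinal parameter, with GCC
# follow-up age-adjusted. Lower = worse for gcc (µm), vfi (%) and md (dB).
param_columns <- function(cohort, parameter, age_adjust = TRUE) {
  parameter <- match.arg(parameter, c("gcc", "vfi", "md"))
  bcol <- paste0("param_", parameter, "_base")
  fcol <- paste0("param_", parameter, "_follow")
  if (!all(c(bcol, fcol) %in% names(cohort)))
    stop("cohort lacks columns for parameter '", parameter, "'")
  base <- cohort[[bcol]]
  follow <- cohort[[fcol]]
  if (parameter == "gcc" && age_adjust) {
    if (!"interval_years" %in% names(cohort))
      stop("GCC age adjustment requires interval_years")
    follow <- age_adjust_gcc(follow, cohort$interval_years)
  }
  keep <- is.finite(base) & is.finite(follow)
  list(base = base[keep], follow = follow[keep],
       n_excluded = sum(!keep))
}

#' Progression detection rate by subset resampling
#'
#' Estimates, for a longitudinal cohort and one parameter (GCC, VFI or MD),
#' the probability that a random subset of `n` patients shows a
#' statistically significant decline between baseline and follow-up.
#' Per repetition, `n` patients are drawn without replacement and the
#' normality-adaptive paired test ([adaptive_paired_test()]) is applied in
#' the worsening direction (lower is worse for all three parameters; GCC is
#' age-adjusted first). The detection rate is the proportion of significant
#' repetitions. Subset draws depend only on the seed and repetition index —
#' not on the parameter — so rates for different parameters computed under
#' the same seed share subsets and can be compared pairwise with McNemar's
#' test ([compare_detection_rates()]).
#'
#' @param cohort Data.frame of longitudinal records (see
#'   [generate_longitudinal_cohort()] for the schema).
#' @param parameter `"gcc"`, `"vfi"` or `"md"`.
#' @param n Subset size, between 3 and the cohort size.
#' @param reps Repetitions, default 1000.
#' @param alpha Significance level, default 0.05.
#' @param seed Integer seed for the subset draws.
#' @return An object of class `detection_rate_result`: list with
#'   `parameter`, `n`, `rate`, `reps`, `alpha`, and the per-repetition
#'   `significant_flags`.
#' @export
detection_rate <- function(cohort, parameter, n, reps = 1000L, alpha = 0.05,
                           seed = 1L) {
  N <- nrow(cohort)
  if (n > N) stop("subset size n exceeds cohort size")
  if (n < 3) stop("subset size n must be >= 3")
  vals <- param_columns(cohort, parameter)
  if (length(vals$base) < N)
    stop("records with missing values present; drop them before resampling")
  set.seed(seed)
  subsets <- lapply(seq_len(reps), function(i) sample.int(N, n))
  flags <- vapply(subsets, function(ix) {
    adaptive_paired_test(vals$base[ix], vals$follow[ix], alpha,
                         alternative = "less")$significant
  }, logical(1))
  structure(
    list(parameter = parameter, n = as.integer(n), rate = mean(flags),
         reps = as.integer(reps), alpha = alpha,
         significant_flags = flags, seed = as.integer(seed)),
    class = "detection_rate_result")
}

#' Detection rates across subset sizes and parameters
#'
#' Convenience wrapper running [detection_rate()] over a grid of subset
#' sizes for one or more parameters, sharing subset draws across parameters
#' at each size.
#'
#' @inheritParams detection_rate
#' @param parameters Character vector among `"gcc"`, `"vfi"`, `"md"`.
#' @param n_range Integer vector of subset sizes, default `5:20`.
#' @return Data.frame with columns `parameter`, `n`, `rate`, `reps`.
#' @export
detection_rate_table <- function(cohort, parameters = c("gcc", "vfi", "md"),
                                 n_range = 5:20, reps = 1000L, alpha = 0.05,
                                 seed = 1L) {
  rows <- list()
  for (n in n_range) {
    for (p in parameters) {
      res <- detection_rate(cohort, p, n, reps, alpha, seed = seed + n)
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = p, n = n, rate = res$rate, reps = reps)
    }
  }
  do.call(rbind, rows)
}

#' Proportion of patients worsening per parameter
#'
#' Deterministic per-parameter count of patients whose follow-up value is
#' strictly worse than baseline: GCC after age adjustment (thinner = worse),
#' VFI lower = worse, MD lower = worse. Records with missing values for a
#' parameter are excluded and counted.
#'
#' @param cohort Data.frame of longitudinal records.
#' @param parameters Parameters to evaluate.
#' @return Data.frame with columns `parameter`, `n_used`, `n_excluded`,
#'   `proportion_worsened`.
#' @export
worsening_proportions <- function(cohort,
                                  parameters = c("gcc", "vfi", "md")) {
  if (!nrow(cohort)) stop("cohort is empty")
  rows <- lapply(parameters, function(p) {
    vals <- param_columns(cohort, p)
    data.frame(parameter = p, n_used = length(vals$base),
               n_excluded = vals$n_excluded,
               proportion_worsened = mean(vals$follow < vals$base))
  })
  do.call(rbind, rows)
}

# Exact McNemar p-value from discordant counts b and c: conditional on
# b + c, the discordant split is Binomial(b + c, 1/2) under the null.
mcnemar_exact_p <- function(b, c) {
  nd <- b + c
  if (nd == 0) return(1)
  min(1, 2 * stats::pbinom(min(b, c), nd, 0.5))
}

#' Compare two detection rates
#'
#' When both results were computed at the same subset size with paired
#' repetitions (same seed, hence identical subsets), the per-repetition
#' significance flags form matched pairs and McNemar's exact test on the
#' discordant counts is used. Otherwise Fisher's exact test is applied to
#' the 2x2 table of significant / non-significant counts.
#'
#' @param res_a,res_b `detection_rate_result` objects with equal `n` and
#'   `reps`.
#' @return List with `p_value`, `method` (`"mcnemar"` or `"fisher"`), and
#'   the discordant counts (for McNemar).
#' @export
compare_detection_rates <- function(res_a, res_b) {
  stopifnot(inherits(res_a, "detection_rate_result"),
            inherits(res_b, "detection_rate_result"))
  if (res_a$n != res_b$n)
    stop("detection rates were computed at different subset sizes")
  if (res_a$reps != res_b$reps)
    stop("detection rates were computed with different repetition counts")
  paired <- identical(res_a$seed, res_b$seed)
  if (paired) {
    fa <- res_a$significant_flags; fb <- res_b$significant_flags
    b <- sum(fa & !fb); c <- sum(!fa & fb)
    list(p_value = mcnemar_exact_p(b, c), method = "mcnemar",
         discordant = c(b = b, c = c))
  } else {
    tab <- rbind(c(sum(res_a$significant_flags),
                   res_a$reps - sum(res_a$significant_flags)),
                 c(sum(res_b$significant_flags),
                   res_b$reps - sum(res_b$significant_flags)))
    list(p_value = stats::fisher.test(tab)$p.value, method = "fisher")
  }
}
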