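#' Severity stratification scheme
#'
#' Cut points on a loss-percentage scale defining severity strata. With the
#' default boundaries `c(10, 20)` and labels mild/moderate/severe the
#' assignment is: mild below 10, moderate from 10 to 20 inclusive, severe
#' above 20 — i.e., values equal to a boundary fall into the middle band,
#' matching the clinical convention "mild (<10%), moderate (10%–20%),
#' severe (>20%)". Negative losses (thickening) are mild.
#'
#' @param boundaries Strictly increasing numeric cut points (may be empty,
#'   giving a single all-inclusive stratum).
#' @param labels Character labels, one more than there are boundaries.
#' @return An object of class `stratum_scheme`.
#' @export
stratum_scheme <- function(boundaries = c(10, 20),
                           labels = c("mild", "moderate", "severe")) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) && any(diff(boundaries) <= 0))
    stop("boundaries must be strictly increasing")
  if (length(labels) != length(boundaries) + 1)
    stop("need exactly one more label than boundaries")
  structure(list(boundaries = boundaries, labels = as.character(labels)),
            class = "stratum_scheme")
}

#' Assign severity strata
#'
#' @param values Numeric vector on the scheme's scale.
#' @param scheme A `stratum_scheme`.
#' @return Factor of stratum labels (levels in scheme order).
#' @export
assign_strata <- function(values, scheme) {
  stopifnot(inherits(scheme, "stratum_scheme"))
  b <- scheme$boundaries
  idx <- rep(1L, length(values))
  if (length(b)) {
    idx <- idx + (values >= b[1])
    if (length(b) > 1)
      for (j in 2:length(b)) idx <- idx + (values > b[j])
  }
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Specify a simulated trial design
#'
#' @param m_per_arm Patients per arm, >= 2.
#' @param rescue_ratio Fraction of each sampled RGC somata loss remaining
#'   after treatment, in (0, 1]; smaller means a stronger therapeutic
#'   effect. 1 is the null design (no effect).
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param scheme A `stratum_scheme`, or `NULL` for an unstratified trial.
#' @param biomarker Stratification biomarker: `"none"` (unstratified),
#'   `"gcc"` (observed GCC loss), `"ideal"` (the sampled RGC loss itself),
#'   or `"surrogate"` (RGC loss degraded to `surrogate_r2`).
#' @param surrogate_r2 Squared correlation of the surrogate biomarker with
#'   RGC loss (required when `biomarker = "surrogate"`).
#' @param reps Monte-Carlo repetitions, default 10000.
#' @param seed Master seed; replicate substreams are derived from it so
#'   repetitions are order-independent.
#' @param replace Sample arms with replacement (bootstrap mode) instead of
#'   drawing 2m distinct pool members.
#' @param decision_rule `"one.sided"` (default): a round is effective when
#'   the one-sided adaptive test (treated lower) rejects at `alpha`, which
#'   keeps the null rejection rate at `alpha`. `"two.sided.directional"`:
#'   two-sided test at `alpha` plus a lower-treated-central-value check
#'   (null rate about `alpha/2`).
#' @param bonferroni Divide `alpha` by the number of testable strata in each
#'   round (off by default: the any-stratum rule is applied literally, with
#'   its documented familywise inflation).
#' @param rescue_convention `"remaining"` (default; treated loss =
#'   `rescue_ratio * loss`) or `"rescued"` (treated loss =
#'   `(1 - rescue_ratio) * loss`), flipping the effect-size direction.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(m_per_arm, rescue_ratio, alpha = 0.05,
                         scheme = NULL, biomarker = c("none", "ideal", "gcc",
                                                      "surrogate"),
                         surrogate_r2 = NA_real_, reps = 10000L, seed = 1L,
                         replace = FALSE,
                         decision_rule = c("one.sided",
                                           "two.sided.directional"),
                         rescue_convention = c("remaining", "rescued"),
                         bonferroni = FALSE) {
  biomarker <- match.arg(biomarker)
  decision_rule <- match.arg(decision_rule)
  rescue_convention <- match.arg(rescue_convention)
  if (m_per_arm < 2) stop("m_per_arm must be >= 2")
  if (rescue_ratio <= 0 || rescue_ratio > 1)
    stop("rescue_ratio must lie in (0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (reps < 1) stop("reps must be >= 1")
  if (biomarker == "surrogate" &&
      (!is.finite(surrogate_r2) || surrogate_r2 <= 0 || surrogate_r2 > 1))
    stop("surrogate biomarker requires surrogate_r2 in (0, 1]")
  if (!is.null(scheme)) stopifnot(inherits(scheme, "stratum_scheme"))
  structure(
    list(m_per_arm = as.integer(m_per_arm), rescue_ratio = rescue_ratio,
         alpha = alpha, scheme = scheme, biomarker = biomarker,
         surrogate_r2 = surrogate_r2, reps = as.integer(reps),
         seed = as.integer(seed), replace = replace,
         decision_rule = decision_rule,
         rescue_convention = rescue_convention,
         bonferroni = isTRUE(bonferroni)),
    class = "trial_design")
}

# Two-sample decision without the public length guard (strata can have as
# few as 2 per arm; the rank-sum test then simply cannot reach significance).
two_sample_decision <- function(treat, ctrl, alpha, decision_rule) {
  if (decision_rule == "one.sided") {
    res <- tryCatch(
      adaptive_two_sample_test_unsafe(treat, ctrl, alpha, "less"),
      error = function(e) list(p_value = 1, significant = FALSE))
    res$significant
  } else {
    res <- tryCatch(
      adaptive_two_sample_test_unsafe(treat, ctrl, alpha, "two.sided"),
      error = function(e) list(p_value = 1, significant = FALSE))
    res$significant && (central_value(treat) < central_value(ctrl))
  }
}

central_value <- function(x) {
  if (is_normalish(x)) mean(x) else stats::median(x)
}

adaptive_two_sample_test_unsafe <- function(a, b, alpha, alternative) {
  both_normal <- is_normalish(a) && is_normalish(b)
  if (both_normal) {
    p <- stats::t.test(a, b, var.equal = TRUE,
                       alternative = alternative)$p.value
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = alternative)$p.value)
  }
  if (is.na(p)) p <- 1
  list(p_value = p, significant = p < alpha)
}

# Stratum boundaries live on the GCC-loss scale; when the stratification
# biomarker is on the RGC-loss scale (ideal or surrogate) they are mapped
# through the calibration point line so severity bands stay comparable.
biomarker_boundaries <- function(design, model) {
  sch <- design$scheme
  if (is.null(sch)) return(stratum_scheme(numeric(0), "all"))
  if (design$biomarker %in% c("ideal", "surrogate") && length(sch$boundaries))
    stratum_scheme(model$slope * sch$boundaries + model$intercept, sch$labels)
  else sch
}

#' Run one simulated trial
#'
#' Draws `2 * m_per_arm` patients from the GCC-loss pool (without
#' replacement by default), converts each GCC loss to an RGC somata loss
#' sample under calibration uncertainty via [predict_rgc_loss()], multiplies
#' treated-arm losses by the rescue ratio, and tests treated vs control
#' with the normality-adaptive two-sample test. In a stratified design,
#' patients of both arms are first grouped by the biomarker value under the
#' stratification scheme; each stratum with at least 2 patients per arm is
#' tested, and the trial is effective if any stratum shows the treated arm
#' significantly lower. Consumes the current RNG stream (callers seed it).
#'
#' @param pool Numeric vector of GCC loss percentages.
#' @param design A `trial_design`.
#' @param model A `calibration_model`.
#' @return A list with `effective` (logical), `stratum_significant` (named
#'   logical per stratum label), `stratum_tested` (named logical), and
#'   `n_per_stratum` (patients per stratum across both arms).
#' @export
run_trial <- function(pool, design, model = ton_calibration()) {
  m <- design$m_per_arm
  if (!design$replace && length(pool) < 2 * m)
    stop("pool exhausted: need at least 2*m patients for disjoint arms")
  idx <- if (design$replace) sample.int(length(pool), 2 * m, replace = TRUE)
         else sample.int(length(pool), 2 * m)
  gcc <- pool[idx]
  rgc <- predict_rgc_loss(model, gcc)
  biom <- switch(design$biomarker,
                 none = NULL,
                 gcc = gcc,
                 ideal = rgc,
                 surrogate = make_surrogate_biomarker(rgc,
                                                      design$surrogate_r2))
  treat_i <- seq_len(m); ctrl_i <- m + seq_len(m)
  obs <- rgc
  obs[treat_i] <- if (design$rescue_convention == "remaining")
    design$rescue_ratio * rgc[treat_i] else
    (1 - design$rescue_ratio) * rgc[treat_i]

  sch <- biomarker_boundaries(design, model)
  strata <- if (is.null(biom)) factor(rep(sch$labels[1], 2 * m),
                                      levels = sch$labels)
            else assign_strata(biom, sch)
  labs <- levels(strata)
  sig <- stats::setNames(rep(FALSE, length(labs)), labs)
  tested <- stats::setNames(rep(FALSE, length(labs)), labs)
  nstr <- stats::setNames(integer(length(labs)), labs)
  arm_t <- split(treat_i, strata[treat_i])
  arm_c <- split(ctrl_i, strata[ctrl_i])
  testable <- vapply(labs, function(l) length(arm_t[[l]]) >= 2 &&
                       length(arm_c[[l]]) >= 2, logical(1))
  alpha_use <- if (isTRUE(design$bonferroni) && any(testable))
    design$alpha / sum(testable) else design$alpha
  for (lab in labs) {
    in_t <- arm_t[[lab]]; in_c <- arm_c[[lab]]
    nstr[lab] <- length(in_t) + length(in_c)
    if (testable[[lab]]) {
      tested[lab] <- TRUE
      sig[lab] <- two_sample_decision(obs[in_t], obs[in_c],
                                      alpha_use, design$decision_rule)
    }
  }
  list(effective = any(sig), stratum_significant = sig,
       stratum_tested = tested, n_per_stratum = nstr)
}

#' Estimate trial power by Monte Carlo
#'
#' Repeats [run_trial()] `design$reps` times and reports the proportion of
#' effective rounds together with its binomial Monte-Carlo standard error
#' `sqrt(p (1 - p) / reps)`. A master seed deterministically spawns one
#' substream per repetition, so estimates are reproducible and repetitions
#' are order-independent.
#'
#' @param pool Numeric vector of GCC loss percentages.
#' @param design A `trial_design`.
#' @param model A `calibration_model`.
#' @return An object of class `power_estimate`: a list with `power`,
#'   `mc_se`, `reps`, `per_stratum` (per-label rejection proportions over
#'   all repetitions), `per_stratum_tested` (proportion of repetitions in
#'   which the label was testable), and `design`.
#' @export
estimate_power <- function(pool, design, model = ton_calibration()) {
  stopifnot(inherits(design, "trial_design"))
  reps <- design$reps
  set.seed(design$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps, replace = TRUE)
  sch <- biomarker_boundaries(design, model)
  labs <- sch$labels
  eff <- logical(reps)
  sig_count <- stats::setNames(numeric(length(labs)), labs)
  test_count <- stats::setNames(numeric(length(labs)), labs)
  for (i in seq_len(reps)) {
    set.seed(rep_seeds[i])
    tr <- run_trial(pool, design, model)
    eff[i] <- tr$effective
    sig_count <- sig_count + tr$stratum_significant
    test_count <- test_count + tr$stratum_tested
  }
  p <- mean(eff)
  structure(
    list(power = p, mc_se = sqrt(p * (1 - p) / reps), reps = reps,
         per_stratum = sig_count / reps,
         per_stratum_tested = test_count / reps,
         effective_flags = eff, design = design),
    class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  d <- x$design
  cat(sprintf(
    "Estimated power %.4f (MC SE %.4f, %d reps) | m = %d, rescue = %.2f, biomarker = %s\n",
    x$power, x$mc_se, x$reps, d$m_per_arm, d$rescue_ratio, d$biomarker))
  if (length(x$per_stratum) > 1) {
    cat("  per-stratum rejection:",
        paste(sprintf("%s %.3f", names(x$per_stratum), x$per_stratum),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Estimate power of a biomarker-stratified trial
#'
#' Same engine as [estimate_power()] but requires a stratification scheme
#' and biomarker; a round is effective if any stratum with at least two
#' patients per arm shows the treated arm significantly lower (no
#' multiplicity correction across strata, so the null rejection rate is
#' inflated to roughly `1 - (1 - alpha)^k` for `k` occupied strata).
#' A degenerate single-stratum scheme collapses to the unstratified
#' estimate under the same seed.
#'
#' @inheritParams estimate_power
#' @return A `power_estimate`.
#' @export
estimate_power_stratified <- function(pool, design, model = ton_calibration()) {
  if (is.null(design$scheme))
    stop("stratified estimation requires a stratum scheme")
  if (design$biomarker == "none")
    stop("stratified estimation requires a biomarker")
  estimate_power(pool, design, model)
}

#' Minimal per-arm sample size reaching a target power
#'
#' Walks an ascending grid of per-arm sizes, estimating power at each, and
#' returns the smallest size whose estimated power reaches the target.
#' The same master seed is used at every grid point.
#'
#' @param pool Numeric vector of GCC loss percentages.
#' @param design_template A `trial_design`; its `m_per_arm` is overridden.
#' @param model A `calibration_model`.
#' @param target_power Target power in [0, 1], default 0.6.
#' @param m_grid Ascending integer grid, default `seq(20, 90, by = 10)`.
#' @return A list with `m` (smallest adequate size, or `NA` if the target
#'   is not reached on the grid), `reached` (logical), and `powers`
#'   (data.frame of the grid points actually evaluated).
#' @export
minimal_sample_size <- function(pool, design_template,
                                model = ton_calibration(),
                                target_power = 0.6,
                                m_grid = seq(20L, 90L, by = 10L)) {
  if (!length(m_grid)) stop("m_grid must be non-empty")
  if (is.unsorted(m_grid, strictly = TRUE))
    stop("m_grid must be strictly ascending")
  rows <- list()
  found <- NA_integer_
  for (m in m_grid) {
    d <- design_template
    d$m_per_arm <- as.integer(m)
    est <- estimate_power(pool, d, model)
    rows[[length(rows) + 1L]] <-
      data.frame(m = m, power = est$power, mc_se = est$mc_se)
    if (est$power >= target_power) { found <- as.integer(m); break }
  }
  list(m = found, reached = !is.na(found), powers = do.call(rbind, rows))
}

#' Power surface over sample size, effect size and biomarker scenario
#'
#' Full factorial Monte-Carlo evaluation over per-arm sizes, rescue ratios
#' and biomarker scenarios. Scenario strings are `"none"`, `"ideal"`,
#' `"gcc"`, or `"surrogate:R2"` (e.g. `"surrogate:0.4"`). Cell seeds are
#' derived deterministically from the master seed.
#'
#' @param pool Numeric vector of GCC loss percentages.
#' @param model A `calibration_model`.
#' @param m_grid,rescue_grid Non-empty numeric grids.
#' @param scenarios Character vector of scenario strings.
#' @param scheme `stratum_scheme` used by stratified scenarios.
#' @param alpha Significance level.
#' @param reps Repetitions per cell.
#' @param seed Master seed.
#' @return A data.frame with one row per cell: `scenario`, `m`,
#'   `rescue_ratio`, `power`, `mc_se`, `reps`, `seed`, and one
#'   `reject_<label>` column per stratum label.
#' @export
power_surface <- function(pool, model = ton_calibration(),
                          m_grid = seq(20L, 90L, by = 10L),
                          rescue_grid = seq(0.1, 0.9, by = 0.2),
                          scenarios = c("none", "gcc"),
                          scheme = stratum_scheme(),
                          alpha = 0.05, reps = 10000L, seed = 1L) {
  if (!length(m_grid) || !length(rescue_grid) || !length(scenarios))
    stop("grids must be non-empty")
  grid <- expand.grid(scenario = scenarios, m = m_grid,
                      rescue_ratio = rescue_grid,
                      stringsAsFactors = FALSE)
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid),
                           replace = TRUE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sc <- parse_scenario(grid$scenario[i])
    d <- trial_design(
      m_per_arm = grid$m[i], rescue_ratio = grid$rescue_ratio[i],
      alpha = alpha,
      scheme = if (sc$biomarker == "none") NULL else scheme,
      biomarker = sc$biomarker, surrogate_r2 = sc$r2,
      reps = reps, seed = cell_seeds[i])
    est <- estimate_power(pool, d, model)
    row <- data.frame(scenario = grid$scenario[i], m = grid$m[i],
                      rescue_ratio = grid$rescue_ratio[i],
                      power = est$power, mc_se = est$mc_se,
                      reps = reps, seed = cell_seeds[i])
    for (lab in scheme$labels)
      row[[paste0("reject_", lab)]] <-
        if (lab %in% names(est$per_stratum)) est$per_stratum[[lab]]
        else NA_real_
    out[[i]] <- row
  }
  do.call(rbind, out)
}

parse_scenario <- function(s) {
  if (grepl("^surrogate:", s)) {
    r2 <- as.numeric(sub("^surrogate:", "", s))
    if (!is.finite(r2)) stop("bad surrogate scenario: ", s)
    list(biomarker = "surrogate", r2 = r2)
  } else {
    if (!s %in% c("none", "ideal", "gcc")) stop("unknown scenario: ", s)
    list(biomarker = s, r2 = NA_real_)
  }
}
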