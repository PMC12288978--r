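#' Visual-acuity scale with qualitative-level codes
#'
#' Maps the qualitative acuity levels — no light perception (NLP), light
#' perception (LP), hand motion (HM), finger counting (FC) — to numeric
#' values on a negative log-acuity scale where higher is better and
#' measurable acuities sit above the qualitative band. The default codes
#' (NLP −2.9, LP −2.6, HM −2.3, FC −1.85) respect the required ordering
#' NLP < LP < HM < FC < measurable and are fully user-configurable, since
#' no standard numeric coding of these levels exists.
#'
#' @param codes Named numeric vector with entries `NLP`, `LP`, `HM`, `FC`,
#'   strictly increasing in that order.
#' @return An object of class `va_scale`.
#' @export
va_scale <- function(codes = c(NLP = -2.9, LP = -2.6, HM = -2.3,
                               FC = -1.85)) {
  need <- c("NLP", "LP", "HM", "FC")
  if (!all(need %in% names(codes)))
    stop("codes must name NLP, LP, HM and FC")
  codes <- codes[need]
  if (any(diff(codes) <= 0))
    stop("codes must be strictly increasing NLP < LP < HM < FC")
  structure(list(codes = codes, higher_better = TRUE), class = "va_scale")
}

#' Convert visual-acuity tokens to numeric log-acuity values
#'
#' Numeric strings pass through; qualitative tokens are mapped via the
#' scale. Unmappable tokens raise an error naming the offending values.
#'
#' @param x Character or numeric vector of acuities.
#' @param scale A `va_scale`.
#' @return Numeric vector.
#' @export
va_to_numeric <- function(x, scale = va_scale()) {
  stopifnot(inherits(scale, "va_scale"))
  if (is.numeric(x)) return(x)
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  tok <- is.na(out) & !is.na(x) & x != ""
  if (any(tok)) {
    known <- x[tok] %in% names(scale$codes)
    if (!all(known))
      stop("unmapped visual-acuity token(s): ",
           paste(unique(x[tok][!known]), collapse = ", "))
    out[tok] <- scale$codes[x[tok]]
  }
  out
}

# Baseline-VA categories used for the alternative stratification:
# {NLP or LP}, {HM up to -1.4}, {better than -1.4}.
va_category <- function(x, scale = va_scale(), cut = -1.4) {
  raw <- as.character(x)
  num <- va_to_numeric(x, scale)
  labs <- c("NLP/LP", "HM to -1.4", "> -1.4")
  cat <- ifelse(raw %in% c("NLP", "LP"), labs[1],
                ifelse(num <= cut, labs[2], labs[3]))
  factor(cat, levels = labs)
}

#' Stratify a treated cohort by baseline GCC loss or baseline VA
#'
#' GCC stratification uses the same boundary rules as the trial engine
#' (mild < 10, moderate 10–20 inclusive, severe > 20 by default); VA
#' stratification uses the categories NLP/LP, HM to −1.4, and better than
#' −1.4 on the log-acuity scale. The partition is exhaustive and disjoint.
#'
#' @param cohort Data.frame with `gcc_loss_pct` and/or `va_log_pre`.
#' @param by `"gcc"` or `"va"`.
#' @param scheme `stratum_scheme` for GCC stratification.
#' @param scale `va_scale` for mapping qualitative acuity tokens.
#' @return Named list of sub-cohorts (possibly empty data.frames), one per
#'   stratum label, whose row counts sum to `nrow(cohort)`.
#' @export
stratify_records <- function(cohort, by = c("gcc", "va"),
                             scheme = stratum_scheme(),
                             scale = va_scale()) {
  by <- match.arg(by)
  if (by == "gcc") {
    if (!"gcc_loss_pct" %in% names(cohort))
      stop("cohort lacks gcc_loss_pct")
    if (any(!is.finite(cohort$gcc_loss_pct)))
      stop("gcc_loss_pct must be finite for every patient")
    f <- assign_strata(cohort$gcc_loss_pct, scheme)
  } else {
    if (!"va_log_pre" %in% names(cohort))
      stop("cohort lacks va_log_pre")
    f <- va_category(cohort$va_log_pre, scale)
  }
  out <- lapply(levels(f), function(lab) cohort[f == lab, , drop = FALSE])
  stats::setNames(out, levels(f))
}

#' Pre/post outcome analysis of one (sub)cohort
#'
#' Paired two-sided comparison of baseline vs post-treatment outcome using
#' the normality-adaptive paired test. Strata with fewer than 3 patients
#' are reported descriptively (mean change, no p-value). For VA and VFI
#' higher is better; for MD (negative dB) higher is also better, so a
#' positive mean change always means improvement.
#'
#' @param cohort Data.frame with paired outcome columns (`va_log_pre` /
#'   `va_log_post` for VA; `param_vfi_base` / `param_vfi_follow` for VFI;
#'   `param_md_base` / `param_md_follow` for MD).
#' @param outcome `"va"`, `"vfi"` or `"md"`.
#' @param alpha Significance level.
#' @param scale `va_scale` for qualitative acuity tokens.
#' @return List with `n`, `mean_change`, `p_value` (NA when n < 3),
#'   `test_used`, `significant`, `improved` (mean change > 0).
#' @export
pre_post_analysis <- function(cohort, outcome = c("va", "vfi", "md"),
                              alpha = 0.05, scale = va_scale()) {
  outcome <- match.arg(outcome)
  cols <- switch(outcome,
                 va = c("va_log_pre", "va_log_post"),
                 vfi = c("param_vfi_base", "param_vfi_follow"),
                 md = c("param_md_base", "param_md_follow"))
  if (!all(cols %in% names(cohort)))
    stop("cohort lacks columns for outcome '", outcome, "'")
  pre <- va_to_numeric(cohort[[cols[1]]], scale)
  post <- va_to_numeric(cohort[[cols[2]]], scale)
  keep <- is.finite(pre) & is.finite(post)
  pre <- pre[keep]; post <- post[keep]
  n <- length(pre)
  if (n < 3) {
    return(list(n = n, mean_change = if (n) mean(post - pre) else NA_real_,
                p_value = NA_real_, test_used = "none (n < 3)",
                significant = FALSE,
                improved = if (n) mean(post - pre) > 0 else NA))
  }
  res <- adaptive_paired_test(pre, post, alpha, alternative = "two.sided")
  list(n = n, mean_change = res$mean_change, p_value = res$p_value,
       test_used = res$test_used, significant = res$significant,
       improved = res$mean_change > 0)
}

#' Per-stratum pre/post outcome table
#'
#' Stratifies a treated cohort and runs [pre_post_analysis()] in each
#' stratum and in the pooled cohort.
#'
#' @inheritParams stratify_records
#' @inheritParams pre_post_analysis
#' @return Data.frame with one row per stratum plus an `all` row: columns
#'   `stratum`, `n`, `mean_change`, `p_value`, `test_used`, `significant`.
#' @export
stratified_outcome_table <- function(cohort, by = c("gcc", "va"),
                                     outcome = c("va", "vfi", "md"),
                                     scheme = stratum_scheme(),
                                     alpha = 0.05, scale = va_scale()) {
  by <- match.arg(by); outcome <- match.arg(outcome)
  strata <- stratify_records(cohort, by, scheme, scale)
  strata[["all"]] <- cohort
  rows <- lapply(names(strata), function(lab) {
    r <- pre_post_analysis(strata[[lab]], outcome, alpha, scale)
    data.frame(stratum = lab, n = r$n, mean_change = r$mean_change,
               p_value = r$p_value, test_used = r$test_used,
               significant = r$significant)
  })
  do.call(rbind, rows)
}
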