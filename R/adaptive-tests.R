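# Shapiro-Wilk normality gate at fixed level 0.05. Degenerate samples
# (constant, or outside shapiro.test's n range) are treated as non-normal so
# the rank-based branch is taken.
is_normalish <- function(x, level = 0.05) {
  if (length(x) < 3 || length(x) > 5000) return(FALSE)
  if (stats::sd(x) == 0) return(FALSE)
  p <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  p >= level
}

#' Normality-adaptive unpaired two-sample test
#'
#' Applies a Shapiro-Wilk normality check (level 0.05) to each sample; if
#' both pass, an unpaired two-sample t test (pooled variance) is used,
#' otherwise the Wilcoxon rank-sum test. The default alternative is
#' two-sided; the trial engine uses `alternative = "less"` for its
#' directional effectiveness rule.
#'
#' @param a,b Numeric samples, each of length >= 3.
#' @param alpha Significance level for the `significant` flag.
#' @param alternative One of `"two.sided"`, `"less"`, `"greater"`
#'   (direction refers to `a` relative to `b`).
#' @return A list with `p_value`, `test_used` (`"t"` or `"wilcoxon"`), and
#'   `significant` (`p_value < alpha`).
#' @export
adaptive_two_sample_test <- function(a, b, alpha = 0.05,
                                     alternative = "two.sided") {
  if (length(a) < 3 || length(b) < 3)
    stop("each sample must have at least 3 observations")
  both_normal <- is_normalish(a) && is_normalish(b)
  if (both_normal) {
    p <- tryCatch(
      stats::t.test(a, b, var.equal = TRUE, alternative = alternative)$p.value,
      error = function(e) 1)
    used <- "t"
  } else {
    p <- tryCatch(
      suppressWarnings(
        stats::wilcox.test(a, b, alternative = alternative)$p.value),
      error = function(e) 1)
    used <- "wilcoxon"
  }
  if (is.na(p)) p <- 1
  list(p_value = p, test_used = used, significant = p < alpha)
}

# cache of sign-flip matrices for the exact tie-aware signed-rank test
.signflip_cache <- new.env(parent = emptyenv())

signflip_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.signflip_cache[[key]])) return(.signflip_cache[[key]])
  m <- matrix(0L, nrow = 2^n, ncol = n)
  for (j in seq_len(n)) m[, j] <- rep(rep(0:1, each = 2^(j - 1)), length.out = 2^n)
  .signflip_cache[[key]] <- m
  m
}

# Exact Wilcoxon signed-rank p-value by enumeration over all 2^n sign
# assignments, using midranks so tied |differences| are handled exactly.
# Zeros are dropped (standard practice). Used when ties/zeros make
# stats::wilcox.test fall back to a normal approximation and n is small.
exact_signed_rank <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  flips <- signflip_matrix(n)
  v_all <- as.vector(flips %*% r)
  switch(alternative,
         two.sided = {
           ev <- sum(r) / 2
           mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-12)
         },
         less = mean(v_all <= v_obs + 1e-12),
         greater = mean(v_all >= v_obs - 1e-12))
}

#' Normality-adaptive paired test
#'
#' Tests paired pre/post samples via their differences `post - pre`.
#' Normality of the differences is assessed by Shapiro-Wilk (level 0.05);
#' normal differences get a paired t test, non-normal ones the Wilcoxon
#' signed-rank test. When ties or zeros would force the signed-rank test
#' into a normal approximation and n <= 14, an exact tie-aware enumeration
#' over all sign assignments is used instead. All-zero differences return
#' p = 1 rather than an error.
#'
#' @param pre,post Numeric paired samples of equal length >= 3.
#' @param alpha Significance level for the `significant` flag.
#' @param alternative Direction of `post` relative to `pre`:
#'   `"two.sided"` (default), `"less"` (post lower), `"greater"`.
#' @return A list with `p_value`, `test_used` (`"paired t"` or
#'   `"signed-rank"`), `significant`, and `mean_change` (mean of post - pre).
#' @export
adaptive_paired_test <- function(pre, post, alpha = 0.05,
                                 alternative = "two.sided") {
  if (length(pre) != length(post)) stop("pre and post must be paired")
  if (length(pre) < 3) stop("need at least 3 pairs")
  d <- post - pre
  if (all(d == 0))
    return(list(p_value = 1, test_used = "signed-rank",
                significant = FALSE, mean_change = 0))
  if (is_normalish(d)) {
    p <- stats::t.test(d, alternative = alternative)$p.value
    used <- "paired t"
  } else {
    nz <- d[d != 0]
    has_ties <- any(duplicated(abs(nz))) || any(d == 0)
    if (has_ties && length(nz) <= 14 && length(nz) > 0) {
      p <- exact_signed_rank(d, alternative)
    } else {
      p <- tryCatch(
        suppressWarnings(
          stats::wilcox.test(d, alternative = alternative)$p.value),
        error = function(e) 1)
    }
    used <- "signed-rank"
  }
  if (is.na(p)) p <- 1
  list(p_value = p, test_used = used, significant = p < alpha,
       mean_change = mean(d))
}
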