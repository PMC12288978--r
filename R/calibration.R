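#' Paired-eye thickness loss percentage
#'
#' Computes the percentage loss of a retinal layer thickness in the injured
#' eye relative to the contralateral (healthy) eye:
#' \deqn{loss\% = 100 (T_c - T_i) / T_c}
#' where \eqn{T_c} is the contralateral thickness and \eqn{T_i} the injured
#' thickness, both in micrometres. Negative values indicate thickening of the
#' injured eye (e.g., transient post-traumatic edema) and are permitted; the
#' result can never exceed 100 for a non-negative injured thickness.
#'
#' @param contralateral Thickness of the contralateral healthy eye (µm), > 0.
#' @param injured Thickness of the injured eye (µm), >= 0.
#' @return Numeric vector of loss percentages on the 0–100 scale.
#' @examples
#' loss_percent(100, 80)  # 20
#' loss_percent(100, 110) # -10 (thickening)
#' @export
loss_percent <- function(contralateral, injured) {
  if (any(!is.finite(contralateral)) || any(!is.finite(injured)))
    stop("thickness values must be finite")
  if (any(contralateral <= 0))
    stop("contralateral thickness must be positive")
  if (any(injured < 0))
    stop("injured thickness must be non-negative")
  100 * (contralateral - injured) / contralateral
}

#' Construct a calibration model linking GCC loss to RGC somata loss
#'
#' A linear calibration \eqn{\hat{Y} = a x + b} mapping GCC thickness loss
#' percentage (x) to retinal ganglion cell somata loss percentage, with 95%
#' confidence intervals on both coefficients, a residual scale and an R².
#' The coefficient intervals drive uncertainty propagation in
#' [predict_rgc_loss()].
#'
#' @param slope Slope (RGC-loss percentage points per GCC-loss point).
#' @param intercept Intercept (percentage points).
#' @param slope_ci Length-2 numeric, 95% CI for the slope (must contain it).
#' @param intercept_ci Length-2 numeric, 95% CI for the intercept.
#' @param sigma Residual standard error (percentage points), >= 0.
#' @param r2 Coefficient of determination in [0, 1].
#' @param n_fit Number of observations the model was fitted on.
#' @return An object of class `calibration_model`.
#' @seealso [ton_calibration()] for the packaged large-animal model,
#'   [fit_calibration()] to fit from data.
#' @export
calibration_model <- function(slope, intercept,
                              slope_ci = c(slope, slope),
                              intercept_ci = c(intercept, intercept),
                              sigma = 0, r2 = 1, n_fit = NA_integer_) {
  stopifnot(is.numeric(slope), is.numeric(intercept),
            length(slope_ci) == 2, length(intercept_ci) == 2)
  slope_ci <- sort(as.numeric(slope_ci))
  intercept_ci <- sort(as.numeric(intercept_ci))
  if (slope < slope_ci[1] || slope > slope_ci[2])
    stop("slope_ci must contain the slope estimate")
  if (intercept < intercept_ci[1] || intercept > intercept_ci[2])
    stop("intercept_ci must contain the intercept estimate")
  if (!is.na(sigma) && sigma < 0) stop("sigma must be >= 0")
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) stop("r2 must lie in [0, 1]")
  structure(
    list(slope = as.numeric(slope), intercept = as.numeric(intercept),
         slope_ci = slope_ci, intercept_ci = intercept_ci,
         sigma = as.numeric(sigma), r2 = as.numeric(r2),
         n_fit = as.integer(n_fit)),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Linear calibration: RGC somata loss % =",
      format(x$slope, digits = 4), "x GCC loss % ",
      ifelse(x$intercept < 0, "-", "+"), format(abs(x$intercept), digits = 4),
      "\n")
  cat(sprintf("  95%% CI slope [%.3f, %.3f], intercept [%.3f, %.3f]\n",
              x$slope_ci[1], x$slope_ci[2],
              x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("  sigma = %.3f, R^2 = %.3f, n = %s\n",
              x$sigma, x$r2, x$n_fit))
  invisible(x)
}

#' The packaged traumatic-optic-neuropathy calibration model
#'
#' The default conversion from GCC thickness loss percentage to RGC somata
#' loss percentage, derived from a large-animal (goat) optic-canal crush
#' model: slope 2.697 (95% CI 2.130–3.265), intercept −2.445 (95% CI −11.00
#' to 6.110), R² = 0.87. The same model ships as JSON in
#' `inst/extdata/ton_calibration.json`.
#'
#' @return A `calibration_model`.
#' @export
ton_calibration <- function() {
  calibration_model(slope = 2.697, intercept = -2.445,
                    slope_ci = c(2.130, 3.265),
                    intercept_ci = c(-11.00, 6.110),
                    sigma = NA_real_, r2 = 0.87, n_fit = NA_integer_)
}

#' Fit the GCC-to-RGC calibration by ordinary least squares
#'
#' Simple linear regression of RGC somata loss percentage on GCC thickness
#' loss percentage. Returns the coefficient estimates with their 95%
#' confidence intervals, the residual standard error and R², packaged as a
#' `calibration_model`.
#'
#' @param gcc_loss Numeric vector of GCC thickness loss percentages.
#' @param rgc_loss Numeric vector of RGC somata loss percentages, same length.
#' @return A `calibration_model`.
#' @export
fit_calibration <- function(gcc_loss, rgc_loss) {
  if (length(gcc_loss) != length(rgc_loss))
    stop("gcc_loss and rgc_loss must have the same length")
  if (length(gcc_loss) < 3) stop("need at least 3 observations")
  if (stats::sd(gcc_loss) == 0)
    stop("degenerate design: gcc_loss is constant")
  fit <- stats::lm(rgc_loss ~ gcc_loss)
  # noiseless inputs trigger a harmless "perfect fit" warning in summary()
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  co <- stats::coef(fit)
  # noiseless data leave confint degenerate-narrow; clamp to contain estimates
  slope_ci <- range(c(ci["gcc_loss", ], co[["gcc_loss"]]))
  int_ci <- range(c(ci["(Intercept)", ], co[["(Intercept)"]]))
  calibration_model(
    slope = co[["gcc_loss"]], intercept = co[["(Intercept)"]],
    slope_ci = slope_ci, intercept_ci = int_ci,
    sigma = sm$sigma, r2 = sm$r.squared, n_fit = length(gcc_loss))
}

# Envelope of predictions over the 4 corner combinations of the coefficient
# CIs, evaluated at x. Returns a list(lo, hi) of vectors aligned with x.
prediction_envelope <- function(model, x) {
  corners <- expand.grid(s = model$slope_ci, i = model$intercept_ci)
  preds <- vapply(seq_len(nrow(corners)),
                  function(k) corners$s[k] * x + corners$i[k],
                  numeric(length(x)))
  preds <- matrix(preds, nrow = length(x))
  list(lo = apply(preds, 1, min), hi = apply(preds, 1, max))
}

#' Sample RGC somata loss predictions under calibration uncertainty
#'
#' For each GCC loss percentage the point prediction is
#' \eqn{\hat{Y} = a x + b}. Because the calibration is uncertain
#' (R² < 1), each \eqn{\hat{Y}} is surrounded by a range determined by the
#' 95% confidence intervals of slope and intercept: the envelope is the
#' min/max over the four corner combinations of the coefficient CI limits
#' evaluated at x. A draw is taken from a normal density centred at
#' \eqn{\hat{Y}} with scale \eqn{\sigma = (Y_{hi} - Y_{lo}) / (2 \times 1.96)}
#' (so 95% of the untruncated mass falls inside the envelope), truncated to
#' the envelope by inverse-CDF sampling, then clamped to the biologically
#' meaningful range [0, 100]. With degenerate (point) CIs the envelope has
#' zero width and the point prediction is returned deterministically.
#'
#' `method = "coefficients"` instead draws a (slope, intercept) pair per
#' call from independent normals whose 95% intervals match the coefficient
#' CIs, for sensitivity analysis against the envelope reading.
#'
#' @param model A `calibration_model`.
#' @param gcc_loss Numeric vector of GCC thickness loss percentages.
#' @param method `"envelope"` (default) or `"coefficients"`.
#' @return Numeric vector of sampled RGC somata loss percentages in [0, 100].
#' @export
predict_rgc_loss <- function(model, gcc_loss, method = c("envelope", "coefficients")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "calibration_model"))
  yhat <- model$slope * gcc_loss + model$intercept
  if (method == "coefficients") {
    sd_s <- diff(model$slope_ci) / (2 * 1.96)
    sd_i <- diff(model$intercept_ci) / (2 * 1.96)
    a <- stats::rnorm(length(gcc_loss), model$slope, sd_s)
    b <- stats::rnorm(length(gcc_loss), model$intercept, sd_i)
    return(pmin(pmax(a * gcc_loss + b, 0), 100))
  }
  env <- prediction_envelope(model, gcc_loss)
  sig <- (env$hi - env$lo) / (2 * 1.96)
  y <- yhat
  pos <- sig > 0
  if (any(pos)) {
    plo <- stats::pnorm(env$lo[pos], yhat[pos], sig[pos])
    phi <- stats::pnorm(env$hi[pos], yhat[pos], sig[pos])
    u <- stats::runif(sum(pos))
    y[pos] <- stats::qnorm(plo + u * (phi - plo), yhat[pos], sig[pos])
  }
  pmin(pmax(y, 0), 100)
}

#' Construct a surrogate biomarker with a target correlation strength
#'
#' Adds Gaussian noise to a vector of (latent) RGC somata loss values so the
#' population squared correlation between the surrogate and the input equals
#' `target_r2`. The noise variance is solved from the identity
#' \eqn{\sigma^2_{noise} = \sigma^2_{signal} (1 - R^2) / R^2}. With
#' `target_r2 = 1` the input is returned unchanged. This emulates imperfect
#' stratification biomarkers (e.g., time since injury, which correlates only
#' weakly with neurodegeneration).
#'
#' @param rgc_losses Numeric vector of RGC somata loss percentages, length >= 2.
#' @param target_r2 Target squared correlation in (0, 1].
#' @return Numeric vector, same length as input.
#' @export
make_surrogate_biomarker <- function(rgc_losses, target_r2) {
  if (!is.numeric(target_r2) || length(target_r2) != 1 ||
      target_r2 <= 0 || target_r2 > 1)
    stop("target_r2 must lie in (0, 1]")
  if (length(rgc_losses) < 2) stop("need at least 2 values")
  if (target_r2 == 1) return(rgc_losses)
  v_sig <- stats::var(rgc_losses)
  v_noise <- v_sig * (1 - target_r2) / target_r2
  rgc_losses + stats::rnorm(length(rgc_losses), 0, sqrt(v_noise))
}

#' Write / read a calibration model as JSON
#'
#' @param model A `calibration_model`.
#' @param path File path.
#' @return `read_calibration_json` returns a `calibration_model`;
#'   `write_calibration_json` returns `path` invisibly.
#' @export
write_calibration_json <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(
    slope = x$slope, intercept = x$intercept,
    slope_ci = as.numeric(x$slope_ci),
    intercept_ci = as.numeric(x$intercept_ci),
    sigma = if (is.null(x$sigma)) NA_real_ else x$sigma,
    r2 = if (is.null(x$r2)) NA_real_ else x$r2,
    n_fit = if (is.null(x$n_fit)) NA_integer_ else x$n_fit)
}
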