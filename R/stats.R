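#' Calibration regression of automatic against manual counts
#'
#' Ordinary least squares of the automatic estimate on the manual reference
#' count, the standard way of validating an automatic counter: estimated =
#' a + b * manual. A slope near 1 and intercept near 0 with high R-squared
#' means the two methods agree across the density range.
#'
#' @param pairs data frame with numeric columns `manual` and `estimated`
#'   (extra columns are ignored); at least 3 rows, manual counts not all
#'   identical.
#' @return a `calibration_fit`: `intercept`, `slope`, `r_squared`, `p_value`
#'   (two-sided test of slope = 0 on n - 2 df), `n`, and the underlying
#'   [stats::lm] fit in `$model`.
#' @examples
#' fit_calibration(data.frame(manual = 0:2, estimated = c(1, 3, 5)))
#' @export
fit_calibration <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (!all(c("manual", "estimated") %in% names(pairs))) {
    stop_ovocount("`pairs` needs columns `manual` and `estimated`",
                  "ovocount_parameter_error")
  }
  if (nrow(pairs) < 3L) {
    stop_ovocount("calibration needs at least 3 (manual, estimated) pairs",
                  "ovocount_statistics_error")
  }
  if (stats::var(pairs$manual) == 0) {
    stop_ovocount("manual counts are all identical; the slope is undefined",
                  "ovocount_statistics_error")
  }
  fit <- stats::lm(estimated ~ manual, data = pairs)
  coefs <- summary(fit)$coefficients
  structure(list(intercept = unname(coefs["(Intercept)", "Estimate"]),
                 slope = unname(coefs["manual", "Estimate"]),
                 r_squared = summary(fit)$r.squared,
                 p_value = unname(coefs["manual", "Pr(>|t|)"]),
                 n = nrow(pairs), model = fit),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> Y = %.3f x + %.3f  (R^2 = %.4f, p = %.3g, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Stratified calibration for low and high egg densities
#'
#' Counting reliability degrades when eggs crowd and merge, so the
#' calibration is also fitted separately below and above a density cutoff
#' (default 100 eggs per image, the density at which per-object counting
#' visibly weakens). The low-density slope is expected to sit closer to 1
#' than the high-density slope.
#'
#' @param pairs as in [fit_calibration()].
#' @param cutoff manual-count cutoff separating the regimes (rows with
#'   `manual <= cutoff` go to the low stratum).
#' @return list with `calibration_fit` elements `low` and `high` (either may
#'   be `NULL` when a stratum has fewer than 3 usable rows) and the `cutoff`.
#' @export
fit_calibration_stratified <- function(pairs, cutoff = 100) {
  pairs <- as.data.frame(pairs)
  fit_or_null <- function(p) {
    if (nrow(p) >= 3L && stats::var(p$manual) > 0) fit_calibration(p) else NULL
  }
  list(low = fit_or_null(pairs[pairs$manual <= cutoff, , drop = FALSE]),
       high = fit_or_null(pairs[pairs$manual > cutoff, , drop = FALSE]),
       cutoff = cutoff)
}

#' Error metrics of automatic counts against ground truth
#'
#' Per-image absolute error |auto - true| and percent error
#' 100 |auto - true| / true, averaged over images, plus the share of images
#' counted exactly right. Images with a true count of 0 have no defined
#' percent error; they are excluded from `mean_pct_error` and reported in
#' `n_undefined_pct`.
#'
#' @param auto integer vector of automatic totals.
#' @param truth integer vector of true totals, aligned with `auto`.
#' @return an `error_metrics` list: `mean_abs_error`, `mean_pct_error`,
#'   `exact_match_fraction`, `n_images`, `n_undefined_pct`, and the per-image
#'   table in `$per_image`.
#' @examples
#' evaluate_against_truth(c(98, 100), c(100, 100))
#' @export
evaluate_against_truth <- function(auto, truth) {
  if (length(auto) != length(truth)) {
    stop_ovocount("`auto` and `truth` must have the same length",
                  "ovocount_parameter_error")
  }
  abs_err <- abs(auto - truth)
  pct_err <- ifelse(truth > 0, 100 * abs_err / truth, NA_real_)
  structure(list(mean_abs_error = mean(abs_err),
                 mean_pct_error = mean(pct_err, na.rm = TRUE),
                 exact_match_fraction = mean(abs_err == 0),
                 n_images = length(auto),
                 n_undefined_pct = sum(truth == 0 & auto != 0),
                 per_image = data.frame(auto = auto, truth = truth,
                                        abs_error = abs_err,
                                        pct_error = pct_err)),
            class = "error_metrics")
}

#' @export
print.error_metrics <- function(x, ...) {
  cat(sprintf("<error_metrics> %d images: mean |error| %.2f eggs, mean error %.2f%%, %.0f%% exact\n",
              x$n_images, x$mean_abs_error, x$mean_pct_error,
              100 * x$exact_match_fraction))
  invisible(x)
}

#' Egg percentage for one arm of a dual-choice assay
#'
#' `100 * eggs_choice / total_eggs`: the share of a replicate's eggs laid in
#' one of its two containers. The two arms of one replicate sum to 100 when
#' both use the same total.
#'
#' @param eggs_choice eggs laid in the arm, `0 <= eggs_choice <= total_eggs`.
#' @param total_eggs total eggs of the replicate, > 0.
#' @return percentage in \[0, 100\].
#' @examples
#' choice_percent(7, 28)
#' @export
choice_percent <- function(eggs_choice, total_eggs) {
  if (any(total_eggs <= 0)) {
    stop_ovocount("total_eggs must be positive", "ovocount_parameter_error")
  }
  if (any(eggs_choice < 0) || any(eggs_choice > total_eggs)) {
    stop_ovocount("eggs_choice must lie in [0, total_eggs]",
                  "ovocount_parameter_error")
  }
  100 * eggs_choice / total_eggs
}

#' Welch two-sample comparison of choice percentages
#'
#' Unequal-variance t test between the egg percentages of two assay arms
#' (e.g. semiochemical vs water), the standard parametric test for a
#' dual-choice oviposition experiment once normality holds. Positive t means
#' the first group's mean is higher.
#'
#' @param group_a,group_b numeric vectors of percentages, each with at least
#'   2 values and not both of zero variance.
#' @return a `choice_summary`: per-group means, `t_statistic`,
#'   Welch-Satterthwaite `df`, two-sided `p_value`, and the group values.
#' @examples
#' welch_choice_test(c(10, 20, 30), c(40, 50, 60))
#' @export
welch_choice_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_ovocount("each group needs at least 2 values",
                  "ovocount_statistics_error")
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    stop_ovocount("both groups have zero variance; the test is undefined",
                  "ovocount_statistics_error")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  structure(list(mean_a = mean(group_a), mean_b = mean(group_b),
                 t_statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 group_a = group_a, group_b = group_b),
            class = "choice_summary")
}

#' @export
print.choice_summary <- function(x, ...) {
  cat(sprintf("<choice_summary> mean %.1f%% vs %.1f%%: t(%.2f) = %.3f, p = %.4g\n",
              x$mean_a, x$mean_b, x$df, x$t_statistic, x$p_value))
  invisible(x)
}

#' Calibration scatter plot with fitted line
#'
#' @param fit a `calibration_fit`.
#' @param path output PNG path.
#' @return `invisible(path)`.
#' @export
plot_calibration <- function(fit, path) {
  stopifnot(inherits(fit, "calibration_fit"))
  grDevices::png(path, width = 700, height = 500)
  on.exit(grDevices::dev.off(), add = TRUE)
  d <- fit$model$model
  plot(d$manual, d$estimated, pch = 19, col = "grey30",
       xlab = "Manual count (eggs)", ylab = "Automatic estimate (eggs)",
       main = sprintf("Y = %.2f x + %.2f,  R^2 = %.3f", fit$slope,
                      fit$intercept, fit$r_squared))
  graphics::abline(fit$model, col = "firebrick", lwd = 2)
  graphics::abline(0, 1, col = "grey60", lty = 2)
  invisible(path)
}
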