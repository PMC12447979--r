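# Agreement and accuracy statistics: R-squared, RMSE, MAE, Bland-Altman
# limits of agreement, and paired model comparisons.

#' Bland-Altman agreement statistics
#'
#' Bias and 1.96-SD limits of agreement of the paired differences
#' `pred - actual` (sample SD, n-1 denominator).
#'
#' @param pred,actual paired series in mmHg (equal lengths, n >= 2).
#' @return list with `bias`, `loa_low`, `loa_high`, `sd`.
#' @export
bland_altman <- function(pred, actual) {
  if (length(pred) != length(actual)) stop("pred and actual lengths differ")
  if (length(pred) < 2) stop("need at least 2 pairs for Bland-Altman limits")
  d <- pred - actual
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd = s)
}

#' Accuracy and agreement metrics for a prediction series
#'
#' `r2 = 1 - SS_res / SS_tot` by default (`r2_method = "ss"`); the
#' squared-Pearson alternative (`"correlation"`) is the square of the
#' correlation between predicted and actual values.  When the actual series
#' has zero variance the R-squared is reported as `NA` with an explanatory
#' attribute.  RMSE and MAE are the root-mean-squared and mean absolute
#' errors; bias and limits of agreement come from [bland_altman()].
#'
#' @param pred,actual paired series in mmHg (equal lengths, n >= 3).
#' @param r2_method `"ss"` or `"correlation"`.
#' @return an object of class `metrics_report`: list with `r2`, `rmse`,
#'   `mae`, `bias`, `loa_low`, `loa_high`, `n`, `r2_method`.
#' @export
compute_metrics <- function(pred, actual, r2_method = c("ss", "correlation")) {
  r2_method <- match.arg(r2_method)
  if (length(pred) != length(actual)) stop("pred and actual lengths differ")
  n <- length(pred)
  if (n < 3) stop("need at least 3 pairs to compute metrics")
  err <- pred - actual
  sst <- sum((actual - mean(actual))^2)
  if (sst <= 0) {
    r2 <- NA_real_
    attr(r2, "reason") <- "actual series has zero variance"
  } else if (r2_method == "ss") {
    r2 <- 1 - sum(err^2) / sst
  } else {
    r2 <- stats::cor(pred, actual)^2
  }
  ba <- bland_altman(pred, actual)
  structure(list(r2 = r2, rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
                 bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
                 n = n, r2_method = r2_method),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d\n  R2 (%s): %s  RMSE: %.3f mmHg  MAE: %.3f mmHg\n",
              x$n, x$r2_method,
              if (is.na(x$r2)) "undefined" else sprintf("%.3f", x$r2),
              x$rmse, x$mae))
  cat(sprintf("  Bland-Altman bias: %.2f mmHg, limits [%.2f, %.2f]\n",
              x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Paired comparison of two models' error metrics
#'
#' Computes the paired t statistic and two-sided p-value by the textbook
#' formula (`t = mean(d) / (sd(d) / sqrt(n))` on the paired differences
#' `a - b`), plus the companion Wilcoxon signed-rank p-value.  All-zero
#' differences are flagged degenerate (p undefined); a constant nonzero
#' shift has zero-variance differences and is reported as the infinite-t
#' limit with p = 0.
#'
#' @param errors_a,errors_b paired per-subject (or per-seed) metric values
#'   (equal lengths, at least 5 pairs).
#' @return an object of class `comparison_result`: `statistic`, `p_value`,
#'   `p_wilcoxon`, `test`, `degenerate`, `n`.
#' @export
compare_models <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b)) stop("paired metric lengths differ")
  n <- length(errors_a)
  if (n < 5) stop("need at least 5 pairs for a paired comparison")
  d <- errors_a - errors_b
  degenerate <- all(d == 0)
  if (degenerate) {
    stat <- NA_real_; pval <- NA_real_; pw <- NA_real_
  } else if (stats::sd(d) == 0) {
    stat <- sign(mean(d)) * Inf
    pval <- 0
    pw <- suppressWarnings(stats::wilcox.test(errors_a, errors_b,
                                              paired = TRUE, exact = FALSE)$p.value)
  } else {
    stat <- mean(d) / (stats::sd(d) / sqrt(n))
    pval <- 2 * stats::pt(-abs(stat), df = n - 1)
    pw <- suppressWarnings(stats::wilcox.test(errors_a, errors_b,
                                              paired = TRUE, exact = FALSE)$p.value)
  }
  structure(list(statistic = stat, p_value = pval, p_wilcoxon = pw,
                 test = "paired t (with signed-rank companion)",
                 degenerate = degenerate, n = n, differences = d),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<comparison_result> degenerate: all paired differences are zero\n")
  } else {
    cat(sprintf("<comparison_result> t = %.4g, p = %.4g (signed-rank p = %.4g), n = %d\n",
                x$statistic, x$p_value, x$p_wilcoxon, x$n))
  }
  invisible(x)
}
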