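# Quantitative evaluation of count regressions: RMSE, coefficient of
# determination and rounded-prediction accuracy, plus per-ground-truth
# prediction distributions for violin-style summaries.

check_pairs <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat lengths differ", call. = FALSE)
  if (!length(y)) stop("empty prediction set", call. = FALSE)
  invisible(NULL)
}

#' Root mean squared error
#'
#' `sqrt(mean((y - yhat)^2))` between integer ground-truth counts and raw
#' (unrounded) predictions.
#'
#' @param y integer ground-truth leaf counts.
#' @param yhat raw real-valued predictions.
#' @return a single nonnegative number.
#' @export
rmse <- function(y, yhat) {
  check_pairs(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, with the total sum of squares taken around the
#' mean of the ground truth. Undefined (an error) when `y` is constant.
#'
#' @inheritParams rmse
#' @return a single number `<= 1`.
#' @export
r_squared <- function(y, yhat) {
  check_pairs(y, yhat)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0)
    stop("r_squared is undefined for constant ground truth", call. = FALSE)
  1 - sum((y - yhat)^2) / ss_tot
}

#' Round half away from zero
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

#' Counting accuracy
#'
#' Fraction of predictions whose rounded value equals the integer ground
#' truth. The default rounding is half-up (`floor(x + 0.5)`); banker's
#' rounding (`"nearest_even"`, base [round()]) is available.
#'
#' @inheritParams rmse
#' @param rounding `"half_up"` or `"nearest_even"`.
#' @return a fraction in `[0, 1]`.
#' @export
count_accuracy <- function(y, yhat, rounding = c("half_up", "nearest_even")) {
  rounding <- match.arg(rounding)
  check_pairs(y, yhat)
  r <- if (rounding == "half_up") round_half_up(yhat) else round(yhat)
  mean(r == y)
}

#' Per-ground-truth prediction distributions
#'
#' Groups raw predictions by their ground-truth count and summarizes each
#' group with quantiles and a kernel-density estimate, the ingredients of a
#' violin plot of predictions against true counts.
#'
#' @inheritParams rmse
#' @return a named list (one element per distinct ground-truth count, in
#'   increasing order) with `values`, `n`, `median`, `quantiles`
#'   (2.5/25/50/75/97.5%) and `density` (`NULL` for groups of size < 2).
#' @export
distribution_summary <- function(y, yhat) {
  check_pairs(y, yhat)
  groups <- split(yhat, y)
  lapply(groups, function(v) {
    list(values = v, n = length(v), median = stats::median(v),
         quantiles = stats::quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975)),
         density = if (length(v) >= 2 && stats::sd(v) > 0)
           stats::density(v) else NULL)
  })
}

#' Evaluate predictions against a manifest
#'
#' @param y integer ground-truth counts.
#' @param yhat raw predictions.
#' @return an object of class `"leafcount_eval"`: a list with `rmse`, `r2`,
#'   `accuracy`, `n` and `by_count` (see [distribution_summary()]).
#' @export
evaluate_predictions <- function(y, yhat) {
  structure(list(rmse = rmse(y, yhat),
                 r2 = r_squared(y, yhat),
                 accuracy = count_accuracy(y, yhat),
                 n = length(y),
                 by_count = distribution_summary(y, yhat)),
            class = "leafcount_eval")
}

#' @export
print.leafcount_eval <- function(x, ...) {
  cat(sprintf("Leaf-count evaluation on %d images\n", x$n))
  cat(sprintf("  RMSE     : %.4f\n", x$rmse))
  cat(sprintf("  R-squared: %.4f\n", x$r2))
  cat(sprintf("  Accuracy : %.4f\n", x$accuracy))
  invisible(x)
}
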