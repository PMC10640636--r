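#' Normal-approximation binomial confidence interval
#'
#' Wald interval: `p_hat +/- z * sqrt(p_hat (1 - p_hat) / n)` with `z` the
#' standard-normal quantile at `(1 + level)/2` (1.959964 at 95%), clipped
#' to `[0, 1]`.
#'
#' @param p_hat Observed proportion in `[0, 1]`.
#' @param n Denominator (>= 1).
#' @param level Confidence level (default 0.95).
#' @return Object of class `proportion_ci`: list with `estimate`,
#'   `lower`, `upper`, `n`, `level`.
#' @export
binom_ci_normal <- function(p_hat, n, level = 0.95) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.numeric(p_hat) || p_hat < 0 || p_hat > 1) {
    stop("p_hat must be in [0, 1]", call. = FALSE)
  }
  z <- stats::qnorm((1 + level) / 2)
  half <- z * sqrt(p_hat * (1 - p_hat) / n)
  structure(
    list(
      estimate = p_hat,
      lower = max(0, p_hat - half),
      upper = min(1, p_hat + half),
      n = n, level = level
    ),
    class = "proportion_ci"
  )
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%.1f%% (95%% CI: %.1f, %.1f), n = %d\n",
              100 * x$estimate, 100 * x$lower, 100 * x$upper, as.integer(x$n)))
  invisible(x)
}

#' Accuracy, sensitivity and specificity with binomial CIs
#'
#' Accuracy is `(tp + tn) / total`, sensitivity `tp / (tp + fn)` (among
#' truly recurrent patients), specificity `tn / (tn + fp)` (among truly
#' non-recurrent patients); each is wrapped in a normal-approximation CI
#' with its own denominator. A zero denominator yields an `NA` estimate
#' flagged in `undefined`.
#'
#' @param counts A [confusion_counts()] object.
#' @param level Confidence level.
#' @return List with `accuracy`, `sensitivity`, `specificity`
#'   (`proportion_ci` or `NA`), `counts` and `undefined` (character
#'   vector of metrics with zero denominators).
#' @export
summarize_confusion <- function(counts, level = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  n_pos <- counts$tp + counts$fn
  n_neg <- counts$tn + counts$fp
  undefined <- character(0)
  mk <- function(num, den, what) {
    if (den == 0L) {
      undefined <<- c(undefined, what)
      return(NA)
    }
    binom_ci_normal(num / den, den, level)
  }
  list(
    accuracy = mk(counts$tp + counts$tn, total, "accuracy"),
    sensitivity = mk(counts$tp, n_pos, "sensitivity"),
    specificity = mk(counts$tn, n_neg, "specificity"),
    counts = counts,
    undefined = undefined
  )
}

#' Format a metrics summary as a one-row data.frame in percent
#'
#' @param summary Result of [summarize_confusion()].
#' @param label Row label for the predictor.
#' @return data.frame with estimate and CI columns in percent (1 decimal).
#' @export
metrics_row <- function(summary, label = "") {
  cell <- function(ci) {
    if (!inherits(ci, "proportion_ci")) {
      return(c(NA_real_, NA_real_, NA_real_))
    }
    round(100 * c(ci$estimate, ci$lower, ci$upper), 1)
  }
  a <- cell(summary$accuracy)
  s <- cell(summary$sensitivity)
  p <- cell(summary$specificity)
  data.frame(
    predictor = label,
    accuracy = a[1], accuracy_lo = a[2], accuracy_hi = a[3],
    sensitivity = s[1], sensitivity_lo = s[2], sensitivity_hi = s[3],
    specificity = p[1], specificity_lo = p[2], specificity_hi = p[3],
    stringsAsFactors = FALSE
  )
}
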