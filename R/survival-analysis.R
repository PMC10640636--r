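#' Kaplan-Meier estimate per image class
#'
#' Product-limit estimator of time to recurrence per group; censored
#' times reduce the risk set without producing steps. The cumulative
#' incidence column is `1 - S(t)`.
#'
#' @param time Positive follow-up times (months).
#' @param event Logical event indicators.
#' @param group Group labels (e.g. image class "low"/"high").
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `cuminc`.
#' @export
km_estimate <- function(time, event, group) {
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  group <- as.factor(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- if (is.null(fit$strata)) {
    rep(levels(group)[1], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  data.frame(
    group = strata,
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    surv = fit$surv,
    cuminc = 1 - fit$surv,
    stringsAsFactors = FALSE
  )
}

#' Cox proportional-hazards fit for a binary group
#'
#' Maximizes the Cox partial likelihood (Breslow tie handling by default;
#' Efron available) by Newton iteration and reports the hazard ratio for
#' the second factor level versus the first, with a Wald 95% CI
#' `exp(log_hr +/- 1.959964 * se)` from the observed information. A
#' monotone likelihood (infinite HR) is detected and reported as an
#' error.
#'
#' @param time Positive follow-up times.
#' @param event Logical event indicators.
#' @param group Two-level group (factor, character or logical); the
#'   hazard ratio contrasts the second level vs the first.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return Object of class `cox_fit`: list with `log_hr`, `se`, `hr`,
#'   `ci` (length-2), `n_events`, `ties_method`.
#' @export
cox_fit <- function(time, event, group, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  if (sum(event) < 1) stop("need at least one event", call. = FALSE)
  if (is.logical(group)) group <- factor(group, levels = c(FALSE, TRUE))
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("group must take exactly two values", call. = FALSE)
  x <- as.numeric(group) - 1
  fit <- survival::coxph(
    survival::Surv(time, event) ~ x,
    ties = ties,
    control = survival::coxph.control(eps = 1e-9, iter.max = 100)
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15 || se > 100) {
    stop("partial likelihood is monotone: hazard ratio diverges", call. = FALSE)
  }
  z <- stats::qnorm(0.975)
  structure(
    list(
      log_hr = beta,
      se = se,
      hr = exp(beta),
      ci = c(lower = exp(beta - z * se), upper = exp(beta + z * se)),
      n_events = sum(event),
      ties_method = ties,
      groups = levels(group)
    ),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit (%s ties): HR %.2f (95%% CI: %.2f, %.2f), %d events\n",
              x$ties_method, x$hr, x$ci[1], x$ci[2], x$n_events))
  invisible(x)
}
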