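#' Build a balanced 1:1 age-matched case-control set
#'
#' Every patient who recurred within three years (a case) is paired with a
#' non-recurrent control from the same age bin, sampled uniformly without
#' replacement. Bins are half-open `[5k, 5k + width)` anchored at zero.
#'
#' @param cohort Cohort data.frame (needs `patient_id`, `age`,
#'   `recurred_3yr`).
#' @param bin_width Age bin width in years (default 5).
#' @param seed Integer seed for control sampling.
#' @param nearest_bin_fallback If `TRUE`, a bin with too few controls may
#'   borrow from the nearest bin (by bin distance); default `FALSE`, in
#'   which case an infeasible bin is an error naming the bin.
#' @return Object of class `matched_cohort`: list with `pairs`
#'   (data.frame `case_id`, `control_id`, `bin`) and `records` (the 2n
#'   matched rows of `cohort`, cases first).
#' @export
match_balanced <- function(cohort, bin_width = 5, seed = 1L,
                           nearest_bin_fallback = FALSE) {
  stopifnot(all(c("patient_id", "age", "recurred_3yr") %in% names(cohort)))
  if (anyNA(cohort$age)) stop("age missing for some patients", call. = FALSE)
  cases <- cohort[cohort$recurred_3yr, , drop = FALSE]
  controls <- cohort[!cohort$recurred_3yr, , drop = FALSE]
  if (nrow(cases) == 0L) stop("cohort contains no cases", call. = FALSE)

  bin_of <- function(age) floor(age / bin_width) * bin_width
  case_bin <- bin_of(cases$age)
  ctrl_bin <- bin_of(controls$age)

  with_seed(substream_seed(seed, "matching"), {
    available <- controls$patient_id
    avail_bin <- ctrl_bin
    pair_case <- character(0)
    pair_ctrl <- character(0)
    pair_bin <- numeric(0)
    for (b in sort(unique(case_bin))) {
      ids_case <- cases$patient_id[case_bin == b]
      pool <- available[avail_bin == b]
      if (length(pool) < length(ids_case)) {
        if (!nearest_bin_fallback) {
          stop(sprintf(
            "matching infeasible in age bin [%g,%g): %d cases, %d controls",
            b, b + bin_width, length(ids_case), length(pool)
          ), call. = FALSE)
        }
        # borrow nearest-bin controls, closest bins first
        deficit <- length(ids_case) - length(pool)
        other <- order(abs(avail_bin - b))
        other <- other[avail_bin[other] != b]
        borrow <- available[other][seq_len(min(deficit, length(other)))]
        if (length(borrow) < deficit) {
          stop("matching infeasible even with nearest-bin fallback", call. = FALSE)
        }
        pool <- c(pool, borrow)
      }
      chosen <- if (length(pool) == 1L) pool else sample(pool, length(ids_case))
      chosen <- chosen[seq_along(ids_case)]
      pair_case <- c(pair_case, ids_case)
      pair_ctrl <- c(pair_ctrl, chosen)
      pair_bin <- c(pair_bin, rep(b, length(ids_case)))
      keep <- !(available %in% chosen)
      available <- available[keep]
      avail_bin <- avail_bin[keep]
    }
    pairs <- data.frame(
      case_id = pair_case, control_id = pair_ctrl, bin = pair_bin,
      stringsAsFactors = FALSE
    )
    records <- rbind(
      cohort[match(pairs$case_id, cohort$patient_id), , drop = FALSE],
      cohort[match(pairs$control_id, cohort$patient_id), , drop = FALSE]
    )
    rownames(records) <- NULL
    out <- list(pairs = pairs, records = records, bin_width = bin_width)
    class(out) <- "matched_cohort"
    out
  })
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("matched_cohort:", nrow(x$pairs), "case-control pairs,",
      x$bin_width, "year age bins\n")
  invisible(x)
}

#' Confusion counts for a binary recurrence predictor
#'
#' @param truth Logical vector, `TRUE` for recurrence.
#' @param prediction Logical vector, `TRUE` for predicted recurrence.
#' @return Object of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, prediction) {
  stopifnot(length(truth) == length(prediction))
  out <- list(
    tp = sum(truth & prediction),
    fp = sum(!truth & prediction),
    tn = sum(!truth & !prediction),
    fn = sum(truth & !prediction)
  )
  class(out) <- "confusion_counts"
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts: tp=%d fp=%d tn=%d fn=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Evaluate a clinical comparator marker as a recurrence predictor
#'
#' The grade rule predicts recurrence iff combined histologic grade is 3
#' (high); the ER rule predicts recurrence iff the tumor is ER-negative.
#'
#' @param matched A [match_balanced()] result, or any cohort data.frame.
#' @param marker `"grade"` or `"er"`.
#' @param strict If `TRUE`, missing marker values are an error; otherwise
#'   they are excluded with a warning.
#' @return [confusion_counts()] against `recurred_3yr`.
#' @export
biomarker_predictor <- function(matched, marker = c("grade", "er"),
                                strict = FALSE) {
  marker <- match.arg(marker)
  records <- if (inherits(matched, "matched_cohort")) matched$records else matched
  val <- records[[marker]]
  miss <- is.na(val)
  if (any(miss)) {
    if (strict) stop(sum(miss), " patients missing ", marker, call. = FALSE)
    warning(sum(miss), " patients missing ", marker, "; excluded", call. = FALSE)
    records <- records[!miss, , drop = FALSE]
    val <- val[!miss]
  }
  pred <- switch(marker,
    grade = val == 3,
    er = val == "negative"
  )
  cc <- confusion_counts(records$recurred_3yr, pred)
  if (cc$tp + cc$fn == 0L) {
    attr(cc, "flag") <- "sensitivity undefined: no true cases predicted positive or negative"
  }
  cc
}

#' Apply declarative eligibility filters to a cohort
#'
#' Each rule is a character exclusion predicate evaluated over the cohort
#' columns (e.g. `"stage == 4"` or `"is.na(grade)"`); patients for whom a
#' rule evaluates `TRUE` are excluded. Rules are applied sequentially so
#' the per-rule counts form an exclusion cascade.
#'
#' @param cohort Cohort data.frame.
#' @param rules Named list/character vector of exclusion predicates.
#' @return List with `cohort` (retained rows) and `log` (data.frame
#'   `rule`, `expression`, `n_excluded`, `n_remaining`).
#' @export
apply_eligibility_filters <- function(cohort, rules = list()) {
  log <- data.frame(
    rule = character(0), expression = character(0),
    n_excluded = integer(0), n_remaining = integer(0),
    stringsAsFactors = FALSE
  )
  current <- cohort
  for (nm in names(rules)) {
    expr_txt <- rules[[nm]]
    expr <- parse(text = expr_txt)[[1]]
    vars <- all.vars(expr)
    unknown <- setdiff(vars, names(cohort))
    if (length(unknown)) {
      stop("unknown field(s) in rule '", nm, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    excl <- eval(expr, envir = current, enclos = baseenv())
    excl[is.na(excl)] <- FALSE
    current <- current[!excl, , drop = FALSE]
    log <- rbind(log, data.frame(
      rule = nm, expression = expr_txt,
      n_excluded = sum(excl), n_remaining = nrow(current),
      stringsAsFactors = FALSE
    ))
  }
  list(cohort = current, log = log)
}
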