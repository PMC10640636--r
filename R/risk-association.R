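#' Build image class x genomic risk tables for each assay
#'
#' Tallies patients with a non-missing genomic category into a 2x2 table
#' (rows: genomic low-intermediate / high; columns: image low / high).
#'
#' @param classes data.frame from [assign_full_cohort_classes()]
#'   (`patient_id`, `image_class`).
#' @param cohort Cohort data.frame with `oncotype_cat` and `rorpt_cat`.
#' @param assays Character vector of assay column suffixes to tabulate.
#' @return Named list of 2x2 integer matrices with dimnames
#'   `genomic = c("low-intermediate", "high")`,
#'   `image = c("low", "high")`.
#' @export
build_risk_tables <- function(classes, cohort,
                              assays = c("oncotype", "rorpt")) {
  m <- match(classes$patient_id, cohort$patient_id)
  out <- list()
  for (assay in assays) {
    col <- paste0(assay, "_cat")
    if (!col %in% names(cohort)) stop("cohort lacks column ", col, call. = FALSE)
    cat <- cohort[[col]][m]
    keep <- !is.na(cat)
    if (!any(keep)) stop("no patients with non-missing ", assay, call. = FALSE)
    tab <- table(
      genomic = factor(cat[keep], levels = c("low-intermediate", "high")),
      image = factor(classes$image_class[keep], levels = c("low", "high"))
    )
    out[[assay]] <- unclass(tab)
  }
  out
}

#' Relative frequency difference from a 2x2 risk table
#'
#' Point estimate: `P(image-high | genomic-high) - P(image-high |
#' genomic low-intermediate)`, the coefficient of an identity-link
#' binomial GLM with a single binary predictor. The closed form and the
#' iteratively (re)weighted GLM fit are both computed and must agree to
#' 1e-8, guarding against identity-link convergence quirks; the Wald CI
#' uses the GLM variance (the two-sample proportion-difference SE).
#'
#' @param table 2x2 matrix: rows genomic (reference first, i.e.
#'   low-intermediate then high), columns image (low, high).
#' @param level Confidence level.
#' @return Object of class `rfd_result`: list with `rfd`, `se`, `ci`,
#'   `reference_row`, `p_reference`, `p_exposed`, and `boundary` flag.
#' @export
rfd_estimate <- function(table, level = 0.95) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("expected a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  n1 <- sum(table[1, ])
  n2 <- sum(table[2, ])
  if (n1 == 0L || n2 == 0L) stop("a table row has zero margin", call. = FALSE)
  p1 <- table[1, 2] / n1  # image-high among genomic low-intermediate
  p2 <- table[2, 2] / n2  # image-high among genomic high
  rfd_closed <- p2 - p1

  dat <- data.frame(
    genomic_high = c(0, 1),
    img_high = c(table[1, 2], table[2, 2]),
    img_low = c(table[1, 1], table[2, 1])
  )
  # step-halving warnings can fire when a proportion sits on the boundary;
  # agreement with the closed form is asserted below regardless
  fit <- suppressWarnings(stats::glm(
    cbind(img_high, img_low) ~ genomic_high,
    family = stats::binomial(link = "identity"),
    data = dat,
    start = c(max(min(p1, 1 - 1e-9), 1e-9), rfd_closed)
  ))
  rfd_glm <- unname(stats::coef(fit)["genomic_high"])
  if (abs(rfd_glm - rfd_closed) > 1e-8) {
    stop("identity-link GLM and closed form disagree: ",
         rfd_glm, " vs ", rfd_closed, call. = FALSE)
  }
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  boundary <- any(c(p1, p2) %in% c(0, 1))
  z <- stats::qnorm((1 + level) / 2)
  structure(
    list(
      rfd = rfd_glm,
      rfd_closed_form = rfd_closed,
      se = se,
      ci = c(lower = rfd_glm - z * se, upper = rfd_glm + z * se),
      reference_row = rownames(table)[1] %||% "low-intermediate",
      p_reference = p1,
      p_exposed = p2,
      boundary = boundary,
      level = level
    ),
    class = "rfd_result"
  )
}

#' @export
print.rfd_result <- function(x, ...) {
  cat(sprintf("RFD %.1f%% (95%% CI: %.1f, %.1f), reference = %s%s\n",
              100 * x$rfd, 100 * x$ci[1], 100 * x$ci[2], x$reference_row,
              if (x$boundary) " [boundary proportion: CI unreliable]" else ""))
  invisible(x)
}

#' Dichotomize raw OncotypeDX recurrence scores
#'
#' Scores below 26 are low-intermediate risk; 26 and above are high risk.
#'
#' @param score Numeric vector of recurrence scores.
#' @return Character vector in `{"low-intermediate", "high"}` (NA kept).
#' @export
categorize_oncotype <- function(score) {
  ifelse(is.na(score), NA_character_,
         ifelse(score < 26, "low-intermediate", "high"))
}
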