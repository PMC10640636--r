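#' Fit the maximum-margin linear recurrence classifier
#'
#' Fits a soft-margin linear support vector machine on patient-level
#' feature vectors under hinge loss at the given regularization (cost)
#' parameter. Features are standardized per dimension before fitting and
#' the standardization is stored in the model, so prediction is invariant
#' to invertible per-dimension affine rescaling of the inputs. The model
#' is oriented so that positive decision values correspond to the
#' recurrent ("high-risk") class.
#'
#' @param x Numeric matrix, one patient per row.
#' @param y Logical vector (`TRUE` = recurred within 3 years).
#' @param regularization Positive soft-margin cost (default 1.0).
#' @return Object of class `margin_model`: list with `weights`, `bias`,
#'   `regularization`, `center`, `scale`.
#' @export
margin_fit <- function(x, y, regularization = 1.0) {
  x <- as.matrix(x)
  y <- as.logical(y)
  if (nrow(x) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  if (regularization <= 0) stop("regularization must be positive", call. = FALSE)

  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")

  fit <- e1071::svm(
    x = xs, y = factor(y, levels = c(FALSE, TRUE)),
    type = "C-classification", kernel = "linear",
    cost = regularization, scale = FALSE
  )
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  d <- drop(xs %*% w) + b
  # orient so recurrent patients sit on the positive side
  if (mean(d[y]) < mean(d[!y])) {
    w <- -w
    b <- -b
  }
  structure(
    list(
      weights = unname(w), bias = unname(b),
      regularization = regularization,
      center = unname(center), scale = unname(scl)
    ),
    class = "margin_model"
  )
}

#' Predict recurrence classes and decision values
#'
#' Labels are the sign of the decision value; a point exactly on the
#' boundary (decision value 0) is assigned to the positive (recurrent)
#' class by convention.
#'
#' @param model A `margin_model`.
#' @param x Numeric matrix or vector of features.
#' @return List with `label` (logical) and `decision` (numeric).
#' @export
margin_predict <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(model$weights)) {
    stop("feature dimension mismatch: model has ", length(model$weights),
         ", input has ", ncol(x), call. = FALSE)
  }
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  d <- drop(xs %*% model$weights) + model$bias
  list(label = d >= 0, decision = d)
}

#' Regularized hinge objective of a margin model on a data set
#'
#' `0.5 * ||w||^2 + C * sum(max(0, 1 - y_i f(x_i)))` in the model's
#' standardized feature space, with y in {-1, +1}.
#'
#' @param model A `margin_model` (or a list with `weights`, `bias`,
#'   `center`, `scale`, `regularization`).
#' @param x Feature matrix.
#' @param y Logical labels.
#' @return The objective value (scalar).
#' @export
hinge_objective <- function(model, x, y) {
  xs <- sweep(sweep(as.matrix(x), 2, model$center), 2, model$scale, "/")
  f <- drop(xs %*% model$weights) + model$bias
  ypm <- ifelse(as.logical(y), 1, -1)
  0.5 * sum(model$weights^2) +
    model$regularization * sum(pmax(0, 1 - ypm * f))
}

#' Serialize a margin model to JSON
#'
#' @param model A `margin_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
margin_write_json <- function(model, path) {
  jsonlite::write_json(
    list(
      weights = model$weights, bias = model$bias,
      regularization = model$regularization,
      center = model$center, scale = model$scale
    ),
    path,
    digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a margin model from JSON
#'
#' @param path JSON file written by [margin_write_json()].
#' @return A `margin_model`.
#' @export
margin_read_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      weights = as.numeric(m$weights), bias = as.numeric(m$bias),
      regularization = as.numeric(m$regularization),
      center = as.numeric(m$center), scale = as.numeric(m$scale)
    ),
    class = "margin_model"
  )
}

#' @export
print.margin_model <- function(x, ...) {
  cat("margin_model: linear, dim", length(x$weights),
      "cost", x$regularization, "\n")
  invisible(x)
}
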