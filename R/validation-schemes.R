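#' Cross-patient stratified k-fold cross-validation
#'
#' Patients are assigned to label-stratified folds; each patient is
#' predicted exactly once, by a model whose training set excludes it.
#'
#' @param x Patients x C feature matrix (rownames = patient ids, or pass
#'   `ids`).
#' @param y Logical labels, one per patient.
#' @param ids Patient ids (defaults to rownames of `x`).
#' @param k Number of folds (default 10).
#' @param regularization Margin-classifier cost.
#' @param seed Integer seed for fold assignment.
#' @return A `prediction_set` data.frame with columns `patient_id`,
#'   `scheme`, `fold`, `true`, `pred`, `decision`; the per-fold training
#'   ids are attached as attribute `"fold_train_ids"`.
#' @export
cross_patient_cv <- function(x, y, ids = rownames(x), k = 10L,
                             regularization = 1.0, seed = 1L) {
  x <- as.matrix(x)
  y <- as.logical(y)
  k <- as.integer(k)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  fold <- integer(length(y))
  if (k == length(y)) {
    # leave-one-out: every patient is its own fold
    fold <- seq_along(y)
  } else if (min(table(y)) < k) {
    stop("k exceeds the size of the smaller class", call. = FALSE)
  } else {
    with_seed(substream_seed(seed, "cv-folds"), {
      for (cls in c(TRUE, FALSE)) {
        ix <- which(y == cls)
        fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
      }
    })
  }
  pred <- logical(length(y))
  dec <- numeric(length(y))
  train_ids <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- margin_fit(x[tr, , drop = FALSE], y[tr], regularization)
    p <- margin_predict(model, x[!tr, , drop = FALSE])
    pred[!tr] <- p$label
    dec[!tr] <- p$decision
    train_ids[[f]] <- ids[tr]
  }
  out <- data.frame(
    patient_id = ids, scheme = "cross_patient", fold = fold,
    true = y, pred = pred, decision = dec, stringsAsFactors = FALSE
  )
  attr(out, "fold_train_ids") <- train_ids
  class(out) <- c("prediction_set", "data.frame")
  out
}

#' Within-patient half-core split validation
#'
#' Each patient's cores are randomly partitioned into a training half and
#' a test half (odd counts put the extra core in training). The training
#' halves are averaged into per-patient training vectors, one model is fit
#' on all of them, and it is evaluated on the averaged test halves.
#'
#' @param cf A `core_features` object (list with `x`, `patient_id`,
#'   `core_id`).
#' @param labels Named logical vector (patient id -> label).
#' @param regularization Margin-classifier cost.
#' @param seed Integer seed for the core partition.
#' @param strict If `TRUE`, any patient with fewer than 2 cores is an
#'   error; otherwise such patients are excluded with a warning.
#' @return A `prediction_set` data.frame (scheme `"within_patient"`), with
#'   attributes `"split"` (data.frame patient_id, n_train, n_test,
#'   train_cores, test_cores) and `"model"` (the fitted `margin_model`).
#' @export
within_patient_split <- function(cf, labels, regularization = 1.0,
                                 seed = 1L, strict = FALSE) {
  pids <- unique(cf$patient_id)
  counts <- table(cf$patient_id)[pids]
  few <- pids[counts < 2L]
  if (length(few)) {
    if (strict) {
      stop("patients with < 2 cores: ", paste(few, collapse = ", "), call. = FALSE)
    }
    warning(length(few), " patients with < 2 cores excluded: ",
            paste(few, collapse = ", "), call. = FALSE)
    pids <- setdiff(pids, few)
  }
  if (length(pids) < 2L) stop("need >= 2 patients with >= 2 cores", call. = FALSE)

  d <- ncol(cf$x)
  x_train <- matrix(0, length(pids), d)
  x_test <- matrix(0, length(pids), d)
  n_train <- integer(length(pids))
  n_test <- integer(length(pids))
  train_cores <- character(length(pids))
  test_cores <- character(length(pids))
  with_seed(substream_seed(seed, "within-split"), {
    for (i in seq_along(pids)) {
      rows <- which(cf$patient_id == pids[i])
      perm <- sample(rows)
      n_tr <- as.integer(ceiling(length(rows) / 2))
      tr <- perm[seq_len(n_tr)]
      te <- perm[-seq_len(n_tr)]
      x_train[i, ] <- colMeans(cf$x[tr, , drop = FALSE])
      x_test[i, ] <- colMeans(cf$x[te, , drop = FALSE])
      n_train[i] <- length(tr)
      n_test[i] <- length(te)
      train_cores[i] <- paste(cf$core_id[tr], collapse = ",")
      test_cores[i] <- paste(cf$core_id[te], collapse = ",")
    }
  })
  y <- as.logical(labels[pids])
  model <- margin_fit(x_train, y, regularization)
  p <- margin_predict(model, x_test)
  out <- data.frame(
    patient_id = pids, scheme = "within_patient", fold = NA_integer_,
    true = y, pred = p$label, decision = p$decision,
    stringsAsFactors = FALSE
  )
  attr(out, "split") <- data.frame(
    patient_id = pids, n_train = n_train, n_test = n_test,
    train_cores = train_cores, test_cores = test_cores,
    stringsAsFactors = FALSE
  )
  attr(out, "model") <- model
  class(out) <- c("prediction_set", "data.frame")
  out
}

#' Confusion counts within grade strata
#'
#' Splits an existing prediction set (no refitting) into the low/
#' intermediate-grade stratum (grades 1-2) and the high-grade stratum
#' (grade 3) and tallies confusion counts in each.
#'
#' @param predictions A `prediction_set`.
#' @param cohort Cohort data.frame with `patient_id` and `grade`.
#' @return List with `overall`, `high_grade`, `low_intermediate_grade`
#'   ([confusion_counts()] each; an empty stratum is `NULL` and named in
#'   `missing_strata`).
#' @export
stratified_evaluate <- function(predictions, cohort) {
  grade <- cohort$grade[match(predictions$patient_id, cohort$patient_id)]
  if (anyNA(grade)) stop("grade missing for some predicted patients", call. = FALSE)
  strata <- list(
    high_grade = grade == 3,
    low_intermediate_grade = grade %in% c(1, 2)
  )
  out <- list(overall = confusion_counts(predictions$true, predictions$pred))
  missing <- character(0)
  for (nm in names(strata)) {
    sel <- strata[[nm]]
    if (!any(sel)) {
      out[[nm]] <- NULL
      missing <- c(missing, nm)
    } else {
      out[[nm]] <- confusion_counts(predictions$true[sel], predictions$pred[sel])
    }
  }
  out$missing_strata <- missing
  out
}

#' Cross-validation accuracy as a function of the number of folds
#'
#' @param x,y,ids,regularization,seed As in [cross_patient_cv()].
#' @param k_values Integer vector of fold counts.
#' @return Named numeric vector of accuracies, one per k.
#' @export
kfold_sweep <- function(x, y, ids = rownames(x), k_values = c(2L, 5L, 10L),
                        regularization = 1.0, seed = 1L) {
  acc <- vapply(k_values, function(k) {
    ps <- cross_patient_cv(x, y, ids = ids, k = k,
                           regularization = regularization, seed = seed)
    mean(ps$pred == ps$true)
  }, numeric(1))
  stats::setNames(acc, paste0("k", k_values))
}

#' Assign low/high image classes to every patient in the full cohort
#'
#' Matched patients keep their held-out predictions from the supplied
#' prediction set; all remaining patients are scored by a final model
#' trained on the full matched set. The provenance of each class is
#' recorded.
#'
#' @param predictions A `prediction_set` over the matched patients.
#' @param matched_x,matched_y Feature matrix and labels of the matched
#'   set used to train the final model (for the within-patient scheme,
#'   pass the training-half features). If `model` is supplied they are
#'   ignored.
#' @param all_x Feature matrix for every patient to classify (rownames =
#'   patient ids, or pass `all_ids`).
#' @param all_ids Patient ids for `all_x`.
#' @param model Optional pre-fitted `margin_model` used for unmatched
#'   patients (e.g. the within-patient model).
#' @param regularization Cost for the final model when it must be fit.
#' @return data.frame with `patient_id`, `image_class` ("low"/"high") and
#'   `source` ("held_out" or "model").
#' @export
assign_full_cohort_classes <- function(predictions, matched_x = NULL,
                                       matched_y = NULL, all_x,
                                       all_ids = rownames(all_x),
                                       model = NULL, regularization = 1.0) {
  all_x <- as.matrix(all_x)
  if (is.null(all_ids)) stop("patient ids required for the full cohort", call. = FALSE)
  if (is.null(model)) {
    model <- margin_fit(matched_x, matched_y, regularization)
  }
  p <- margin_predict(model, all_x)
  cls <- ifelse(p$label, "high", "low")
  src <- rep("model", length(all_ids))
  m <- match(all_ids, predictions$patient_id)
  held <- !is.na(m)
  cls[held] <- ifelse(predictions$pred[m[held]], "high", "low")
  src[held] <- "held_out"
  data.frame(
    patient_id = all_ids, image_class = cls, source = src,
    stringsAsFactors = FALSE
  )
}

#' Write a prediction set as TSV
#'
#' @param predictions A `prediction_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_prediction_set <- function(predictions, path) {
  utils::write.table(as.data.frame(predictions), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
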