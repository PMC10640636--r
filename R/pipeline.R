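#' Assemble and validate a study run configuration
#'
#' @param params A [synthetic_params()] object describing the synthetic
#'   cohort (or the conditions under which features were produced).
#' @param k Folds for cross-patient cross-validation.
#' @param regularization Margin-classifier cost.
#' @param matching List with `bin_width` and `nearest_bin_fallback`.
#' @param filters Named list of eligibility exclusion predicates (see
#'   [apply_eligibility_filters()]).
#' @param with_images If `TRUE`, [simulate_study()] also writes toy core
#'   images.
#' @param image_params Passed to [generate_core_images()].
#' @param output_dir Directory for artifacts.
#' @param seed Root seed for every stage.
#' @return Object of class `study_config` (validated list) carrying a
#'   `config_hash`.
#' @export
study_config <- function(params = synthetic_params(),
                         k = 10L,
                         regularization = 1.0,
                         matching = list(bin_width = 5, nearest_bin_fallback = FALSE),
                         filters = list(),
                         with_images = FALSE,
                         image_params = list(size = 128L),
                         output_dir = tempfile("recurtma_run_"),
                         seed = params$seed) {
  cfg <- list(
    params = params, k = as.integer(k), regularization = regularization,
    matching = matching, filters = filters,
    with_images = isTRUE(with_images), image_params = image_params,
    output_dir = output_dir, seed = as.integer(seed)
  )
  validate_synthetic_params(params)
  if (cfg$k < 2L) stop("k must be >= 2", call. = FALSE)
  if (!is.numeric(cfg$regularization) || cfg$regularization <= 0) {
    stop("regularization must be positive", call. = FALSE)
  }
  cfg$config_hash <- config_hash(cfg)
  class(cfg) <- "study_config"
  cfg
}

config_hash <- function(cfg) {
  cfg$config_hash <- NULL
  cfg$output_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(
    jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE),
    tmp
  )
  unname(tools::md5sum(tmp))
}

#' Simulate a study: cohort, features and (optionally) core images
#'
#' Writes `cohort.csv` (one patient per row), `core_features.csv` (wide:
#' id columns plus one column per feature), optional PNG images under
#' `images/patient_id/core_k.png`, and a `manifest.json` recording row
#' counts, the config hash and the seeds used.
#'
#' @param config A [study_config()].
#' @return Invisibly, a list with `cohort`, `features`, `paths`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config$params)
  features <- generate_patient_features(cohort, config$params)

  cohort_path <- file.path(config$output_dir, "cohort.csv")
  utils::write.csv(cohort, cohort_path, row.names = FALSE)

  feat_df <- data.frame(
    patient_id = features$patient_id,
    core_id = features$core_id,
    stringsAsFactors = FALSE
  )
  fx <- as.data.frame(features$x)
  names(fx) <- sprintf("f%04d", seq_len(ncol(fx)))
  feat_path <- file.path(config$output_dir, "core_features.csv")
  utils::write.csv(cbind(feat_df, fx), feat_path, row.names = FALSE)

  image_paths <- NULL
  if (config$with_images) {
    ip <- config$image_params
    ip$seed <- ip$seed %||% substream_seed(config$seed, "images")
    imgs <- generate_core_images(cohort, ip)
    image_paths <- write_core_images(imgs, file.path(config$output_dir, "images"))
  }

  manifest <- list(
    config_hash = config$config_hash,
    seed = config$seed,
    n_patients = nrow(cohort),
    n_cases = sum(cohort$recurred_3yr),
    n_controls = sum(!cohort$recurred_3yr),
    n_cores = nrow(features$x),
    feature_dim = ncol(features$x),
    n_images = length(image_paths),
    files = c(cohort = "cohort.csv", features = "core_features.csv")
  )
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  invisible(list(
    cohort = cohort, features = features,
    paths = list(cohort = cohort_path, features = feat_path,
                 manifest = manifest_path, images = image_paths)
  ))
}

#' Read simulated core features back from CSV
#'
#' @param path A `core_features.csv` written by [simulate_study()].
#' @return A `core_features` object.
#' @export
read_core_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list(
    x = as.matrix(df[, grep("^f\\d+$", names(df)), drop = FALSE]),
    patient_id = df$patient_id,
    core_id = df$core_id
  )
  dimnames(out$x) <- NULL
  class(out) <- "core_features"
  out
}

subset_core_features <- function(cf, ids) {
  keep <- cf$patient_id %in% ids
  out <- list(
    x = cf$x[keep, , drop = FALSE],
    patient_id = cf$patient_id[keep],
    core_id = cf$core_id[keep]
  )
  class(out) <- "core_features"
  out
}

#' Run the full analysis pipeline on a (synthetic or supplied) study
#'
#' Executes: eligibility filters, 1:1 age-matched balanced set
#' construction, patient-level aggregation, cross-patient k-fold CV and
#' within-patient half-core validation, accuracy/sensitivity/specificity
#' with binomial CIs (overall and per grade stratum) including the grade
#' and ER comparator rules, full-cohort image-class assignment, KM and
#' Cox time-to-event analysis per scheme, and image-class x genomic-risk
#' RFD tables per scheme and assay. Writes a JSON report plus TSV
#' artifacts, all stamped with the config hash.
#'
#' @param config A [study_config()].
#' @param cohort Optional cohort data.frame (generated if `NULL`).
#' @param features Optional `core_features` (generated if `NULL`).
#' @return The report (list), invisibly also written to
#'   `output_dir/report.json`.
#' @export
run_study <- function(config, cohort = NULL, features = NULL) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[recurtma] ", ...)

  if (is.null(cohort)) cohort <- generate_cohort(config$params)
  if (is.null(features)) features <- generate_patient_features(cohort, config$params)

  # -- eligibility -----------------------------------------------------
  filt <- apply_eligibility_filters(cohort, config$filters)
  cohort <- filt$cohort
  if (nrow(filt$log)) {
    log_stage("eligibility: excluded ", sum(filt$log$n_excluded), " patients")
  }
  features <- subset_core_features(features, cohort$patient_id)

  # -- matched balanced set -------------------------------------------
  matched <- match_balanced(
    cohort,
    bin_width = config$matching$bin_width %||% 5,
    seed = config$seed,
    nearest_bin_fallback = isTRUE(config$matching$nearest_bin_fallback)
  )
  log_stage("matched ", nrow(matched$pairs), " case-control pairs")
  matched_ids <- matched$records$patient_id
  labels <- stats::setNames(cohort$recurred_3yr, cohort$patient_id)

  cf_matched <- subset_core_features(features, matched_ids)
  pf_matched <- patient_feature_matrix(cf_matched)
  y_matched <- as.logical(labels[pf_matched$patient_id])

  # -- validation schemes ---------------------------------------------
  cv <- cross_patient_cv(
    pf_matched$x, y_matched, ids = pf_matched$patient_id,
    k = config$k, regularization = config$regularization, seed = config$seed
  )
  within <- within_patient_split(
    cf_matched, labels,
    regularization = config$regularization, seed = config$seed
  )
  log_stage("validation: cross-patient acc ",
            round(mean(cv$pred == cv$true), 3),
            ", within-patient acc ", round(mean(within$pred == within$true), 3))

  # -- metrics ---------------------------------------------------------
  strat_cv <- stratified_evaluate(cv, cohort)
  strat_within <- stratified_evaluate(within, cohort)
  metrics <- rbind(
    metrics_row(summarize_confusion(biomarker_predictor(matched, "grade")), "grade"),
    metrics_row(summarize_confusion(biomarker_predictor(matched, "er")), "er"),
    metrics_row(summarize_confusion(strat_within$overall), "within_patient"),
    metrics_row(summarize_confusion(strat_cv$overall), "cross_patient")
  )
  strat_rows <- list()
  for (stratum in c("high_grade", "low_intermediate_grade")) {
    for (blk in list(list("cross_patient", strat_cv), list("within_patient", strat_within))) {
      cc <- blk[[2]][[stratum]]
      if (!is.null(cc)) {
        strat_rows[[length(strat_rows) + 1L]] <-
          metrics_row(summarize_confusion(cc), paste(blk[[1]], stratum, sep = "."))
      }
    }
  }
  metrics_strat <- if (length(strat_rows)) do.call(rbind, strat_rows) else NULL

  # -- full-cohort classes, survival, genomic association --------------
  pf_all <- patient_feature_matrix(features)
  classes_cv <- assign_full_cohort_classes(
    cv, matched_x = pf_matched$x, matched_y = y_matched,
    all_x = pf_all$x, all_ids = pf_all$patient_id,
    regularization = config$regularization
  )
  classes_within <- assign_full_cohort_classes(
    within, all_x = pf_all$x, all_ids = pf_all$patient_id,
    model = attr(within, "model")
  )

  survival_block <- function(classes, scheme) {
    grp <- factor(classes$image_class[match(cohort$patient_id, classes$patient_id)],
                  levels = c("low", "high"))
    km <- km_estimate(cohort$event_time, cohort$event_indicator, grp)
    cx <- tryCatch(
      cox_fit(cohort$event_time, cohort$event_indicator, grp),
      error = function(e) {
        log_stage("cox (", scheme, ") failed: ", conditionMessage(e))
        NULL
      }
    )
    list(km = km, cox = cx)
  }
  surv_cv <- survival_block(classes_cv, "cross_patient")
  surv_within <- survival_block(classes_within, "within_patient")

  rfd_block <- function(classes) {
    tabs <- build_risk_tables(classes, cohort)
    lapply(tabs, rfd_estimate)
  }
  rfd_cv <- rfd_block(classes_cv)
  rfd_within <- rfd_block(classes_within)
  log_stage("association: cross-patient ROR-PT RFD ",
            round(100 * rfd_cv$rorpt$rfd, 1), "%")

  # -- artifacts -------------------------------------------------------
  write_prediction_set(rbind(as.data.frame(cv), as.data.frame(within)),
                       file.path(config$output_dir, "predictions.tsv"))
  utils::write.table(metrics, file.path(config$output_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rbind(surv_cv$km, surv_within$km),
                     file.path(config$output_dir, "km.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cox_out <- function(cx) {
    if (is.null(cx)) return(NULL)
    list(hr = cx$hr, log_hr = cx$log_hr, se = cx$se,
         ci = unname(cx$ci), n_events = cx$n_events, ties = cx$ties_method)
  }
  rfd_out <- function(rl) {
    lapply(rl, function(r) list(
      rfd = r$rfd, ci = unname(r$ci), se = r$se,
      p_reference = r$p_reference, p_exposed = r$p_exposed
    ))
  }
  report <- list(
    config_hash = config$config_hash,
    seed = config$seed,
    n_patients = nrow(cohort),
    n_matched = length(matched_ids),
    exclusion_log = filt$log,
    accuracy = list(
      cross_patient = mean(cv$pred == cv$true),
      within_patient = mean(within$pred == within$true)
    ),
    metrics = metrics,
    metrics_by_grade = metrics_strat,
    cox = list(cross_patient = cox_out(surv_cv$cox),
               within_patient = cox_out(surv_within$cox)),
    rfd = list(cross_patient = rfd_out(rfd_cv),
               within_patient = rfd_out(rfd_within))
  )
  jsonlite::write_json(
    report, file.path(config$output_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", force = TRUE
  )
  invisible(report)
}
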