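test_that("leave-one-out on separable patients is perfect and ordinary k errors correctly", {
  s <- separable_xy(n_per = 3)
  ids <- sprintf("P%d", 1:6)
  cv <- cross_patient_cv(s$x, s$y, ids = ids, k = 6, seed = 1)
  expect_equal(mean(cv$pred == cv$true), 1.0)
  expect_error(cross_patient_cv(s$x, s$y, ids = ids, k = 5, seed = 1),
               "smaller class")
  expect_error(cross_patient_cv(s$x, s$y, ids = ids, k = 1, seed = 1), ">= 2")
})

test_that("zero-signal cross-validation accuracy is at chance", {
  st <- balanced_study(n = 200, seed = 19, signal = 0)
  cv <- cross_patient_cv(st$pf$x, st$y, ids = st$pf$patient_id, k = 10, seed = 19)
  acc <- mean(cv$pred == cv$true)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 200))
})

test_that("cross-validation is deterministic and leak-free by construction", {
  st <- balanced_study(n = 60, seed = 23, feature_dim = 64)
  cv1 <- cross_patient_cv(st$pf$x, st$y, ids = st$pf$patient_id, k = 5, seed = 4)
  cv2 <- cross_patient_cv(st$pf$x, st$y, ids = st$pf$patient_id, k = 5, seed = 4)
  expect_identical(as.data.frame(cv1), as.data.frame(cv2))
  # every matched patient appears exactly once as a test case
  expect_setequal(cv1$patient_id, st$pf$patient_id)
  expect_equal(anyDuplicated(cv1$patient_id), 0)
  # the model that predicts fold f was never trained on fold f's ids
  train_ids <- attr(cv1, "fold_train_ids")
  for (f in unique(cv1$fold)) {
    test_ids <- cv1$patient_id[cv1$fold == f]
    expect_length(intersect(test_ids, train_ids[[f]]), 0)
  }
})

test_that("within-patient split trains and tests on disjoint core halves", {
  st <- balanced_study(n = 40, seed = 29, feature_dim = 32)
  w <- within_patient_split(st$cf, st$labels, seed = 3)
  split <- attr(w, "split")
  # ceil-to-train: a 3-core patient contributes 2 training, 1 test core
  odd <- split[split$n_train + split$n_test == 3, ]
  if (nrow(odd)) {
    expect_true(all(odd$n_train == 2 & odd$n_test == 1))
  }
  expect_true(all(split$n_train >= split$n_test))
  for (i in seq_len(nrow(split))) {
    tr <- strsplit(split$train_cores[i], ",")[[1]]
    te <- strsplit(split$test_cores[i], ",")[[1]]
    expect_length(intersect(tr, te), 0)
  }
  expect_setequal(w$patient_id, unique(st$cf$patient_id))
})

test_that("identical cores with separable labels give perfect within-patient accuracy", {
  x <- rbind(c(5, 5), c(5, 5), c(-5, -5), c(-5, -5),
             c(5, 6), c(5, 6), c(-5, -6), c(-5, -6))
  cf <- list(x = x, patient_id = rep(c("a", "b", "c", "d"), each = 2),
             core_id = rep(c("core_1", "core_2"), 4))
  labels <- c(a = TRUE, b = FALSE, c = TRUE, d = FALSE)
  w <- within_patient_split(cf, labels, seed = 1)
  expect_equal(mean(w$pred == w$true), 1.0)
})

test_that("patients with fewer than two cores are excluded, or error when strict", {
  cf <- list(
    x = matrix(rnorm(10), 5, 2),
    patient_id = c("a", "a", "b", "b", "solo"),
    core_id = c("core_1", "core_2", "core_1", "core_2", "core_1")
  )
  labels <- c(a = TRUE, b = FALSE, solo = TRUE)
  expect_warning(w <- within_patient_split(cf, labels, seed = 1), "solo")
  expect_false("solo" %in% w$patient_id)
  expect_error(within_patient_split(cf, labels, seed = 1, strict = TRUE), "solo")
})

test_that("grade-stratified confusion counts conserve the overall tally", {
  st <- balanced_study(n = 80, seed = 37, feature_dim = 64)
  cv <- cross_patient_cv(st$pf$x, st$y, ids = st$pf$patient_id, k = 5, seed = 5)
  strat <- stratified_evaluate(cv, st$cohort)
  for (fld in c("tp", "fp", "tn", "fn")) {
    expect_equal(strat$high_grade[[fld]] + strat$low_intermediate_grade[[fld]],
                 strat$overall[[fld]])
  }
  # brute-force row filter oracle for the high-grade stratum
  grade <- st$cohort$grade[match(cv$patient_id, st$cohort$patient_id)]
  sel <- grade == 3
  expect_equal(strat$high_grade$tp, sum(cv$true[sel] & cv$pred[sel]))
  expect_equal(strat$high_grade$tn, sum(!cv$true[sel] & !cv$pred[sel]))
})

test_that("an empty stratum is flagged as missing, not zero", {
  co <- tiny_cohort(6, rep(c(TRUE, FALSE), 3), grade = rep(3L, 6))
  preds <- structure(
    data.frame(
      patient_id = co$patient_id, scheme = "cross_patient", fold = 1L,
      true = co$recurred_3yr, pred = co$recurred_3yr, decision = 0,
      stringsAsFactors = FALSE
    ),
    class = c("prediction_set", "data.frame")
  )
  strat <- stratified_evaluate(preds, co)
  expect_null(strat$low_intermediate_grade)
  expect_equal(strat$missing_strata, "low_intermediate_grade")
})

test_that("k-fold sweep is deterministic and beats chance at both ends on signal", {
  st <- balanced_study(n = 120, seed = 41, signal = 15, feature_dim = 128)
  sw1 <- kfold_sweep(st$pf$x, st$y, ids = st$pf$patient_id,
                     k_values = c(2L, 10L), seed = 2)
  sw2 <- kfold_sweep(st$pf$x, st$y, ids = st$pf$patient_id,
                     k_values = c(2L, 10L), seed = 2)
  expect_identical(sw1, sw2)
  expect_gt(sw1[["k2"]], 0.5)
  expect_gt(sw1[["k10"]], 0.5)
})

test_that("mean accuracy does not fall from 2-fold to 10-fold over repeated fold draws", {
  st <- balanced_study(n = 202, seed = 43)
  accs <- vapply(1:20, function(sd) {
    kfold_sweep(st$pf$x, st$y, ids = st$pf$patient_id,
                k_values = c(2L, 10L), seed = sd)
  }, numeric(2))
  expect_gte(mean(accs["k10", ]), mean(accs["k2", ]))
})

test_that("full-cohort class assignment reuses held-out predictions and covers everyone", {
  p <- synthetic_params(n_patients = 400, seed = 47)
  cohort <- generate_cohort(p)
  cf <- generate_patient_features(cohort, p)
  pf_all <- patient_feature_matrix(cf)
  labels <- stats::setNames(cohort$recurred_3yr, cohort$patient_id)
  matched <- match_balanced(cohort, seed = 47)
  cf_m <- recurtma:::subset_core_features(cf, matched$records$patient_id)
  pf_m <- patient_feature_matrix(cf_m)
  y_m <- as.logical(labels[pf_m$patient_id])
  cv <- cross_patient_cv(pf_m$x, y_m, ids = pf_m$patient_id, k = 5, seed = 47)
  classes <- assign_full_cohort_classes(
    cv, matched_x = pf_m$x, matched_y = y_m,
    all_x = pf_all$x, all_ids = pf_all$patient_id
  )
  expect_setequal(classes$patient_id, cohort$patient_id)
  expect_equal(sum(table(classes$image_class)), nrow(cohort))
  m <- match(cv$patient_id, classes$patient_id)
  expect_equal(classes$image_class[m], ifelse(cv$pred, "high", "low"))
  expect_true(all(classes$source[m] == "held_out"))
  expect_true(all(classes$source[-m] == "model"))
})
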