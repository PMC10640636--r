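test_that("degenerate recurrence rate yields an all-censored cohort", {
  p <- synthetic_params(n_patients = 50, recurrence_rate = 0, seed = 3)
  co <- generate_cohort(p)
  expect_equal(nrow(co), 50)
  expect_false(any(co$recurred_3yr))
  expect_false(any(co$event_indicator))
  expect_true(all(co$event_time >= 36))
})

test_that("recurrence fraction and conditional grade distribution match their targets", {
  p <- synthetic_params(n_patients = 10000, seed = 42)
  co <- generate_cohort(p)
  p_hat <- mean(co$recurred_3yr)
  se <- sqrt(0.07 * 0.93 / 10000)
  expect_lt(abs(p_hat - 0.07), 3 * se)

  rec <- co[co$recurred_3yr, ]
  g3 <- mean(rec$grade == 3)
  target <- 74 / 101
  se_g <- sqrt(target * (1 - target) / nrow(rec))
  expect_lt(abs(g3 - target), 3 * se_g)

  er_neg <- mean(rec$er == "negative")
  target_er <- 57 / 101
  expect_lt(abs(er_neg - target_er), 3 * sqrt(target_er * (1 - target_er) / nrow(rec)))
})

test_that("cohort invariants hold: times positive, early recurrence implies event by 36 months", {
  co <- generate_cohort(synthetic_params(n_patients = 500, seed = 8))
  expect_true(all(co$event_time > 0))
  expect_true(all(co$event_time[co$recurred_3yr] <= 36))
  expect_true(all(co$event_indicator[co$recurred_3yr]))
  expect_true(all(co$grade %in% 1:3))
  expect_true(all(co$er %in% c("positive", "negative")))
  expect_true(all(co$oncotype_cat %in% c("low-intermediate", "high", NA)))
})

test_that("identical params and seed reproduce cohorts and features bitwise", {
  p <- synthetic_params(n_patients = 60, seed = 123)
  expect_identical(generate_cohort(p), generate_cohort(p))
  co <- generate_cohort(p)
  f1 <- generate_patient_features(co, p)
  f2 <- generate_patient_features(co, p)
  expect_identical(f1$x, f2$x)
})

test_that("parameter validation rejects invalid probability tables and cosine targets", {
  expect_error(synthetic_params(recurrence_rate = 1.3), "probability")
  expect_error(
    synthetic_params(grade_given_recurrence = list(
      recurrent = c(0.5, 0.2, 0.2), nonrecurrent = c(1, 0, 0) / 1
    )),
    "sum to 1"
  )
  expect_error(
    synthetic_params(within_cos_target = 0.8, between_cos_target = 0.84),
    "exceed"
  )
  p <- synthetic_params(n_patients = 10, seed = 1)
  p$within_cos_target <- 0.5  # corrupt after construction
  expect_error(generate_patient_features(tiny_cohort(4, rep(c(TRUE, FALSE), 2)), p),
               "exceed")
})

test_that("cosine calibration converges to the 0.91 / 0.84 targets at n = 500", {
  p <- synthetic_params(n_patients = 500, seed = 7)
  co <- generate_cohort(p)
  st <- cosine_similarity_stats(generate_patient_features(co, p))
  expect_lt(abs(st$within_mean - 0.91), 0.02)
  expect_lt(abs(st$between_mean - 0.84), 0.02)
})

test_that("zero core noise (within target 1) makes a patient's cores identical", {
  p <- synthetic_params(
    n_patients = 6, balanced = TRUE, within_cos_target = 1,
    between_cos_target = 0.84, feature_dim = 32, seed = 5
  )
  co <- generate_cohort(p)
  cf <- generate_patient_features(co, p)
  rows <- which(cf$patient_id == cf$patient_id[1])
  for (r in rows[-1]) expect_equal(cf$x[r, ], cf$x[rows[1], ])
  st <- cosine_similarity_stats(cf)
  expect_equal(st$within_mean, 1.0, tolerance = 1e-12)
})

test_that("label-signal monotonicity: CV accuracy is non-decreasing in signal strength", {
  acc <- vapply(c(0, 3, 15), function(s) {
    mean(vapply(1:3, function(sd) {
      st <- balanced_study(n = 120, seed = sd, signal = s, feature_dim = 128)
      cv <- cross_patient_cv(st$pf$x, st$y, ids = st$pf$patient_id, k = 5, seed = sd)
      mean(cv$pred == cv$true)
    }, numeric(1)))
  }, numeric(1))
  # stochastic tolerance: allow small inversions, require a clear overall rise
  expect_gt(acc[2], acc[1] - 0.05)
  expect_gt(acc[3], acc[2] - 0.05)
  expect_gt(acc[3], acc[1] + 0.1)
})

test_that("toy core images have the right shapes and deterministic content", {
  co <- tiny_cohort(2, c(TRUE, FALSE))
  imgs <- generate_core_images(co, list(size = 128, seed = 11))
  expect_length(imgs$images, 4)  # 2 patients x 2 cores
  expect_equal(dim(imgs$images[[1]]), c(128, 128, 3))
  expect_equal(nrow(imgs$ids), 4)
  imgs2 <- generate_core_images(co, list(size = 128, seed = 11))
  expect_identical(imgs$images, imgs2$images)
  expect_error(generate_core_images(co, list(size = 32)), ">= 64")
})

test_that("constant risk latent produces no systematic nuclei-density difference", {
  co <- tiny_cohort(50, rep(c(TRUE, FALSE), 25))
  imgs <- generate_core_images(co, list(size = 64, risk = rep(0, 50), seed = 2))
  frac <- vapply(imgs$images, count_dark_pixels, numeric(1)) / (64 * 64)
  grp <- co$recurred_3yr[match(imgs$ids$patient_id, co$patient_id)]
  d <- mean(frac[grp]) - mean(frac[!grp])
  se <- sqrt(var(frac[grp]) / sum(grp) + var(frac[!grp]) / sum(!grp))
  expect_lt(abs(d), 3 * se)
})

test_that("high-risk patients get denser nuclei fields than low-risk patients", {
  co <- tiny_cohort(50, rep(c(TRUE, FALSE), 25))
  risk <- ifelse(co$recurred_3yr, 1, -1)
  imgs <- generate_core_images(co, list(size = 64, risk = risk, seed = 3))
  frac <- vapply(imgs$images, count_dark_pixels, numeric(1)) / (64 * 64)
  grp <- co$recurred_3yr[match(imgs$ids$patient_id, co$patient_id)]
  expect_gt(mean(frac[grp]), mean(frac[!grp]))
  # painted-pixel attribute agrees in direction with the luminance count
  painted <- vapply(imgs$images, function(im) attr(im, "n_nuclei_pixels"), numeric(1))
  expect_gt(mean(painted[grp]), mean(painted[!grp]))
})

test_that("survival cohort generator hits its target event rate and group mix", {
  d <- generate_survival_cohort(4000, hr = 2.7, target_event_rate = 0.07, seed = 9)
  expect_lt(abs(mean(d$event) - 0.07), 3 * sqrt(0.07 * 0.93 / 4000))
  expect_lt(abs(mean(d$group == "high") - 0.45), 3 * sqrt(0.45 * 0.55 / 4000))
  expect_true(all(d$time > 0 & d$time <= 36))
  expect_identical(levels(d$group), c("low", "high"))
})
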