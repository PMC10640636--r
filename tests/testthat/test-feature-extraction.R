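test_that("channel standardization has the two-point, constant and random-moment properties", {
  img <- array(0, c(4, 4, 3))
  img[, , 1] <- matrix(rep(c(0, 2), 8), 4, 4)  # half 0, half 2
  img[, , 2] <- 0.7                             # constant channel
  img[, , 3] <- matrix(rnorm(16), 4, 4)
  out <- standardize_channels(img)
  expect_setequal(unique(as.vector(out[, , 1])), c(-1, 1))
  expect_true(all(out[, , 2] == 0))

  set.seed(1)
  rnd <- array(runif(64 * 64 * 3), c(64, 64, 3))
  std <- standardize_channels(rnd)
  for (ch in 1:3) {
    v <- std[, , ch]
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-6)
  }
  expect_error(standardize_channels(array(0, c(4, 4, 2))), "RGB")
})

test_that("identity extractor at layer 0 returns the pixels channels-first", {
  img <- array(runif(8 * 6 * 3), c(8, 6, 3))
  fm <- extract_features(img, identity_extractor(), 0)
  expect_equal(fm$values, aperm(img, c(3, 1, 2)))
  expect_error(extract_features(img, identity_extractor(), 1), "layer_index")
})

test_that("toy extractor is bitwise deterministic across constructions and runs", {
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  e1 <- toy_extractor(seed = 42)
  e2 <- toy_extractor(seed = 42)
  expect_identical(
    extract_features(img, e1, 5)$values,
    extract_features(img, e2, 5)$values
  )
  expect_false(identical(
    extract_features(img, e1, 3)$values,
    extract_features(img, toy_extractor(seed = 43), 3)$values
  ))
})

test_that("a corner-pixel change only perturbs the corner's receptive field", {
  set.seed(2)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  ex <- toy_extractor()
  layer <- 3L  # conv2
  rf <- receptive_field(ex, layer)
  base <- extract_features(img, ex, layer)$values
  img2 <- img
  img2[1, 1, ] <- img2[1, 1, ] + 1
  pert <- extract_features(img2, ex, layer)$values
  diff <- apply(abs(pert - base), c(2, 3), max)
  changed <- which(diff > 1e-12, arr.ind = TRUE)
  expect_gt(nrow(changed), 0)
  # output (i,j) sees input rows [(i-1)*stride + 1, (i-1)*stride + size]
  starts_r <- (changed[, 1] - 1) * rf$stride + 1
  starts_c <- (changed[, 2] - 1) * rf$stride + 1
  expect_true(all(starts_r <= 1 & 1 <= starts_r + rf$size - 1))
  expect_true(all(starts_c <= 1 & 1 <= starts_c + rf$size - 1))
})

test_that("spatial mean pooling equals an explicit double loop and respects trivia", {
  fm_const <- structure(
    list(values = array(3.3, c(4, 5, 6)), extractor_id = "x", layer_index = 1L),
    class = "feature_map"
  )
  expect_equal(spatial_mean_pool(fm_const), rep(3.3, 4))

  fm1 <- structure(
    list(values = array(c(1, 2, 3, 4), c(1, 2, 2)), extractor_id = "x", layer_index = 1L),
    class = "feature_map"
  )
  expect_equal(spatial_mean_pool(fm1), 2.5)

  set.seed(3)
  v <- array(rnorm(8 * 4 * 4), c(8, 4, 4))
  fm <- structure(list(values = v, extractor_id = "x", layer_index = 1L),
                  class = "feature_map")
  pooled <- spatial_mean_pool(fm)
  oracle <- numeric(8)
  for (c in 1:8) {
    acc <- 0
    for (i in 1:4) for (j in 1:4) acc <- acc + v[c, i, j]
    oracle[c] <- acc / 16
  }
  expect_equal(pooled, oracle, tolerance = 1e-12)

  # commutes with channel permutation
  perm <- sample(8)
  fm_p <- structure(list(values = v[perm, , , drop = FALSE], extractor_id = "x",
                         layer_index = 1L), class = "feature_map")
  expect_equal(spatial_mean_pool(fm_p), pooled[perm])
})

test_that("patient aggregation is the element-wise mean, invariant to core order", {
  one <- aggregate_patient(list(c(1, 2, 3)), label = TRUE)
  expect_equal(one$vector, c(1, 2, 3))
  expect_true(one$label)

  two <- aggregate_patient(list(c(0, 0), c(2, 2)))
  expect_equal(two$vector, c(1, 1))

  set.seed(4)
  cores <- lapply(1:4, function(i) rnorm(12))
  agg <- aggregate_patient(cores)
  oracle <- colMeans(do.call(rbind, cores))
  expect_equal(agg$vector, oracle, tolerance = 1e-12)
  expect_equal(aggregate_patient(rev(cores))$vector, agg$vector)

  expect_error(aggregate_patient(list(c(1, 2), c(1, 2, 3))), "length")
  expect_error(aggregate_patient(list()), "at least one")
})

test_that("cosine similarity statistics handle the degenerate and synthetic cases", {
  cf_same <- list(x = matrix(1, 4, 3), patient_id = c("a", "a", "b", "b"),
                  core_id = paste0("c", 1:4))
  st <- cosine_similarity_stats(cf_same)
  expect_equal(st$within_mean, 1.0)
  expect_equal(st$between_mean, 1.0)

  cf_orth <- list(
    x = rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)),
    patient_id = c("a", "a", "b", "b"), core_id = paste0("c", 1:4)
  )
  st2 <- cosine_similarity_stats(cf_orth)
  expect_equal(st2$within_mean, 1.0)
  expect_equal(st2$between_mean, 0.0)

  st3 <- cosine_similarity_stats(balanced_study(n = 60, seed = 6, feature_dim = 64)$cf)
  expect_gt(st3$within_mean, st3$between_mean)

  cf_zero <- list(
    x = rbind(c(1, 0), c(1, 1), c(0, 0), c(0, 1), c(1, 0)),
    patient_id = c("a", "a", "b", "b", "b"), core_id = paste0("c", 1:5)
  )
  expect_warning(st4 <- cosine_similarity_stats(cf_zero), "zero-norm")
  expect_equal(st4$n_within_pairs, 2)  # the zero-norm core of b is gone
})

test_that("pipeline composition standardize -> extract -> pool -> aggregate is deterministic", {
  set.seed(5)
  imgs <- lapply(1:2, function(i) array(runif(64 * 64 * 3), c(64, 64, 3)))
  ex <- toy_extractor()
  run <- function() {
    vecs <- lapply(imgs, function(im) {
      spatial_mean_pool(extract_features(standardize_channels(im), ex, 4))
    })
    aggregate_patient(vecs)$vector
  }
  expect_identical(run(), run())
})

test_that("layer selection picks the signal-bearing layer and breaks ties low", {
  expect_equal(as.integer(select_layer(candidate_layers = 5, labels = NULL)), 5L)

  n <- 40
  y <- stats::setNames(rep(c(TRUE, FALSE), each = n / 2), sprintf("P%02d", 1:n))
  wins <- 0L
  for (sd in 1:20) {
    set.seed(sd)
    noise <- matrix(rnorm(n * 10), n, 10, dimnames = list(names(y), NULL))
    signal <- matrix(rnorm(n * 10), n, 10, dimnames = list(names(y), NULL))
    signal[y, 1] <- signal[y, 1] + 4
    pick <- select_layer(
      labels = y, candidate_layers = c(1, 2),
      features_by_layer = list(noise, signal), seed = sd
    )
    if (as.integer(pick) == 2L) wins <- wins + 1L
  }
  expect_gte(wins, 19L)

  # identical layers tie -> lower index
  set.seed(21)
  same <- matrix(rnorm(n * 10), n, 10, dimnames = list(names(y), NULL))
  same[y, 1] <- same[y, 1] + 4
  pick <- select_layer(labels = y, candidate_layers = c(3, 7),
                       features_by_layer = list(same, same), seed = 1)
  expect_equal(as.integer(pick), 3L)
})

test_that("images written as PNG round-trip through the reader", {
  co <- tiny_cohort(1, TRUE)
  imgs <- generate_core_images(co, list(size = 64, seed = 4))
  dir <- withr::local_tempdir()
  paths <- write_core_images(imgs, dir)
  expect_true(all(file.exists(paths)))
  back <- read_core_image(paths[1])
  expect_equal(dim(back), c(64, 64, 3))
  expect_lt(max(abs(back - imgs$images[[1]])), 1 / 255)  # 8-bit quantization
})
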