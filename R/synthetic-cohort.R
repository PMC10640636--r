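#' Generate a synthetic breast-cancer cohort
#'
#' Simulates one patient per row with the clinical, outcome and genomic
#' fields used by the downstream analysis. Early recurrence is drawn at
#' `recurrence_rate` (or fixed at 50% of patients in balanced mode), grade
#' and ER status are drawn from their conditional distributions given
#' recurrence, recurrence times are uniform on (0, 36] months, and
#' non-recurrent patients are administratively censored at `censor_horizon`.
#' Each patient also carries a standard-normal latent (`risk_latent`) that
#' the feature and image generators reuse, so that genomic risk categories
#' can share signal with the image features (controlled by the
#' `genomic_enrichment` leakage parameters).
#'
#' @param params A [synthetic_params()] object.
#' @return A data.frame with one row per patient. Columns: `patient_id`,
#'   `age`, `race`, `grade`, `stage`, `er`, `pr`, `her2`, `recurred_3yr`,
#'   `event_time`, `event_indicator`, `oncotype_cat`, `rorpt_cat`,
#'   `n_cores`, `risk_latent`.
#' @export
generate_cohort <- function(params) {
  validate_synthetic_params(params)
  n <- params$n_patients
  with_seed(substream_seed(params$seed, "cohort"), {
    if (params$balanced) {
      n_case <- n %/% 2L
      recurred <- rep(c(TRUE, FALSE), each = n_case)
      age_case <- pmin(74, pmax(20, round(stats::rnorm(n_case, 51.5, 10.7))))
      # controls share the case's 5-year age bin, emulating matched sampling
      bin_lo <- (age_case %/% 5L) * 5L
      age_ctrl <- pmin(74L, bin_lo + sample.int(5L, n_case, replace = TRUE) - 1L)
      age <- c(age_case, age_ctrl)
    } else {
      recurred <- stats::runif(n) < params$recurrence_rate
      age <- pmin(74, pmax(20, round(
        ifelse(recurred, stats::rnorm(n, 51.5, 10.7), stats::rnorm(n, 52.8, 11.2))
      )))
    }

    # conditional draws: sample both arms, pick per patient
    grade_rec <- sample(1:3, n, replace = TRUE, prob = params$grade_given_recurrence$recurrent)
    grade_non <- sample(1:3, n, replace = TRUE, prob = params$grade_given_recurrence$nonrecurrent)
    grade <- ifelse(recurred, grade_rec, grade_non)
    er <- ifelse(
      stats::runif(n) < ifelse(recurred,
        params$er_given_recurrence$recurrent,
        params$er_given_recurrence$nonrecurrent
      ),
      "positive", "negative"
    )
    stage_rec <- sample(1:3, n, replace = TRUE, prob = c(0.109, 0.515, 0.376))
    stage_non <- sample(1:3, n, replace = TRUE, prob = c(0.478, 0.419, 0.103))
    stage <- ifelse(recurred, stage_rec, stage_non)
    race <- ifelse(stats::runif(n) < ifelse(recurred, 0.653, 0.472), "Black", "Non-Black")
    pr_status <- ifelse(stats::runif(n) < ifelse(recurred, 0.297, 0.688), "positive", "negative")
    her2 <- ifelse(stats::runif(n) < ifelse(recurred, 0.168, 0.143), "positive", "negative")

    event_time <- ifelse(recurred, stats::runif(n, 0, 36), params$censor_horizon)
    event_time[recurred & event_time == 0] <- 1e-6  # open at zero
    n_cores <- sample(seq(params$cores_min, params$cores_max), n, replace = TRUE)
    risk_latent <- stats::rnorm(n)

    # genomic categories share the image-signal latent (label + patient latent)
    sig <- as.numeric(recurred) + 0.5 * risk_latent
    sig <- if (stats::sd(sig) > 0) (sig - mean(sig)) / stats::sd(sig) else sig * 0
    draw_assay <- function(ge) {
      p_high <- stats::plogis(stats::qlogis(ge$p_high) + ge$leakage * sig)
      cat <- ifelse(stats::runif(n) < p_high, "high", "low-intermediate")
      cat[stats::runif(n) < ge$p_missing] <- NA_character_
      cat
    }
    oncotype_cat <- draw_assay(params$genomic_enrichment$oncotype)
    rorpt_cat <- draw_assay(params$genomic_enrichment$rorpt)

    data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      age = as.numeric(age),
      race = race,
      grade = as.integer(grade),
      stage = as.integer(stage),
      er = er,
      pr = pr_status,
      her2 = her2,
      recurred_3yr = recurred,
      event_time = event_time,
      event_indicator = recurred,
      oncotype_cat = oncotype_cat,
      rorpt_cat = rorpt_cat,
      n_cores = as.integer(n_cores),
      risk_latent = risk_latent,
      stringsAsFactors = FALSE
    )
  })
}

#' Solve the feature-noise scales for the cosine-similarity targets
#'
#' Under the isotropic model (unit-norm patient latent plus N(0, sigma^2 I)
#' core noise) the expected within-patient cosine similarity is
#' 1 / (1 + sigma^2 d), which gives sigma in closed form. The
#' between-patient similarity further depends on the patient-specific
#' latent scale tau and the label shift beta = signal_strength * tau; tau is
#' found by a 1-D root search on the analytic expectation.
#'
#' @param params A [synthetic_params()] object.
#' @param p_bar Recurrence fraction in the cohort being generated.
#' @return List with `sigma` (core noise SD per coordinate), `tau`
#'   (patient latent SD per coordinate) and `beta` (label shift magnitude).
#' @keywords internal
calibrate_feature_scales <- function(params, p_bar) {
  d <- params$feature_dim
  w <- params$within_cos_target
  b <- params$between_cos_target
  s <- params$signal_strength
  sigma2 <- (1 / w - 1) / d
  rho_target <- b / w  # required expected latent-latent cosine

  exp_latent_cos <- function(tau) {
    beta2 <- (s * tau)^2
    nrm <- function(y) sqrt(1 + beta2 * y + tau^2 * d)
    # average over the four label-pair combinations
    pp <- p_bar^2 * (1 + beta2) / nrm(1)^2
    pn <- 2 * p_bar * (1 - p_bar) * 1 / (nrm(1) * nrm(0))
    nn <- (1 - p_bar)^2 * 1 / nrm(0)^2
    pp + pn + nn
  }
  f <- function(tau) exp_latent_cos(tau) - rho_target
  if (f(1e-9) < 0) stop("cosine targets infeasible", call. = FALSE)
  tau <- stats::uniroot(f, c(1e-9, 5), tol = 1e-12)$root
  list(sigma = sqrt(sigma2), tau = tau, beta = s * tau)
}

#' Generate per-core feature vectors for a cohort
#'
#' Each patient receives a unit-norm latent vector: a shared population
#' direction, plus an isotropic patient-specific component of per-coordinate
#' SD `tau`, plus a recurrence-label shift of magnitude `beta` along a fixed
#' signal direction. The patient's `risk_latent` from [generate_cohort()] is
#' used as the patient-specific coefficient on the signal direction, so
#' image features and genomic categories share one latent. Each core is the
#' patient latent plus independent isotropic noise; the noise and latent
#' scales are calibrated so the expected within- and between-patient cosine
#' similarities match the targets in `params`.
#'
#' @param cohort Data frame from [generate_cohort()].
#' @param params A [synthetic_params()] object.
#' @return An object of class `core_features`: list with `x` (matrix,
#'   total cores x feature_dim), `patient_id`, `core_id` (character
#'   vectors, one entry per row of `x`).
#' @export
generate_patient_features <- function(cohort, params) {
  validate_synthetic_params(params)
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  d <- params$feature_dim
  p_bar <- mean(cohort$recurred_3yr)
  sc <- calibrate_feature_scales(params, p_bar)

  with_seed(substream_seed(params$seed, "features"), {
    n <- nrow(cohort)
    g <- c(1, rep(0, d - 1))   # shared population direction
    e <- c(0, 1, rep(0, d - 2))  # label-signal direction, orthogonal to g
    n_cores <- cohort$n_cores
    total <- sum(n_cores)

    # patient latents: e-coefficient reuses the cohort's stored risk_latent
    P <- matrix(stats::rnorm(n * d, sd = sc$tau), n, d)
    P[, 2] <- sc$tau * cohort$risk_latent
    M <- P
    M[, 1] <- M[, 1] + 1
    M[, 2] <- M[, 2] + sc$beta * as.numeric(cohort$recurred_3yr)
    L <- M / sqrt(rowSums(M^2))

    idx <- rep(seq_len(n), n_cores)
    noise <- if (sc$sigma > 0) {
      matrix(stats::rnorm(total * d, sd = sc$sigma), total, d)
    } else {
      matrix(0, total, d)
    }
    x <- L[idx, , drop = FALSE] + noise
    core_id <- unlist(lapply(n_cores, seq_len), use.names = FALSE)
    out <- list(
      x = x,
      patient_id = cohort$patient_id[idx],
      core_id = sprintf("core_%d", core_id)
    )
    attr(out, "scales") <- sc
    class(out) <- "core_features"
    out
  })
}

#' @export
print.core_features <- function(x, ...) {
  cat(
    "core_features:", nrow(x$x), "cores,",
    length(unique(x$patient_id)), "patients, dim", ncol(x$x), "\n"
  )
  invisible(x)
}

#' Generate toy H&E-like core images for a cohort
#'
#' Paints textured elliptical "nuclei" on a pink background; the number of
#' nuclei per core increases monotonically with the patient's image-signal
#' latent (recurrence label plus `risk_latent`), so high-risk patients have
#' denser cores. These are caricatures used to exercise the image path, not
#' realistic histology.
#'
#' @param cohort Data frame from [generate_cohort()].
#' @param image_params List with `size` (square image side in pixels,
#'   >= 64), `base_nuclei` (mean nucleus count at average risk),
#'   `density_slope` (relative increase per SD of risk), `noise_sd`
#'   (texture noise SD), and optionally `seed` (defaults to a substream of
#'   the cohort seed) and `risk` (override vector of per-patient risk
#'   latents; e.g. constant for a null construction).
#' @return List with `images` (list of size x size x 3 arrays in `[0,1]`,
#'   each carrying an `n_nuclei_pixels` attribute counting painted pixels)
#'   and `ids` (data.frame with `patient_id`, `core_id`).
#' @export
generate_core_images <- function(cohort, image_params = list()) {
  size <- as.integer(image_params$size %||% 128L)
  if (size < 64L) stop("image size must be >= 64", call. = FALSE)
  base_nuclei <- image_params$base_nuclei %||% 40
  slope <- image_params$density_slope %||% 0.35
  noise_sd <- image_params$noise_sd %||% 0.02
  seed <- image_params$seed %||% substream_seed(1L, "images")

  risk <- image_params$risk %||%
    (as.numeric(cohort$recurred_3yr) + 0.5 * cohort$risk_latent)
  s_risk <- stats::sd(risk)
  risk <- if (is.finite(s_risk) && s_risk > 0) (risk - mean(risk)) / s_risk else risk * 0

  bg <- c(0.95, 0.80, 0.85)   # eosin-pink background
  fg <- c(0.35, 0.25, 0.55)   # hematoxylin-purple nuclei

  with_seed(seed, {
    images <- list()
    pid <- character(0)
    cid <- character(0)
    xg <- matrix(rep(seq_len(size), size), size, size)
    yg <- t(xg)
    for (i in seq_len(nrow(cohort))) {
      n_nuc <- max(1L, round(base_nuclei * (1 + slope * risk[i])))
      for (k in seq_len(cohort$n_cores[i])) {
        img <- array(rep(bg, each = size * size), c(size, size, 3))
        mask <- matrix(FALSE, size, size)
        for (j in seq_len(n_nuc)) {
          cx <- stats::runif(1, 1, size)
          cy <- stats::runif(1, 1, size)
          a <- stats::runif(1, 2, 4.5)
          b <- stats::runif(1, 2, 4.5)
          th <- stats::runif(1, 0, pi)
          u <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
          v <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
          mask <- mask | (u^2 / a^2 + v^2 / b^2 <= 1)
        }
        for (ch in 1:3) {
          pl <- img[, , ch]
          pl[mask] <- fg[ch]
          img[, , ch] <- pl
        }
        img <- img + array(stats::rnorm(size * size * 3, sd = noise_sd), dim(img))
        img <- array(pmin(pmax(img, 0), 1), dim(img))
        attr(img, "n_nuclei_pixels") <- sum(mask)
        images[[length(images) + 1L]] <- img
        pid <- c(pid, cohort$patient_id[i])
        cid <- c(cid, sprintf("core_%d", k))
      }
    }
    list(images = images, ids = data.frame(
      patient_id = pid, core_id = cid, stringsAsFactors = FALSE
    ))
  })
}

#' Write core images as PNG files in patient_id/core_k.png layout
#'
#' @param imgs Result of [generate_core_images()].
#' @param dir Output directory.
#' @return Invisibly, the vector of written paths.
#' @export
write_core_images <- function(imgs, dir) {
  paths <- character(nrow(imgs$ids))
  for (i in seq_along(imgs$images)) {
    pdir <- file.path(dir, imgs$ids$patient_id[i])
    dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
    paths[i] <- file.path(pdir, paste0(imgs$ids$core_id[i], ".png"))
    png::writePNG(imgs$images[[i]], paths[i])
  }
  invisible(paths)
}

#' Generate a synthetic survival cohort with a known hazard ratio
#'
#' Two-group exponential times-to-recurrence with a specified true hazard
#' ratio for the high-risk group and administrative censoring at `horizon`;
#' the baseline hazard is solved so that the expected overall event
#' fraction matches `target_event_rate`. Used for hazard-ratio recovery
#' experiments.
#'
#' @param n Number of patients.
#' @param hr True hazard ratio (high vs low group).
#' @param p_group Probability of membership in the high-risk group.
#' @param target_event_rate Expected overall event fraction by `horizon`.
#' @param horizon Administrative censoring time in months.
#' @param seed Integer seed.
#' @return data.frame with `time`, `event`, `group` ("low"/"high").
#' @export
generate_survival_cohort <- function(n, hr = 2.7, p_group = 0.45,
                                     target_event_rate = 0.07,
                                     horizon = 36, seed = 1L) {
  stopifnot(n >= 2, hr > 0, horizon > 0)
  f <- function(l) {
    p_group * (1 - exp(-l * hr * horizon)) +
      (1 - p_group) * (1 - exp(-l * horizon)) - target_event_rate
  }
  lambda0 <- stats::uniroot(f, c(1e-10, 10), tol = 1e-12)$root
  with_seed(seed, {
    high <- stats::runif(n) < p_group
    t_ev <- stats::rexp(n, rate = lambda0 * ifelse(high, hr, 1))
    data.frame(
      time = pmin(t_ev, horizon),
      event = t_ev <= horizon,
      group = factor(ifelse(high, "high", "low"), levels = c("low", "high"))
    )
  })
}
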