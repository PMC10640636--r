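# Shared fixtures and independent oracles, built in code at test time.

# minimal cohort data.frame builder
tiny_cohort <- function(n, recurred, age = rep(50, n), grade = rep(2L, n),
                        er = rep("positive", n), stage = rep(1L, n)) {
  data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    age = age, race = "Non-Black", grade = grade, stage = stage,
    er = er, pr = "positive", her2 = "negative",
    recurred_3yr = recurred,
    event_time = ifelse(recurred, 18, 60),
    event_indicator = recurred,
    oncotype_cat = NA_character_, rorpt_cat = NA_character_,
    n_cores = 2L, risk_latent = 0,
    stringsAsFactors = FALSE
  )
}

# balanced synthetic study: cohort + core features + patient matrix
balanced_study <- function(n = 202, seed = 1, signal = 3,
                           feature_dim = 512, ...) {
  p <- synthetic_params(
    n_patients = n, balanced = TRUE, seed = seed,
    signal_strength = signal, feature_dim = feature_dim, ...
  )
  cohort <- generate_cohort(p)
  cf <- generate_patient_features(cohort, p)
  pf <- patient_feature_matrix(cf)
  labels <- stats::setNames(cohort$recurred_3yr, cohort$patient_id)
  list(params = p, cohort = cohort, cf = cf, pf = pf,
       labels = labels, y = as.logical(labels[pf$patient_id]))
}

# two well-separated gaussian clusters in 2-D, for separable-classifier tests
separable_xy <- function(n_per = 3, gap = 10, seed = 99) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n_per * 2, -gap / 2, 0.3), n_per, 2),
    matrix(rnorm(n_per * 2, gap / 2, 0.3), n_per, 2)
  )
  list(x = x, y = rep(c(FALSE, TRUE), each = n_per))
}

# independent product-limit oracle: S(t) at each event time, one group
km_oracle <- function(time, event) {
  ev_times <- sort(unique(time[event]))
  s <- 1
  out <- numeric(length(ev_times))
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  data.frame(time = ev_times, surv = out)
}

# independent Breslow partial log-likelihood for a binary covariate
cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event]))) {
    d_ix <- which(time == t & event)
    risk <- which(time >= t)
    ll <- ll + sum(beta * x[d_ix]) -
      length(d_ix) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# grid maximizer of the partial likelihood
cox_grid_oracle <- function(time, event, x, lo = -3, hi = 3, n = 20001) {
  grid <- seq(lo, hi, length.out = n)
  ll <- vapply(grid, cox_partial_loglik, numeric(1),
               time = time, event = event, x = x)
  grid[which.max(ll)]
}

# luminance-threshold nuclei pixel counter (independent of the generator mask)
count_dark_pixels <- function(img, threshold = 0.55) {
  lum <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
  sum(lum < threshold)
}
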