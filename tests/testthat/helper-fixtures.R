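# Fixtures built in code: small profile tables and centroid tables for
# exercising the allocation math independently of the packaged centroids.

param_codes <- qst_parameters()$code

# one-row profile with the given named parameter values; the rest missing
make_profile <- function(id = "s1", etiology = NA_character_, ...) {
  vals <- list(...)
  prof <- tibble::tibble(subject_id = id, etiology = etiology)
  for (p in param_codes) {
    prof[[p]] <- if (p %in% names(vals)) vals[[p]] else NA_real_
  }
  prof
}

# profile sitting exactly on a centroid of `cent`
profile_at_centroid <- function(cent, phenotype, id = phenotype) {
  sub <- cent[cent$phenotype == phenotype, ]
  prof <- tibble::tibble(subject_id = id, etiology = NA_character_)
  for (p in param_codes) prof[[p]] <- sub$mu[sub$parameter == p]
  prof
}

# centroid table whose PHS/DMA means are themselves legal codes, so that a
# profile placed exactly at a centroid satisfies the profile invariants
legal_centroids <- function() {
  grid <- tidyr::expand_grid(
    phenotype = c("SL", "TH", "MH"),
    parameter = param_codes
  )
  grid$mu <- c(
    # SL: detection loss
    -2, -1.8, -1.9, 0, -0.5, -1, -1, -0.6, 0, -0.5, 0.2, -1.7, -1.5,
    # TH: near-normal with thermal gain
    -0.2, -0.4, -0.3, 0, 0.9, 0.8, 0.1, 0.3, 0, 0.4, 0.2, -0.3, -0.2,
    # MH: thermal loss + pinprick gain
    -1.4, -1.2, -1.3, 0, -0.1, -0.3, 1.2, 1.4, 2, 0.5, 0.8, -0.8, -0.6
  )
  grid$sigma <- rep(1, nrow(grid))
  grid
}

# all-zero profile (the ideal healthy subject)
zero_profile <- function(id = "h1") {
  do.call(make_profile, c(list(id = id),
                          stats::setNames(as.list(rep(0, 13)), param_codes)))
}

# brute-force AUC oracle: Mann-Whitney U over all (patient, healthy) pairs,
# ties counted 1/2; probability that a healthy subject outscores a patient
auc_oracle <- function(scores_patients, scores_healthy) {
  u <- 0
  for (p in scores_patients) {
    for (h in scores_healthy) {
      u <- u + (h > p) + 0.5 * (h == p)
    }
  }
  u / (length(scores_patients) * length(scores_healthy))
}

# brute-force Youden oracle: exhaustive sweep over candidate thresholds
youden_oracle <- function(scores_patients, scores_healthy) {
  ts <- sort(unique(c(scores_patients, scores_healthy)))
  j <- vapply(ts, function(t) {
    mean(scores_patients <= t) - mean(scores_healthy <= t)
  }, numeric(1))
  max(j)
}

# Monte-Carlo power of the two-sample t test, vectorized over replicates
mc_power_parallel <- function(n, d, alpha = 0.05, reps = 50000) {
  x1 <- matrix(stats::rnorm(n * reps, mean = d), nrow = n)
  x2 <- matrix(stats::rnorm(n * reps), nrow = n)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- (colSums(x1^2) - n * m1^2) / (n - 1)
  v2 <- (colSums(x2^2) - n * m2^2) / (n - 1)
  tstat <- (m1 - m2) / sqrt((v1 + v2) / n)
  mean(abs(tstat) > stats::qt(1 - alpha / 2, df = 2 * n - 2))
}

# Monte-Carlo power of the paired t test on within-subject differences
mc_power_paired <- function(n, d, alpha = 0.05, reps = 50000) {
  x <- matrix(stats::rnorm(n * reps, mean = d), nrow = n)
  m <- colMeans(x)
  v <- (colSums(x^2) - n * m^2) / (n - 1)
  tstat <- m / sqrt(v / n)
  mean(abs(tstat) > stats::qt(1 - alpha / 2, df = n - 1))
}
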