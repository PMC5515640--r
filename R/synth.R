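#' Generate a synthetic QST cohort
#'
#' Simulates z-profiles with the statistical structure the allocation
#' algorithm assumes: within each phenotype group, every continuous parameter
#' is drawn independently from `Normal(mu, (sd_scale * sigma)^2)` around the
#' group's centroid; the healthy group uses `(0, 1)` for every parameter.
#' The two coded parameters (PHS, DMA) are drawn from the same Gaussians and,
#' under `discrete_handling = "thresholded"`, snapped to the nearest legal
#' code (`{0, 2}` for PHS, `{0, 2, 3}` for DMA; equidistant draws snap to the
#' lower code). `"gaussian"` leaves them continuous for stress tests — such
#' profiles violate the profile invariants and are returned unvalidated.
#' Missingness is applied independently per cell at `missing_rate` (never
#' removing a subject's last non-missing value). The ground-truth group is
#' attached as `true_phenotype`.
#'
#' @param n_per_group Named integer vector of group sizes, names among
#'   `SL`, `TH`, `MH`, `HEALTHY`; zero counts allowed.
#' @param centroids A centroid table from [qst_centroids()].
#' @param sd_scale Non-negative multiplier on the centroid SDs (default 1;
#'   0 puts every subject exactly at its centroid).
#' @param missing_rate Per-cell missingness probability in `[0, 1)`.
#' @param discrete_handling `"thresholded"` (default, code-conformant) or
#'   `"gaussian"`.
#' @param seed Integer seed; mandatory (cohorts with the same seed are
#'   bit-identical). R's default Mersenne-Twister generator is used via
#'   [withr::with_seed()].
#' @return A profiles tibble with `subject_id`, `etiology` (`NA`),
#'   `true_phenotype`, and the 13 parameter columns.
#' @examples
#' cohort <- generate_cohort(c(SL = 5, HEALTHY = 5), seed = 1)
#' @export
generate_cohort <- function(n_per_group, centroids = qst_centroids(),
                            sd_scale = 1, missing_rate = 0,
                            discrete_handling = c("thresholded", "gaussian"),
                            seed) {
  discrete_handling <- match.arg(discrete_handling)
  if (missing(seed)) rlang::abort("`seed` is mandatory for cohort generation.")
  if (sd_scale < 0) rlang::abort("`sd_scale` must be non-negative.")
  if (missing_rate < 0 || missing_rate >= 1) {
    rlang::abort("`missing_rate` must lie in [0, 1).")
  }
  groups <- names(n_per_group)
  if (is.null(groups) || !all(groups %in% qst_phenotypes(TRUE))) {
    rlang::abort("`n_per_group` must be named with groups among SL, TH, MH, HEALTHY.")
  }
  if (any(n_per_group < 0)) rlang::abort("Group sizes must be >= 0.")
  if (!inherits(centroids, "qst_centroids")) centroids <- validate_centroids(centroids)

  mats <- centroid_matrices(centroids)
  params <- qst_param_codes()

  withr::with_seed(seed, {
    pieces <- lapply(groups, function(g) {
      n <- n_per_group[[g]]
      if (n == 0) return(NULL)
      Z <- matrix(stats::rnorm(n * 13,
                               mean = rep(mats$mu[g, ], each = n),
                               sd = rep(sd_scale * mats$sigma[g, ], each = n)),
                  nrow = n, dimnames = list(NULL, params))
      if (discrete_handling == "thresholded") {
        Z[, "PHS"] <- snap_to_codes(Z[, "PHS"], c(0, 2))
        Z[, "DMA"] <- snap_to_codes(Z[, "DMA"], c(0, 2, 3))
      }
      d <- tibble::as_tibble(Z)
      d$true_phenotype <- g
      d
    })
    out <- dplyr::bind_rows(pieces)
    out$subject_id <- sprintf("synth_%04d", seq_len(nrow(out)))
    out$etiology <- NA_character_
    out <- dplyr::select(out, "subject_id", "etiology", "true_phenotype",
                         dplyr::all_of(params))
    if (missing_rate > 0) {
      out <- inject_missing_impl(out, rate = missing_rate)
    }
    out
  })
}

# nearest legal code; exact ties go to the lower code
snap_to_codes <- function(x, codes) {
  codes <- sort(codes)
  idx <- vapply(x, function(v) {
    d <- abs(v - codes)
    which(d == min(d))[1]
  }, integer(1))
  codes[idx]
}

# core missingness routine; assumes RNG state is managed by the caller
inject_missing_impl <- function(profiles, rate,
                                pattern = "random", parameters = NULL) {
  params <- qst_param_codes()
  Z <- as.matrix(profiles[, params])
  if (pattern == "random") {
    drop <- matrix(stats::runif(length(Z)) < rate, nrow = nrow(Z))
    drop[is.na(Z)] <- FALSE
    # never remove a subject's last non-missing value
    for (i in seq_len(nrow(Z))) {
      keep <- which(!is.na(Z[i, ]) & !drop[i, ])
      if (length(keep) == 0) {
        present <- which(!is.na(Z[i, ]))
        spare <- present[sample.int(length(present), 1)]
        drop[i, spare] <- FALSE
      }
    }
    Z[drop] <- NA_real_
  } else {
    if (is.null(parameters) || !all(parameters %in% params)) {
      rlang::abort("`parameters` must name QST parameters for the block pattern.")
    }
    if (length(setdiff(params, parameters)) == 0) {
      rlang::abort("Cannot blank every parameter.")
    }
    Z[, parameters] <- NA_real_
  }
  profiles[, params] <- tibble::as_tibble(Z)
  profiles
}

#' Inject missing values into profiles
#'
#' Applies a missingness pattern for robustness testing: `"random"` blanks
#' each cell independently with probability `rate` (never a subject's last
#' non-missing value); `"parameter_block"` blanks the named parameters for
#' every subject.
#'
#' @param profiles A profiles tibble.
#' @param rate Per-cell missingness probability in `[0, 1)` (random pattern).
#' @param pattern `"random"` or `"parameter_block"`.
#' @param parameters Parameter codes to blank (block pattern).
#' @param seed Integer seed (random pattern).
#' @return The profiles tibble with missing values applied.
#' @export
inject_missing <- function(profiles, rate = 0,
                           pattern = c("random", "parameter_block"),
                           parameters = NULL, seed = NULL) {
  pattern <- match.arg(pattern)
  if (rate < 0 || rate >= 1) rlang::abort("`rate` must lie in [0, 1).")
  if (pattern == "random" && rate > 0) {
    if (is.null(seed)) rlang::abort("`seed` is mandatory for random missingness.")
    withr::with_seed(seed, inject_missing_impl(profiles, rate, pattern, parameters))
  } else if (pattern == "parameter_block") {
    inject_missing_impl(profiles, rate, pattern, parameters)
  } else {
    profiles
  }
}

#' Recovery of true phenotypes by the allocation algorithm
#'
#' Compares deterministic allocations against the ground-truth labels of a
#' simulated cohort: confusion table, overall accuracy, per-phenotype recall
#' and precision, and kappa versus truth (via [cohens_kappa()]).
#'
#' @param profiles A cohort from [generate_cohort()] (must carry
#'   `true_phenotype`).
#' @param allocations The matching `qst_allocation` tibble (deterministic
#'   mode), aligned by `subject_id`.
#' @return An object of class `qst_recovery`: list with `confusion` (truth in
#'   rows), `accuracy`, `per_class` (tibble of recall/precision), `kappa`
#'   (a `qst_kappa`), and `n`.
#' @export
truth_recovery <- function(profiles, allocations) {
  if (!"true_phenotype" %in% names(profiles)) {
    rlang::abort("`profiles` must carry a `true_phenotype` column.")
  }
  alloc <- tibble::as_tibble(allocations)
  if (!all(alloc$mode == "deterministic")) {
    rlang::abort("`truth_recovery` expects deterministic allocations.")
  }
  merged <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(profiles), "subject_id", "true_phenotype"),
    dplyr::select(alloc, "subject_id", "label"),
    by = "subject_id"
  )
  if (nrow(merged) != nrow(alloc) || nrow(merged) != nrow(profiles)) {
    rlang::abort("`profiles` and `allocations` are not aligned on subject_id.")
  }
  merged <- merged[!is.na(merged$label), ]
  kap <- cohens_kappa(merged$true_phenotype, merged$label)
  confusion <- kap$confusion
  per_class <- tibble::tibble(
    phenotype = rownames(confusion),
    recall = diag(confusion) / pmax(rowSums(confusion), 1),
    precision = diag(confusion) / pmax(colSums(confusion), 1)
  )
  structure(list(
    confusion = confusion,
    accuracy = sum(diag(confusion)) / sum(confusion),
    per_class = per_class,
    kappa = kap,
    n = nrow(merged)
  ), class = "qst_recovery")
}

#' @export
print.qst_recovery <- function(x, ...) {
  cat(sprintf("Phenotype recovery on %d subjects: accuracy %.1f%%, kappa %.2f\n",
              x$n, 100 * x$accuracy, x$kappa$kappa))
  print(x$confusion)
  invisible(x)
}

#' @export
glance.qst_recovery <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy, kappa = x$kappa$kappa)
}

#' @export
tidy.qst_recovery <- function(x, ...) x$per_class
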