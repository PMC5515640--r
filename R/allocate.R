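#' Allocate subjects to sensory phenotypes
#'
#' Runs the full allocation pipeline on a cohort of QST z-profiles: per-subject
#' phenotype probabilities (see [qst_probabilities()]) followed by either
#'
#' * **deterministic** allocation — each subject is assigned the single
#'   phenotype with the highest probability (argmax over SL, TH, MH, and
#'   HEALTHY when `include_healthy = TRUE`). Exact ties are broken by the
#'   fixed order SL > TH > MH > HEALTHY and flagged in `tie_flag`. No subject
#'   is excluded; or
#' * **probabilistic** allocation — each subject is assigned *all* phenotypes
#'   whose probability strictly exceeds `cutoff`. `healthy_flag` records
#'   whether the healthy-profile probability also exceeds the cutoff. A
#'   subject whose label set is empty (no phenotype above the cutoff, or only
#'   the healthy profile above it) is excluded.
#'
#' Subjects whose probabilities are not computable (too many missing values)
#' carry `NA` labels and appear in the `"problems"` attribute.
#'
#' @inheritParams qst_probabilities
#' @param mode `"deterministic"` or `"probabilistic"`.
#' @param cutoff Probability cutoff in percent for the probabilistic mode
#'   (strict `>`); the recommended value from the Youden-index analysis of the
#'   healthy-profile probability is 64.
#' @param include_healthy Deterministic mode only: include the healthy profile
#'   as a possible label (the recommended final algorithm) or restrict the
#'   argmax to the three phenotypes.
#' @return A tibble of class `qst_allocation`: the probability columns plus
#'   `mode`, `cutoff`, `label` (deterministic single label, `NA` in
#'   probabilistic mode), `label_set` (comma-separated phenotypes, `""` when
#'   excluded; `NA` in deterministic mode), `n_labels`, `healthy_flag`,
#'   `excluded`, `tie_flag`.
#' @examples
#' prof <- tibble::tibble(subject_id = "s1", etiology = NA_character_)
#' prof[qst_parameters()$code] <- as.list(rep(0, 13))
#' qst_allocate(prof)             # all-zero profile is healthy-like
#' @export
qst_allocate <- function(profiles, centroids = qst_centroids(),
                         mode = c("deterministic", "probabilistic"),
                         protocol = c("full", "simplified"),
                         cutoff = 64, include_healthy = TRUE,
                         min_params = NULL) {
  mode <- match.arg(mode)
  protocol <- match.arg(protocol)
  if (mode == "probabilistic" && (cutoff <= 0 || cutoff >= 100)) {
    rlang::abort("`cutoff` must lie strictly between 0 and 100 (percent).")
  }
  if (nrow(tibble::as_tibble(profiles)) == 0) {
    rlang::abort("`profiles` must contain at least one subject.")
  }
  probs <- qst_probabilities(profiles, centroids, protocol, min_params)

  phens3 <- qst_phenotypes(FALSE)
  pmat <- as.matrix(probs[, paste0("p_", phens3)])
  colnames(pmat) <- phens3
  ph <- probs$p_HEALTHY
  n <- nrow(probs)

  label <- rep(NA_character_, n)
  label_set <- rep(NA_character_, n)
  n_labels <- rep(NA_integer_, n)
  healthy_flag <- rep(NA, n)
  excluded <- rep(NA, n)
  tie_flag <- rep(NA, n)
  ok <- !is.na(ph)

  if (mode == "deterministic") {
    cand <- if (include_healthy) cbind(pmat, HEALTHY = ph) else pmat
    for (i in which(ok)) {
      p <- cand[i, ]
      top <- max(p)
      hits <- names(p)[p == top]
      label[i] <- hits[1]  # column order is the tie-break order
      tie_flag[i] <- length(hits) > 1
    }
    excluded[ok] <- FALSE
    healthy_flag[ok] <- FALSE
    healthy_flag[ok & label == "HEALTHY"] <- TRUE
    n_labels[ok] <- 1L
  } else {
    for (i in which(ok)) {
      hits <- phens3[pmat[i, ] > cutoff]
      label_set[i] <- paste(hits, collapse = ",")
      n_labels[i] <- length(hits)
      healthy_flag[i] <- ph[i] > cutoff
      excluded[i] <- length(hits) == 0
      tie_flag[i] <- FALSE
    }
  }

  cutoff_used <- if (mode == "probabilistic") cutoff else NA_real_
  out <- dplyr::mutate(tibble::as_tibble(probs),
    mode = .env$mode,
    cutoff = .env$cutoff_used,
    label = label,
    label_set = label_set,
    n_labels = n_labels,
    healthy_flag = healthy_flag,
    excluded = excluded,
    tie_flag = tie_flag
  )
  attr(out, "problems") <- attr(probs, "problems")
  class(out) <- c("qst_allocation", class(tibble::tibble()))
  out
}

#' Summarize phenotype frequencies in an allocated cohort
#'
#' For deterministic allocations, returns per-phenotype counts and
#' percentages; percentages sum to 100 within each stratum (computable
#' subjects only). For probabilistic allocations, returns per-phenotype
#' percentages among computable subjects — which are not
#' additive since a subject may carry several labels — plus counts of subjects
#' assigned to exactly 1, 2 or 3 phenotypes, subjects with the healthy flag,
#' and excluded subjects.
#'
#' @param allocations A `qst_allocation` tibble from [qst_allocate()], all
#'   rows from one mode.
#' @param by_etiology Stratify by the `etiology` column?
#' @return A tibble with columns `etiology` (when stratified), `measure`
#'   (phenotype code or one of `exactly_1/2/3`, `healthy_flag`, `excluded`,
#'   `not_computable`), `n` and `pct`.
#' @export
summarize_cohort <- function(allocations, by_etiology = FALSE) {
  alloc <- tibble::as_tibble(allocations)
  modes <- unique(alloc$mode)
  if (length(modes) != 1) {
    rlang::abort("`allocations` mixes deterministic and probabilistic results; summarize one mode at a time.")
  }
  if (!by_etiology) alloc$etiology <- "all"
  alloc$etiology[is.na(alloc$etiology)] <- "unknown"

  one_stratum <- function(d) {
    comp <- d[!is.na(d$excluded), ]
    if (modes == "deterministic") {
      labs <- qst_phenotypes(TRUE)
      n <- unname(vapply(labs, function(l) sum(comp$label == l), integer(1)))
      res <- tibble::tibble(measure = labs, n = n,
                            pct = 100 * n / max(nrow(comp), 1L))
    } else {
      labs <- qst_phenotypes(FALSE)
      n <- unname(vapply(labs, function(l) {
        sum(vapply(strsplit(comp$label_set, ","),
                   function(s) l %in% s, logical(1)))
      }, integer(1)))
      res <- tibble::tibble(measure = labs, n = n,
                            pct = 100 * n / max(nrow(comp), 1L))
      extra <- tibble::tibble(
        measure = c("exactly_1", "exactly_2", "exactly_3",
                    "healthy_flag", "excluded"),
        n = c(sum(comp$n_labels == 1), sum(comp$n_labels == 2),
              sum(comp$n_labels == 3), sum(comp$healthy_flag),
              sum(comp$excluded)),
      )
      extra$pct <- 100 * extra$n / max(nrow(comp), 1L)
      res <- dplyr::bind_rows(res, extra)
    }
    nc <- sum(is.na(d$excluded))
    dplyr::bind_rows(res, tibble::tibble(measure = "not_computable", n = nc,
                                         pct = NA_real_))
  }

  out <- alloc |>
    dplyr::group_by(.data$etiology) |>
    dplyr::group_modify(~ one_stratum(.x)) |>
    dplyr::ungroup()
  if (!by_etiology) out$etiology <- NULL
  out
}
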