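#' Normalized Gaussian similarity of a z-value to a phenotype centroid
#'
#' The per-parameter building block of the allocation algorithm. The Gaussian
#' density of the phenotype's z-distribution, evaluated at the observed
#' z-value, is divided by its value at the centroid mean so that an
#' observation exactly at the mean scores 100%:
#' \deqn{F(z; \mu, \sigma) = 100 \, e^{-(z-\mu)^2 / (2\sigma^2)}}
#' The result lies in (0, 100], equals 100 iff `z == mu`, and decreases
#' strictly in `|z - mu|`.
#'
#' @param z Observed z-value(s); finite numeric, `NA` propagates.
#' @param mu Centroid mean(s).
#' @param sigma Centroid standard deviation(s); strictly positive.
#' @return Similarity percentage(s) in (0, 100].
#' @examples
#' qst_similarity(0, 0, 1)        # 100
#' qst_similarity(1, 0, 1)        # 100 * exp(-0.5)
#' @export
qst_similarity <- function(z, mu, sigma) {
  if (any(sigma <= 0, na.rm = TRUE)) {
    rlang::abort("`sigma` must be strictly positive.")
  }
  100 * exp(-(z - mu)^2 / (2 * sigma^2))
}

#' Per-subject phenotype probabilities
#'
#' Computes, for each subject, the similarity of its QST z-profile to each of
#' the three phenotype centroids and to the healthy reference (`mu = 0`,
#' `sigma = 1` for every parameter). The per-phenotype probability is the
#' arithmetic mean of the per-parameter similarities over the *non-missing*
#' parameters of the protocol set; missing values are simply left out of the
#' average, never imputed. The same set of non-missing parameters is used for
#' all four probabilities of a subject, so `n_used` is shared.
#'
#' Subjects with fewer than `min_params` non-missing parameters in the
#' protocol set are not computable: their probability columns are `NA` and
#' they are listed in the `"problems"` attribute (a tibble with `subject_id`
#' and `problem`), never silently dropped.
#'
#' @param profiles A profiles tibble (see [read_profiles()] /
#'   [validate_profiles()]).
#' @param centroids A centroid table from [qst_centroids()].
#' @param protocol `"full"` (all 13 parameters) or `"simplified"` (WDT and
#'   MPS only).
#' @param min_params Minimum number of non-missing parameters required;
#'   default 7 for the full protocol and 2 (both) for the simplified one.
#' @return A tibble of class `qst_probabilities`: `subject_id`, `etiology`,
#'   `p_SL`, `p_TH`, `p_MH`, `p_HEALTHY` (percentages), `n_used`, `protocol`.
#' @export
qst_probabilities <- function(profiles, centroids = qst_centroids(),
                              protocol = c("full", "simplified"),
                              min_params = NULL) {
  protocol <- match.arg(protocol)
  profiles <- validate_profiles(profiles)
  if (!inherits(centroids, "qst_centroids")) centroids <- validate_centroids(centroids)
  params <- protocol_params(protocol)
  if (is.null(min_params)) min_params <- if (protocol == "full") 7L else 2L

  mats <- centroid_matrices(centroids)
  Z <- as.matrix(profiles[, qst_param_codes()])[, params, drop = FALSE]
  n_used <- rowSums(!is.na(Z))

  phens <- qst_phenotypes(TRUE)
  P <- sapply(phens, function(ph) {
    S <- qst_similarity(
      Z,
      matrix(mats$mu[ph, params], nrow(Z), length(params), byrow = TRUE),
      matrix(mats$sigma[ph, params], nrow(Z), length(params), byrow = TRUE)
    )
    rowMeans(S, na.rm = TRUE)
  })
  P <- matrix(P, nrow = nrow(Z), dimnames = list(NULL, phens))

  bad <- n_used < min_params
  P[bad, ] <- NA_real_

  out <- tibble::tibble(
    subject_id = profiles$subject_id,
    etiology = profiles$etiology,
    p_SL = unname(P[, "SL"]), p_TH = unname(P[, "TH"]),
    p_MH = unname(P[, "MH"]), p_HEALTHY = unname(P[, "HEALTHY"]),
    n_used = as.integer(n_used),
    protocol = protocol
  )
  problems <- tibble::tibble(
    subject_id = profiles$subject_id[bad],
    problem = sprintf("only %d of %d %s-protocol parameters non-missing (minimum %d)",
                      n_used[bad], length(params), protocol, min_params)
  )
  attr(out, "problems") <- problems
  class(out) <- c("qst_probabilities", class(out))
  out
}
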