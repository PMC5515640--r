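#' The 13 QST parameters
#'
#' Metadata for the 13 parameters of the DFNS quantitative sensory testing
#' battery, in the fixed order used throughout the package. Eleven parameters
#' are continuous z-values (normalized against age/sex/region reference data);
#' paradoxical heat sensation (PHS) and dynamic mechanical allodynia (DMA) do
#' not occur in healthy subjects, cannot be z-transformed, and are carried as
#' discrete codes instead (see [code_phs()] and [code_dma()]).
#'
#' @return A tibble with one row per parameter and columns `code` (the
#'   three-letter parameter code), `kind` (`"continuous"` or `"coded"`), and
#'   `label` (full parameter name).
#' @examples
#' qst_parameters()
#' @export
qst_parameters <- function() {
  tibble::tibble(
    code = c("CDT", "WDT", "TSL", "PHS", "CPT", "HPT", "MPT", "MPS",
             "DMA", "PPT", "WUR", "MDT", "VDT"),
    kind = ifelse(code %in% c("PHS", "DMA"), "coded", "continuous"),
    label = c(
      "cold detection threshold", "warm detection threshold",
      "thermal sensory limen", "paradoxical heat sensations",
      "cold pain threshold", "heat pain threshold",
      "mechanical pain threshold", "mechanical pain sensitivity",
      "dynamic mechanical allodynia", "pressure pain threshold",
      "wind-up ratio", "mechanical detection threshold",
      "vibration detection threshold"
    )
  )
}

# fixed parameter order; used by every module
qst_param_codes <- function() qst_parameters()$code

# phenotype label order; also the deterministic tie-break order
qst_phenotypes <- function(include_healthy = TRUE) {
  if (include_healthy) c("SL", "TH", "MH", "HEALTHY") else c("SL", "TH", "MH")
}

# parameter set of a protocol
protocol_params <- function(protocol = c("full", "simplified")) {
  protocol <- match.arg(protocol)
  if (protocol == "full") qst_param_codes() else c("WDT", "MPS")
}

#' Code paradoxical heat sensations as a 0/2 variable
#'
#' PHS does not occur in healthy subjects and has no z-transform; its presence
#' is coded as +2 and its absence as 0 on the z-profile scale.
#'
#' @param phs Logical (presence) or non-negative count of paradoxical heat
#'   sensations observed during thermal sensory limen testing. Vectorized;
#'   `NA` stays `NA`.
#' @return Numeric vector of codes in `{0, 2}`.
#' @examples
#' code_phs(c(0, 1, 3, NA))
#' code_phs(TRUE)
#' @export
code_phs <- function(phs) {
  if (is.logical(phs)) phs <- as.numeric(phs)
  if (!is.numeric(phs)) {
    rlang::abort("`phs` must be logical or a non-negative count.")
  }
  if (any(phs < 0, na.rm = TRUE)) {
    rlang::abort("`phs` must be non-negative.")
  }
  ifelse(is.na(phs), NA_real_, ifelse(phs >= 1, 2, 0))
}

#' Code dynamic mechanical allodynia as a 0/2/3 variable
#'
#' DMA does not occur in healthy subjects and has no z-transform. The mean
#' pain rating to light tactile stimuli (0-100 numerical rating scale) is
#' coded 0 (no allodynia), +2 (ratings below 1) or +3 (ratings from 1 to 100).
#' A rating of exactly 1 codes to 3.
#'
#' @param mean_rating Mean NRS pain rating in `[0, 100]`. Vectorized; `NA`
#'   stays `NA`.
#' @return Numeric vector of codes in `{0, 2, 3}`.
#' @examples
#' code_dma(c(0, 0.5, 1, 40))
#' @export
code_dma <- function(mean_rating) {
  if (is.logical(mean_rating) && all(is.na(mean_rating))) {
    mean_rating <- as.numeric(mean_rating)
  }
  if (!is.numeric(mean_rating)) {
    rlang::abort("`mean_rating` must be numeric.")
  }
  if (any(mean_rating < 0 | mean_rating > 100, na.rm = TRUE)) {
    rlang::abort("`mean_rating` must lie in [0, 100].")
  }
  dplyr::case_when(
    is.na(mean_rating) ~ NA_real_,
    mean_rating == 0 ~ 0,
    mean_rating < 1 ~ 2,
    TRUE ~ 3
  )
}

#' Flag abnormal z-values
#'
#' A QST z-value is abnormal when it falls outside the 95% confidence interval
#' of the healthy reference distribution, i.e. strictly below -1.96 or
#' strictly above 1.96.
#'
#' @param z Numeric vector of z-values; `NA` yields `NA`.
#' @return Logical vector: `TRUE` where `|z| > 1.96`.
#' @examples
#' flag_abnormal(c(-2.5, -1.96, 0, 1.96, 2.5, NA))
#' @export
flag_abnormal <- function(z) {
  if (!is.numeric(z)) rlang::abort("`z` must be numeric.")
  abs(z) > 1.96
}
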