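#' Phenotype centroid table
#'
#' Returns the table of per-parameter means (`mu`) and standard deviations
#' (`sigma`) of the z-profiles of the three sensory phenotypes: sensory loss
#' (SL), thermal hyperalgesia (TH) and mechanical hyperalgesia (MH). The
#' healthy reference is not part of the table: by the definition of the
#' z-transform it has `mu = 0`, `sigma = 1` for every parameter and is applied
#' implicitly wherever a healthy-profile probability is computed.
#'
#' The packaged default (`inst/extdata/centroids_synthetic.csv`) is a
#' *synthetic* centroid table: it reproduces the qualitative structure of the
#' published phenotypes (SL: thermal and mechanical detection loss; TH:
#' preserved detection with mild heat/cold hyperalgesia; MH: thermal loss with
#' pinprick hyperalgesia and allodynia) on the DFNS sign convention, but its
#' numeric values are constructed, not transcribed from a patient cohort.
#' For real use, supply the centroid table of the defining cluster analysis
#' via `path`. No re-signing of z-values is performed: the input profiles must
#' use the same loss/gain sign convention as the centroid table.
#'
#' @param path Optional path to a user-supplied centroid table, either a CSV
#'   with columns `phenotype, parameter, mu, sigma` or a JSON file with the
#'   same fields (an array of records). When `NULL`, the packaged synthetic
#'   table is used.
#' @return A tibble of class `qst_centroids` with columns `phenotype`
#'   (`SL`/`TH`/`MH`), `parameter` (13 codes), `mu` and `sigma`; exactly 39
#'   rows, all `sigma > 0`.
#' @examples
#' qst_centroids()
#' @export
qst_centroids <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "centroids_synthetic.csv",
                        package = "qstphenotype", mustWork = TRUE)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tab <- tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  validate_centroids(tab)
}

#' @keywords internal
validate_centroids <- function(tab) {
  need <- c("phenotype", "parameter", "mu", "sigma")
  if (!all(need %in% names(tab))) {
    rlang::abort(paste0("Centroid table must have columns: ",
                        paste(need, collapse = ", ")))
  }
  tab <- dplyr::select(tab, dplyr::all_of(need))
  tab$phenotype <- toupper(tab$phenotype)
  tab$parameter <- toupper(tab$parameter)
  grid <- tidyr::expand_grid(
    phenotype = qst_phenotypes(include_healthy = FALSE),
    parameter = qst_param_codes()
  )
  merged <- dplyr::left_join(grid, tab, by = c("phenotype", "parameter"))
  if (anyNA(merged$mu) || anyNA(merged$sigma)) {
    miss <- merged[is.na(merged$mu) | is.na(merged$sigma), ]
    rlang::abort(paste0(
      "Centroid table is missing (mu, sigma) for: ",
      paste(paste(miss$phenotype, miss$parameter, sep = "/"), collapse = ", ")
    ))
  }
  if (nrow(tab) != nrow(grid)) {
    rlang::abort("Centroid table must have exactly one row per phenotype x parameter (39 rows).")
  }
  if (any(merged$sigma <= 0)) {
    rlang::abort("All centroid sigma values must be strictly positive.")
  }
  structure(tibble::as_tibble(merged),
            class = c("qst_centroids", class(tibble::tibble())))
}

# centroid table -> list of mu/sigma matrices (phenotype x 13), healthy appended
centroid_matrices <- function(centroids) {
  params <- qst_param_codes()
  phens <- qst_phenotypes(include_healthy = FALSE)
  mu <- sg <- matrix(NA_real_, nrow = 4, ncol = 13,
                     dimnames = list(qst_phenotypes(TRUE), params))
  for (ph in phens) {
    sub <- centroids[centroids$phenotype == ph, ]
    mu[ph, sub$parameter] <- sub$mu
    sg[ph, sub$parameter] <- sub$sigma
  }
  mu["HEALTHY", ] <- 0
  sg["HEALTHY", ] <- 1
  list(mu = mu, sigma = sg)
}
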