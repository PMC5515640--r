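#' Cohen's kappa agreement between two labelings
#'
#' Chance-corrected agreement between two categorical labelings of the same
#' subjects (e.g. full-protocol vs simplified-protocol phenotype allocations,
#' or allocations vs the labels of an original cluster analysis):
#' \deqn{\kappa = (p_o - p_e) / (1 - p_e)}
#' with `p_o` the observed agreement and `p_e` the chance agreement expected
#' from the marginals. The 95% CI uses the large-sample standard error
#' `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))` without bias correction; labels
#' are nominal (no weighting).
#'
#' @param labels_a,labels_b Equal-length vectors of labels over the same
#'   label set.
#' @return An object of class `qst_kappa`: list with `n`,
#'   `percent_agreement`, `kappa`, `kappa_ci95`, and the `confusion` table
#'   (labels_a in rows). Has `tidy()` and `glance()` methods.
#' @examples
#' k <- cohens_kappa(c("SL", "SL", "TH"), c("SL", "TH", "TH"))
#' glance(k)
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    rlang::abort("`labels_a` and `labels_b` must have the same length.")
  }
  if (length(labels_a) == 0) rlang::abort("Label vectors must be non-empty.")
  if (anyNA(labels_a) || anyNA(labels_b)) {
    rlang::abort("Labels must not contain NA.")
  }
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  confusion <- table(a, b, dnn = c("labels_a", "labels_b"))
  n <- length(a)
  p_o <- sum(diag(confusion)) / n
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    rlang::warn("Both labelings are constant and identical; kappa defined as 1.")
    kappa <- 1
    ci <- c(1, 1)
  } else {
    kappa <- (p_o - p_e) / (1 - p_e)
    se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
    ci <- pmin(pmax(kappa + c(-1, 1) * stats::qnorm(0.975) * se, -1), 1)
  }
  structure(list(
    n = n, percent_agreement = 100 * p_o, kappa = kappa,
    kappa_ci95 = ci, confusion = confusion
  ), class = "qst_kappa")
}

#' @export
print.qst_kappa <- function(x, ...) {
  cat(sprintf("Agreement on %d subjects: %.1f%%, kappa = %.2f (95%% CI %.2f-%.2f)\n",
              x$n, x$percent_agreement, x$kappa,
              x$kappa_ci95[1], x$kappa_ci95[2]))
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.qst_kappa <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$confusion, responseName = "n"))
}

#' @export
glance.qst_kappa <- function(x, ...) {
  tibble::tibble(
    n = x$n, percent_agreement = x$percent_agreement, kappa = x$kappa,
    kappa_ci_low = x$kappa_ci95[1], kappa_ci_high = x$kappa_ci95[2]
  )
}
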