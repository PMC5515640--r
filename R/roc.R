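#' ROC analysis of the healthy-profile probability
#'
#' Assesses how well the healthy-profile probability separates patients from
#' healthy subjects. A subject is classified *healthy* when its score is
#' strictly above a threshold and *patient* otherwise, so sensitivity (for
#' detecting patients) at threshold `t` is the fraction of patients with
#' score `<= t` and the false-positive rate is the fraction of healthy
#' subjects with score `<= t`. The threshold sweep runs over all distinct
#' observed scores plus `-Inf`/`+Inf` sentinels (or an integer percentage grid
#' with `thresholds = "integer"`); the AUC is the trapezoidal area under the
#' empirical curve, which equals the Mann-Whitney U statistic divided by
#' `n_patients * n_healthy` with ties counted 1/2.
#'
#' The 95% CI of the AUC uses the Hanley-McNeil standard error by default;
#' `ci_method = "delong"` delegates to \pkg{pROC}.
#'
#' @param scores_patients Healthy-profile probabilities (0-100) of the
#'   patients.
#' @param scores_healthy Healthy-profile probabilities of the healthy
#'   subjects.
#' @param ci_method `"hanley"` (default) or `"delong"`.
#' @param thresholds `"observed"` (all distinct scores; default) or
#'   `"integer"` (grid 0..100).
#' @return An object of class `qst_roc`: a list with `curve` (tibble of
#'   `threshold`, `sensitivity`, `fpr`, `specificity`, `youden`), `auc`,
#'   `auc_ci95`, `youden_cutoff`, `youden_value`, `n_patients`, `n_healthy`.
#'   Has [tidy()][generics::tidy], [glance()][generics::glance] and
#'   [autoplot()][ggplot2::autoplot] methods.
#' @examples
#' roc <- roc_healthy(c(10, 20, 60), c(70, 80, 90))
#' glance(roc)
#' @export
roc_healthy <- function(scores_patients, scores_healthy,
                        ci_method = c("hanley", "delong"),
                        thresholds = c("observed", "integer")) {
  ci_method <- match.arg(ci_method)
  thresholds <- match.arg(thresholds)
  if (length(scores_patients) == 0 || length(scores_healthy) == 0) {
    rlang::abort("Both score vectors must be non-empty.")
  }
  sp <- as.numeric(scores_patients)
  sh <- as.numeric(scores_healthy)
  if (anyNA(sp) || anyNA(sh)) rlang::abort("Scores must not contain NA.")
  n1 <- length(sp); n2 <- length(sh)

  grid <- if (thresholds == "observed") sort(unique(c(sp, sh))) else 0:100
  grid <- c(-Inf, grid, Inf)
  sens <- vapply(grid, function(t) mean(sp <= t), numeric(1))
  fpr <- vapply(grid, function(t) mean(sh <= t), numeric(1))
  curve <- tibble::tibble(
    threshold = grid, sensitivity = sens, fpr = fpr,
    specificity = 1 - fpr, youden = sens - fpr
  )

  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  if (length(unique(c(sp, sh))) == 1) {
    rlang::warn("All scores identical; no discrimination (AUC = 0.5).")
  }

  if (ci_method == "hanley") {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                  (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
    ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  } else {
    if (!requireNamespace("pROC", quietly = TRUE)) {
      rlang::abort("`ci_method = \"delong\"` requires the pROC package.")
    }
    r <- pROC::roc(response = c(rep(0, n1), rep(1, n2)), predictor = c(sp, sh),
                   direction = "<", levels = c(0, 1), quiet = TRUE)
    ci <- as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)]
  }

  yj <- pick_youden(curve)
  structure(list(
    curve = curve, auc = auc, auc_ci95 = ci,
    youden_cutoff = yj$cutoff, youden_value = yj$value,
    n_patients = n1, n_healthy = n2, ci_method = ci_method
  ), class = "qst_roc")
}

# max Youden; ties -> higher specificity, then higher threshold
pick_youden <- function(curve) {
  finite <- curve[is.finite(curve$threshold), ]
  if (nrow(finite) == 0) finite <- curve
  jmax <- max(finite$youden)
  cand <- finite[finite$youden >= jmax - 1e-12, ]
  cand <- cand[cand$specificity >= max(cand$specificity) - 1e-12, ]
  list(cutoff = max(cand$threshold), value = jmax)
}

#' Youden-index cutoff of a ROC analysis
#'
#' Returns the threshold maximizing the Youden index (sensitivity minus
#' false-positive rate). Exact ties are broken toward the higher specificity
#' (the conservative choice: fewer healthy subjects misclassified), then
#' toward the higher threshold.
#'
#' @param roc A `qst_roc` object from [roc_healthy()].
#' @return A named list with `cutoff` (percentage) and `value` (the maximal
#'   Youden index).
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "qst_roc"))
  list(cutoff = roc$youden_cutoff, value = roc$youden_value)
}

#' @export
print.qst_roc <- function(x, ...) {
  cat(sprintf(
    "ROC of healthy-profile probability: %d patients vs %d healthy\n",
    x$n_patients, x$n_healthy))
  cat(sprintf("  AUC = %.3f (95%% CI %.3f-%.3f, %s)\n",
              x$auc, x$auc_ci95[1], x$auc_ci95[2], x$ci_method))
  cat(sprintf("  Youden cutoff = %.1f%% (J = %.3f)\n",
              x$youden_cutoff, x$youden_value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.qst_roc <- function(x, ...) x$curve

#' @export
glance.qst_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, auc_ci_low = x$auc_ci95[1], auc_ci_high = x$auc_ci95[2],
    youden_cutoff = x$youden_cutoff, youden_value = x$youden_value,
    n_patients = x$n_patients, n_healthy = x$n_healthy
  )
}

#' @export
autoplot.qst_roc <- function(object, ...) {
  crv <- object$curve
  best <- crv[which.min(abs(crv$threshold - object$youden_cutoff)), ]
  ggplot2::ggplot(crv, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dotted", colour = "grey50") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_point(data = best, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate (1 - specificity)",
      y = "Sensitivity (detecting patients)",
      title = sprintf("AUC = %.3f; Youden cutoff %.0f%%",
                      object$auc, object$youden_cutoff)
    ) +
    ggplot2::theme_minimal()
}
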