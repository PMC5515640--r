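#' @export
autoplot.qst_allocation <- function(object, by_etiology = FALSE, ...) {
  freq <- summarize_cohort(object, by_etiology = by_etiology)
  freq <- freq[freq$measure %in% qst_phenotypes(TRUE), ]
  freq$measure <- factor(freq$measure, levels = qst_phenotypes(TRUE))
  p <- ggplot2::ggplot(freq, ggplot2::aes(x = .data$measure, y = .data$pct,
                                          fill = .data$measure)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(
      SL = "#4472c4", TH = "#c0504d", MH = "#e8b52c", HEALTHY = "grey60"
    )) +
    ggplot2::labs(x = NULL, y = "Frequency (%)",
                  title = sprintf("Phenotype frequencies (%s)",
                                  unique(object$mode))) +
    ggplot2::theme_minimal()
  if (by_etiology) p <- p + ggplot2::facet_wrap(~etiology)
  p
}

#' Plot QST z-profiles against the phenotype centroids
#'
#' Line plot of individual z-profiles over the 13 parameters in standard
#' order, overlaid on the centroid means of the three phenotypes; dashed
#' lines mark the +/-1.96 abnormality bounds.
#'
#' @param profiles A profiles tibble (a handful of subjects plots best).
#' @param centroids A centroid table from [qst_centroids()].
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles, centroids = qst_centroids()) {
  params <- qst_param_codes()
  long <- tidyr::pivot_longer(
    tibble::as_tibble(profiles)[, c("subject_id", params)],
    dplyr::all_of(params), names_to = "parameter", values_to = "z"
  )
  long$parameter <- factor(long$parameter, levels = params)
  cent <- tibble::as_tibble(centroids)
  cent$parameter <- factor(cent$parameter, levels = params)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$parameter, y = .data$z)) +
    ggplot2::geom_hline(yintercept = c(-1.96, 1.96),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_line(
      data = cent,
      ggplot2::aes(y = .data$mu, group = .data$phenotype,
                   colour = .data$phenotype),
      linewidth = 1, alpha = 0.6
    ) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id),
                       colour = "black", alpha = 0.7, na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(
      SL = "#4472c4", TH = "#c0504d", MH = "#e8b52c"
    )) +
    ggplot2::labs(y = "z-value", x = NULL, colour = "Centroid") +
    ggplot2::theme_minimal()
}
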