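#' Cohen's d from a mean treatment effect and response SD
#'
#' Converts a mean treatment effect (e.g. in points on a 0-10 numerical
#' rating scale) and the SD of the treatment response to a standardized
#' effect size `d = mean_effect / sd_response`.
#'
#' @param mean_effect Mean treatment effect; vectorized.
#' @param sd_response SD of the treatment response, strictly positive; same
#'   units as `mean_effect`.
#' @return Numeric effect size(s).
#' @examples
#' cohen_d(2, 4)    # 0.5
#' cohen_d(3.5, 5)  # 0.7
#' @export
cohen_d <- function(mean_effect, sd_response) {
  if (any(sd_response <= 0, na.rm = TRUE)) {
    rlang::abort("`sd_response` must be strictly positive.")
  }
  mean_effect / sd_response
}

#' Effect size w for a chi-squared comparison of two proportions
#'
#' Builds the 2x2 joint distribution of (arm, outcome) under equal
#' allocation, contrasts it with the null of a common outcome rate, and
#' returns Cohen's `w = sqrt(sum((p1 - p0)^2 / p0))`.
#'
#' @param p_a,p_b Outcome probabilities in the two arms, in (0, 1).
#' @return The effect size w.
#' @export
props_to_w <- function(p_a, p_b) {
  if (any(c(p_a, p_b) <= 0 | c(p_a, p_b) >= 1)) {
    rlang::abort("Proportions must lie strictly between 0 and 1.")
  }
  pbar <- (p_a + p_b) / 2
  p1 <- c(p_a, 1 - p_a, p_b, 1 - p_b) / 2
  p0 <- c(pbar, 1 - pbar, pbar, 1 - pbar) / 2
  sqrt(sum((p1 - p0)^2 / p0))
}

# exact power at integer n for one design
power_at_n <- function(n, effect_size, design, alpha, sides, df) {
  switch(design,
    parallel = stats::power.t.test(
      n = n, delta = effect_size, sd = 1, sig.level = alpha,
      type = "two.sample",
      alternative = if (sides == 2) "two.sided" else "one.sided"
    )$power,
    crossover = stats::power.t.test(
      n = n, delta = effect_size, sd = 1, sig.level = alpha,
      type = "paired",
      alternative = if (sides == 2) "two.sided" else "one.sided"
    )$power,
    dichotomous = stats::pchisq(
      stats::qchisq(1 - alpha, df), df,
      ncp = n * effect_size^2, lower.tail = FALSE
    )
  )
}

#' Smallest sample size reaching a target power
#'
#' Returns the minimal integer sample size achieving the requested power for
#' the given standardized effect size, using the exact noncentral-t power of
#' the two-sample t test (`"parallel"`: n per group), the paired t test
#' (`"crossover"`: total subjects, with the effect size on the
#' within-subject difference scale), or the noncentral chi-squared power
#' (`"dichotomous"`: total N, effect size Cohen's w).
#'
#' @param effect_size Standardized effect size, > 0 (Cohen's d for the t
#'   designs, w for `"dichotomous"`).
#' @param design `"parallel"`, `"crossover"` or `"dichotomous"`.
#' @param alpha Type-I error level (two-sided by default).
#' @param power Target power in (0, 1).
#' @param sides 2 (default) or 1; ignored for `"dichotomous"`.
#' @param df Degrees of freedom of the chi-squared test (default 1).
#' @param cap Upper bound on n; effect sizes too small to be attainable below
#'   the cap raise an error.
#' @return The minimal integer n (per group for `"parallel"`, total
#'   otherwise).
#' @examples
#' required_n(0.5, "parallel")   # 64 per group
#' required_n(0.5, "crossover")  # 34 subjects
#' @export
required_n <- function(effect_size, design = c("parallel", "crossover", "dichotomous"),
                       alpha = 0.05, power = 0.8, sides = 2, df = 1,
                       cap = 1e6) {
  design <- match.arg(design)
  if (effect_size <= 0) rlang::abort("`effect_size` must be > 0.")
  if (alpha <= 0 || alpha >= 1) rlang::abort("`alpha` must lie in (0, 1).")
  if (power <= 0 || power >= 1) rlang::abort("`power` must lie in (0, 1).")
  lo <- 2L
  n <- lo
  # geometric bracketing then walk-down to the minimal n
  while (n <= cap && power_at_n(n, effect_size, design, alpha, sides, df) < power) {
    n <- n * 2L
  }
  if (n > cap) {
    rlang::abort(sprintf(
      "Required n exceeds the cap (%g); effect size %.3g is unattainably small.",
      cap, effect_size))
  }
  while (n > lo && power_at_n(n - 1L, effect_size, design, alpha, sides, df) >= power) {
    n <- n - 1L
  }
  as.integer(n)
}

#' Screening population size for a phenotype subgroup
#'
#' Number of patients who must be screened so that the subgroup with the
#' target phenotype reaches the powered sample size: the subgroup size
#' divided by the phenotype frequency, rounded up.
#'
#' @param subgroup_n Required subgroup size (integer >= 1); vectorized.
#' @param phenotype_frequency Frequency of the phenotype in the screened
#'   population, in (0, 1].
#' @return Integer screening N, `ceiling(subgroup_n / phenotype_frequency)`.
#' @examples
#' screening_size(34, 0.5)   # 68
#' @export
screening_size <- function(subgroup_n, phenotype_frequency) {
  if (any(phenotype_frequency <= 0 | phenotype_frequency > 1, na.rm = TRUE)) {
    rlang::abort("`phenotype_frequency` must lie in (0, 1].")
  }
  if (any(subgroup_n < 1, na.rm = TRUE)) {
    rlang::abort("`subgroup_n` must be >= 1.")
  }
  as.integer(ceiling(subgroup_n / phenotype_frequency))
}

#' Screening table for phenotype-stratified trials
#'
#' Crosses a grid of effect sizes and designs with a table of phenotype
#' frequencies (per etiology, phenotype and — optionally — algorithm variant)
#' and returns, for every cell, the powered subgroup size and the screening
#' population needed to find it. Rows with missing or invalid frequencies are
#' reported in the `"problems"` attribute; the remaining cells are still
#' computed.
#'
#' @param frequencies A data frame with columns `etiology`, `phenotype`,
#'   `frequency` (in (0, 1]); extra columns (e.g. `mode`, `protocol`) are
#'   carried through.
#' @param effect_sizes Numeric vector of effect sizes (default
#'   `c(0.3, 0.5, 0.7)`).
#' @param designs Character vector of designs (default parallel + crossover).
#' @param alpha,power Passed to [required_n()].
#' @return A tibble with one row per frequency row x effect size x design:
#'   the input columns plus `effect_size`, `design`, `subgroup_n` (per group
#'   for parallel, total for crossover) and `screening_n`.
#' @export
screening_table <- function(frequencies,
                            effect_sizes = c(0.3, 0.5, 0.7),
                            designs = c("parallel", "crossover"),
                            alpha = 0.05, power = 0.8) {
  freq <- tibble::as_tibble(frequencies)
  need <- c("etiology", "phenotype", "frequency")
  if (!all(need %in% names(freq))) {
    rlang::abort(paste0("`frequencies` must have columns: ",
                        paste(need, collapse = ", ")))
  }
  bad <- is.na(freq$frequency) | freq$frequency <= 0 | freq$frequency > 1
  problems <- freq[bad, ]
  ok <- freq[!bad, ]

  grid <- tidyr::expand_grid(effect_size = effect_sizes, design = designs)
  grid$subgroup_n <- purrr::map2_int(
    grid$effect_size, grid$design,
    ~ required_n(.x, .y, alpha = alpha, power = power)
  )
  out <- tidyr::crossing(ok, grid)
  out$screening_n <- screening_size(out$subgroup_n, out$frequency)
  attr(out, "problems") <- problems
  out
}
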