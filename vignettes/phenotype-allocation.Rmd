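---
title: "Allocating sensory phenotypes from QST z-profiles: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allocating sensory phenotypes from QST z-profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qstphenotype)
```

## The model

Quantitative sensory testing (QST) under the DFNS protocol yields 13
parameters per patient. Eleven are z-transformed against age-, sex- and
body-region-matched reference data, so that in healthy subjects each has mean
0 and SD 1 and values outside ±1.96 are abnormal at the 5% level
(`flag_abnormal()`, strict inequality). Paradoxical heat sensation (PHS) and
dynamic mechanical allodynia (DMA) do not occur in healthy subjects and are
carried as discrete codes instead: PHS 0/2 for absence/presence
(`code_phs()`), DMA 0/2/3 for no allodynia, mean tactile-pain ratings below
1, and ratings from 1 to 100 on the 0–100 NRS (`code_dma()`; a rating of
exactly 1 codes to 3, since the "below 1" band is open at the top).

Each of the three sensory phenotypes — sensory loss (SL), thermal
hyperalgesia (TH), mechanical hyperalgesia (MH) — is summarized by a
centroid: per-parameter means $\mu_i^{(m)}$ and SDs $\sigma_i^{(m)}$ from the
defining cluster analysis. Classification by Euclidean distance to the
centroid would discard every patient with a missing value (and imputation
could bias the result), so the allocation instead scores each parameter by a
*normalized Gaussian density*:

$$F_i^{(m)}(z) \;=\; 100\,\exp\!\left(-\frac{(z - \mu_i^{(m)})^2}
{2\,{\sigma_i^{(m)}}^2}\right)\,[\%],$$

the phenotype's density at the observed value divided by its maximum, so the
score is 100% exactly at the centroid mean regardless of how broad the
density is, and decreases strictly with the standardized distance. The
package computes this closed form directly; a test verifies its equivalence
to the density-ratio definition to $10^{-12}$ relative error over randomized
inputs. The phenotype probability is the arithmetic mean of $F$ over the
*non-missing* parameters — a missing value simply drops out of the average,
and the same non-missing set is used for all phenotypes of a subject, so the
four probabilities of a subject remain comparable. A fourth probability, for
having a *healthy* profile, uses $\mu = 0, \sigma = 1$ for every parameter
(including PHS and DMA), which is the definition of the z-scale.

Two allocation rules are exposed by `qst_allocate()`:

* **deterministic** — the single phenotype with the highest probability, by
  default over {SL, TH, MH, HEALTHY} (`include_healthy = TRUE`, the
  recommended final form) or over the three phenotypes only;
* **probabilistic** — all phenotypes with probability strictly above a
  cutoff. Patients with an empty label set are excluded, whether or not the
  healthy probability also clears the cutoff (a healthy-only exceedance is
  also an exclusion); `healthy_flag` reports the healthy exceedance
  separately.

The **simplified protocol** restricts the average to WDT and MPS, the two
parameters explaining the largest part of the between-phenotype variance; it
is algebraically identical to the full protocol applied to a profile whose
other 11 parameters are missing (a property the tests check directly; with
the default missingness cap the full-protocol call on such a profile refuses
to compute, so the test passes `min_params = 1`).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cutoff` | 64 (%) | probabilistic threshold, strict `>`; 64 is the Youden-optimal cutoff of the healthy-profile probability reported for the full protocol, and is retained for the simplified protocol as well because its own optimum (63) is within one point |
| `include_healthy` | `TRUE` | deterministic argmax over 4 vs 3 profiles |
| `min_params` | 7 (full), 2 (simplified) | minimum non-missing parameters; averaging over very few parameters is statistically fragile, so subjects below the cap are reported as not computable rather than given a noisy probability. The cap is a package choice — the source algorithm is silent on it — and can be lowered to 1 to reproduce the permissive behaviour. |
| `ci_method` | `"hanley"` | AUC 95% CI; Hanley–McNeil normal-approximation SE by default, DeLong via pROC by flag |
| `thresholds` | `"observed"` | ROC sweep over all distinct observed scores (exact); `"integer"` mimics a 0–100 percentage grid |

Ties in the deterministic argmax are a zero-probability event for continuous
profiles but reachable for coded or degenerate inputs; they are broken by the
fixed order SL > TH > MH > HEALTHY and flagged (`tie_flag`) for audit. Ties
in the Youden criterion are broken toward the higher specificity — the
conservative direction, misclassifying fewer healthy subjects as patients —
and then toward the higher threshold.

## The centroid table

The exact centroid values of the defining cluster analysis are not shipped:
the packaged table (`centroids_synthetic.csv`) is a labelled *synthetic*
stand-in constructed to reproduce the qualitative phenotype structure on the
DFNS sign convention (detection loss negative, gain of pain sensitivity
positive): SL with marked thermal and mechanical detection loss, TH with
near-normal detection and mild heat/cold hyperalgesia, MH with thermal loss,
pinprick hyperalgesia and allodynia. Every quantitative claim validated by
the tests is independent of the specific values: the anchors (100% at the
centroid, the closed-form equivalence, the exclusion rules, protocol
equivalence) hold for any valid centroid table, and the recovery simulations
condition on whichever table generated the data. Users with access to the
published centroid table load it with `qst_centroids(path)`; the sign
convention of the profiles must match the table, and no re-signing is
performed.

## The synthetic cohort generator

`generate_cohort()` draws each continuous parameter independently from
$\mathcal N(\mu_i^{(m)},\, (s\,\sigma_i^{(m)})^2)$ around the subject's true
phenotype centroid ($s$ = `sd_scale`, default 1 — the SDs of the centroid
table are taken at face value), healthy subjects from the $(0, 1)$
reference. This emulates the approximate normality of QST z-values and the
cluster-conditional structure the allocator assumes. PHS and DMA are drawn
from the same Gaussians and snapped to the nearest legal code
(`"thresholded"`; an exactly equidistant draw snaps to the lower code);
`"gaussian"` leaves them continuous for stress testing and is deliberately
non-conformant. Missingness is applied per cell, independently, never
removing a subject's last value.

What the generator does *not* emulate: correlations between parameters
(thermal detection parameters are mechanistically linked and plausibly
intercorrelated, but no covariance structure is published, so the generator
is diagonal), center effects, covariate structure, or heavier-than-normal
tails. Passing recovery tests therefore show that the allocator inverts its
own generative assumptions — at `sd_scale = 0` it must recover every label,
and recovery must degrade monotonically as noise grows — not that it attains
any particular accuracy on real patients, whose within-cluster dispersion
and correlation may differ. The pinned recovery rates in the test suite
(1.00 / 0.995 / 0.83 / 0.50 at `sd_scale` 0/0.5/1/2, 200 subjects per
phenotype, fixed seed) are regression fixtures for the packaged synthetic
centroids, not clinical claims.

Reproducibility: R's default Mersenne-Twister RNG via `withr::with_seed()`;
a seed is mandatory and identical seeds give bit-identical cohorts.

## Sample-size arithmetic

`cohen_d()` converts a mean treatment effect and response SD to a
standardized effect size. `required_n()` returns the *minimal* integer n
achieving the target power: the two-sample and paired noncentral-*t* power
functions are evaluated through `stats::power.t.test()` at integer n
(crossover trials are modeled as a paired comparison of within-subject
differences with the effect size on the difference scale; carry-over and
period effects are out of scope), and the dichotomous family through the
noncentral-χ² tail (`props_to_w()` converts two outcome proportions to
Cohen's w). Tests are two-sided by default with a one-sided flag. The test
suite verifies minimality independently against Monte-Carlo simulation of
the raw t statistics (50,000 replicates per design-effect cell: the
simulated power at n must reach the target and at n − 1 must fall below it,
within Monte-Carlo error).

`screening_size()` applies the prevalence inflation
$N = \lceil n / f \rceil$ for phenotype frequency $f$, and
`screening_table()` crosses effect sizes {0.3, 0.5, 0.7} × designs ×
user-supplied frequency rows, reporting per-group n for parallel designs and
total n otherwise (counts are always ceiling-rounded and labelled to avoid
the per-group/total ambiguity).

## Numerical and degenerate-input choices

* The similarity underflows to exactly 0 beyond ~38 σ from the centroid;
  probabilities remain well-defined (the contract range (0, 100] refers to
  representable values).
* ROC with all scores identical returns AUC 0.5 with a warning; empty score
  vectors are an error.
* The trapezoidal AUC over the observed-score sweep equals the Mann–Whitney
  U statistic divided by $n_1 n_2$ with ties counted ½ (tested exhaustively
  at small n).
* Cohen's kappa for two identical constant labelings ($p_e = 1$) is defined
  as 1 with a warning; the CI uses the large-sample SE
  $\sqrt{p_o(1-p_o)/(n(1-p_e)^2)}$ without bias correction, clipped to
  $[-1, 1]$; labels are nominal, no weighting.
* CSV round-trips are bit-exact: profile values are written with `%.17g` and
  parsed with base R's correctly-rounded `strtod`.
* Whether the 64% cutoff is compared with `>` or `≥` at the exact boundary
  is undocumented in the source algorithm; this package uses strict `>`
  everywhere ("above the cutoff") and records the cutoff in the output.

## Problem sizes used in validation

The test suite simulates cohorts of 150–720 subjects for allocation and
recovery checks, 10,000 subjects for generator-moment checks, exhaustive
ROC instances at $n \le 8$ for the U-statistic equivalence, and 50,000
Monte-Carlo replicates per cell for power verification — sizes at which
every oracle is exact or its Monte-Carlo error is far below the tested
margins.

## Known limitations

* Parameters are treated as independent in both the allocator (the mean of
  per-parameter similarities implicitly weights intercorrelated domains,
  e.g. the thermal detection block, more heavily) and the generator; a
  covariance-aware (Mahalanobis-style) classifier is explicitly out of
  scope because only $(\mu, \sigma)$ are published.
* The allocation averages the whole profile, so a single strongly abnormal
  parameter in an otherwise normal profile can still yield a high healthy
  probability — the healthy criterion is specific, not sensitive, by design.
* Cohort-dependent published results (re-sorting agreement, AUC of the
  original cohorts, phenotype frequencies per etiology) require the original
  patient data and are not reproduced by this package; validation is by
  analytic anchors, independent oracles and simulation.
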