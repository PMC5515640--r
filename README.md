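# qstphenotype

Sensory-profile stratification for peripheral neuropathic pain.

Patients with neuropathic pain — whether from diabetic polyneuropathy (DPN),
peripheral nerve injury (PNI) or postherpetic neuralgia (PHN) — fall into
three recurring somatosensory phenotypes identified by cluster analysis of
quantitative sensory testing (QST) profiles:

* **SL** – *sensory loss*: thermal and mechanical hypoesthesia,
* **TH** – *thermal hyperalgesia*: largely preserved detection with mild heat
  or cold hyperalgesia (the "irritable nociceptor" pattern),
* **MH** – *mechanical hyperalgesia*: thermal loss combined with pinprick
  hyperalgesia or allodynia.

These phenotypes plausibly map onto different pain mechanisms and different
drug responses, so phenotype-stratified trials need a way to allocate an
*individual* patient to a phenotype from their 13 DFNS QST z-values —
including patients with missing values, which are common and which rule out
plain centroid-distance classifiers. `qstphenotype` is aimed at trial
designers and QST researchers who need that allocation plus the surrounding
trial arithmetic.

## The algorithm

For patient *n*, QST parameter *i* and phenotype *m* with centroid mean
μᵢ⁽ᵐ⁾ and SD σᵢ⁽ᵐ⁾, the per-parameter similarity is the Gaussian density
normalized to its own maximum,

```
F = 100 · exp( −(zᵢ⁽ⁿ⁾ − μᵢ⁽ᵐ⁾)² / (2 σᵢ⁽ᵐ⁾²) )   [%]
```

so a value exactly at the centroid mean scores 100%. The phenotype
probability is the arithmetic mean of F over the *non-missing* parameters
(missing values are left out, never imputed). A fourth probability — for
having a *healthy* profile — uses μ = 0, σ = 1 for every parameter, which is
the definition of the z-transform. Two allocation rules are provided:

* **deterministic** — assign the single phenotype with the highest
  probability (ties broken SL > TH > MH > HEALTHY and flagged);
* **probabilistic** — assign *all* phenotypes whose probability exceeds a
  cutoff (default 64%, the Youden-optimal threshold of the healthy-profile
  probability); patients with no phenotype above the cutoff, or only the
  healthy profile above it, are excluded.

A **simplified** protocol uses only WDT and MPS, the two parameters that
explain most of the between-phenotype variance. PHS and DMA, which do not
occur in healthy subjects, enter as discrete codes (0/2 and 0/2/3).

The package also provides ROC/AUC analysis of the healthy-profile
probability with Hanley–McNeil or DeLong confidence intervals and
Youden-index cutoff selection, Cohen's kappa agreement between allocation
variants, phenotype-frequency summaries, power-based subgroup sizes
(noncentral-*t* and noncentral-χ² families) with screening-population
inflation by phenotype frequency, and a synthetic cohort generator for
validation.

**Note on centroids:** the packaged centroid table
(`inst/extdata/centroids_synthetic.csv`) is a *synthetic* stand-in that
reproduces the qualitative phenotype structure; supply the centroid table of
the defining cluster analysis via `qst_centroids(path)` for real use. No
re-signing of z-values is performed — input profiles must use the same
loss/gain sign convention as the centroid table.

## Worked example

```r
library(qstphenotype)

cohort <- generate_cohort(c(SL = 60, TH = 60, MH = 60, HEALTHY = 30), seed = 42)
alloc  <- qst_allocate(cohort, mode = "deterministic")
summarize_cohort(alloc)
#>   measure            n   pct
#> 1 SL                62  29.5
#> 2 TH                37  17.6
#> 3 MH                68  32.4
#> 4 HEALTHY           43  20.5
#> 5 not_computable     0  NA
```

Each subject gets four probabilities and the argmax label; here 43 of the
210 simulated subjects (including most of the 30 simulated healthy controls)
look healthy-like. Against the simulation's ground truth, the patient
phenotypes are recovered well above the 33% chance level:

```r
patients <- cohort[cohort$true_phenotype != "HEALTHY", ]
truth_recovery(patients, qst_allocate(patients, include_healthy = FALSE))
#> Phenotype recovery on 180 subjects: accuracy 81.1%, kappa 0.72
```

The healthy-profile probability separates patients from controls; the ROC
analysis picks the probability cutoff with the highest Youden index:

```r
roc <- roc_healthy(qst_allocate(patients)$p_HEALTHY,
                   qst_allocate(cohort[cohort$true_phenotype == "HEALTHY", ])$p_HEALTHY)
roc
#> ROC of healthy-profile probability: 180 patients vs 30 healthy
#>   AUC = 0.823 (95% CI 0.758-0.888, hanley)
#>   Youden cutoff = 67.9% (J = 0.600)
autoplot(roc)
```

Trial planning: a crossover trial powered at 80% for an effect size of 0.5
needs 34 subjects with the target phenotype; if that phenotype occurs in 33%
of the etiology of interest, 104 patients must be screened:

```r
screening_table(tibble::tibble(etiology = "DPN", phenotype = "TH", frequency = 0.33))
#>   etiology phenotype frequency effect_size design    subgroup_n screening_n
#> 3 DPN      TH             0.33         0.5 crossover         34         104
#> 4 DPN      TH             0.33         0.5 parallel          64         194
#> ...
```

A thin command-line front end over the same functions is installed at
`system.file("cli", "qstphenotype.R", package = "qstphenotype")` with
`allocate`, `plan` and `simulate` subcommands.

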