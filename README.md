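# metwave

Clonal-trajectory analysis of cancer metastases from their measured
diameters.

## The problem

When a tumour seeds metastases it can do so along two idealised routes.
Under **linear** dissemination, fully malignant clones leave the primary in
discrete waves; the members of one wave land in a similar environment at
the same time, grow at a similar rate, and therefore show up on imaging as
a cluster of near-identical diameters. Under **parallel** dissemination,
immature disseminated tumour cells leave early and mature independently in
the target organ, so their diameters are dispersed and cannot be grouped.
Which route dominates has direct clinical consequences: if spread is
linear and early, metastases are already present (if undetectably small)
when the primary is diagnosed, and local treatment alone cannot prevent
later recurrence.

`metwave` operationalises this idea for per-patient sets of lung and liver
metastasis diameters, as measured on CT. It is aimed at clinical
researchers analysing metastasis-size tables, and ships a full synthetic
cohort generator so the entire pipeline can be exercised and validated
without patient data.

## The statistic

Within one patient and organ, diameters are sorted and partitioned by a
one-dimensional gap rule with an organ-specific tolerance `t` (1 mm for
lung, 3 mm for liver, reflecting measurement precision). Under the default
single-linkage rule a *wave* ends wherever an adjacent gap exceeds `t`;
groups of size ≥ 2 are waves, the rest are *isolated*. A greedy
complete-linkage variant (cluster width ≤ `t`) is available for
sensitivity analysis. The linear/parallel ratio is

    LPR = (Σc − Σi) / (Σc + Σi)

where `Σc` is the number of metastases belonging to waves and `Σi` the
number of isolated metastases. `LPR = +1` means every metastasis clusters
(pure linear spread); `LPR = −1` means none do.

Around this core the package provides: cohort tables (medians with
interquartile ranges per parameter; synchronous vs. metachronous
comparisons by two-sided Student's t-test), Kaplan–Meier survival with
complementary log-log confidence intervals, the Gehan–Breslow generalized
Wilcoxon test for curve comparison, and a dual-origin analysis that fits
the timing groups' curves from both the primary-diagnosis clock and the
metastasis-diagnosis clock — separating a detection lead time from a true
difference in clinical behaviour.

## Worked example

```r
library(metwave)

m <- system.file("extdata", "toy_metastases.csv", package = "metwave")
p <- system.file("extdata", "toy_patients.csv", package = "metwave")
cohort <- read_cohort(m, p)
#> Cohort: 2 patients, 7 metastases (0 rejected rows)

part <- cluster_waves(c(6.5, 7.5, 7.0, 12.0),
                      tolerance_mm = default_tolerance("lung"))
part
#> Wave partition (single linkage, tolerance 1.0 mm): 1 wave(s), 1 isolated
#>   wave 1: 6.5, 7.0, 7.5
#>   isolated: 12
compute_lpr(part)
#> LPR 0.500 (sum_c 3, sum_i 1, 1 wave(s), n = 4)
```

Three of the four lung metastases sit within a 1 mm-gap band — one
dispatch wave — while the 12 mm lesion is isolated, giving
LPR = (3 − 1)/(3 + 1) = 0.5: a mostly linear picture.

The same per-patient summary for every patient-organ set:

```r
summarize_cohort(cohort$metastases)
#>   patient_id organ n_total mean_diameter_mm largest_diameter_mm n_waves n_isolated       lpr
#> 1         P1  lung       4          8.25000                  12       1          1 0.5000000
#> 2         P2 liver       3         20.33333                  30       1          1 0.3333333
```

A full synthetic cohort (133 patients, composition and size distributions
emulating a metastatic pancreatic-cancer series) and its dual-origin
survival analysis:

```r
co  <- simulate_cohort(reference_scenario(seed = 1))
dual_origin_analysis(co$patients)
#> Dual-origin survival analysis (synchronous vs. metachronous)
#>         origin synchronous_median metachronous_median      p_value
#>     primary_dx                6.7                16.5 9.081401e-08
#>  metastasis_dx                6.7                 7.4 9.834924e-01
#> Lead-time difference: 9.1 months
```

Counted from primary diagnosis the metachronous group appears to survive
much longer (16.5 vs. 6.7 months, p ≈ 1e-7); counted from metastasis
diagnosis the difference vanishes (p = 0.98). The gap is pure lead time —
exactly the structure this generator encodes (shared post-metastasis
hazard, lognormal detection lead), recovered by the analysis.

A command-line front-end wrapping the same functions is installed at
`system.file("cli", "metwave.R", package = "metwave")` with subcommands
`lpr`, `survival` and `simulate`.

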