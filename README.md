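# spliceshift

Environmental perturbations — drugs, hormones, metal ions, vitamins —
change not only how much genes are expressed but *which isoforms* are
made. `spliceshift` is an R package for detecting and characterizing
treatment-induced shifts in alternative RNA processing from
exon-centric sequencing read counts, and for testing the trans-acting
mechanisms behind them. It is aimed at analysts working with panels of
treated versus vehicle-control RNA-seq libraries across cell types and
individuals.

## The statistical core

For each of eight event types (skipped exons SE, retained introns RI,
alternative 3'/5' splice sites, mutually exclusive exons, alternative
first/last exons AFE/ALE, tandem 3' UTRs) the percent spliced in is
estimated from reads unique to the inclusion/exclusion isoforms with a
conjugate Beta model, Psi | k, n ~ Beta(a + k, b + n − k), and each
treatment-vs-control comparison in one individual yields a delta-Psi
and a Bayes factor

    BF10 = B(a+k_t, b+n_t−k_t) B(a+k_c, b+n_c−k_c) / [ B(a,b) B(a+k_t+k_c, b+n_t+n_c−k_t−k_c) ]

comparing independent Psi values against a shared one. Because the
null distribution of BF10 depends on coverage and event type, the
package calibrates it *empirically*: comparisons between two vehicle
controls (CO2 vs CO1) run through the identical filters provide a null
BF sample per event type, and each treatment BF gets the add-one
empirical p-value `p = (1 + #{null ≥ BF}) / (1 + n)`. Each p-value
becomes a direction-signed score

    Z = sign(deltaPsi) × |Q(p/2)| ,    Q = qnorm,

Z-scores are combined across the 2–3 individuals measuring the same
event and environment by Stouffer's method (sum / sqrt(k)), and
Benjamini–Hochberg control at FDR 15% per event type defines the
significant shifts. Downstream layers quantify directional enrichment
(exact binomial against 50:50, ECDF/KS against the control null,
logistic treatment-by-event-type enrichment), correlate trans-factor
expression changes with the percent of positive events, predict shift
direction from motif-region indicators and TSS footprint imbalances
with an elastic-net logistic model (AUC at lambda.1se), and validate
the AFE mechanism with ATAC-seq accessibility ratio tests and cis-QTL
mapping of AFE usage.

A fully specified synthetic cohort generator (`cohort_config()`,
`simulate_cohort()`, plus footprint / ATAC / genotype arms) reproduces
the study design — cell types × treatments × 3 individuals, controls
in pooled technical replicates — with planted truth for every stage,
so every statistical guarantee is testable.

## Worked example

```r
library(spliceshift)
library(dplyr)

cfg <- cohort_config(n_events_per_type = 500,
                     event_types = c("SE", "RI", "AFE"), seed = 11)
pipe <- run_shift_pipeline(cfg, stages = c("global", "predict"),
                           min_null = 300)
glance(pipe$calls)
#> # A tibble: 1 × 4
#>   n_events n_tested n_significant nominal_fdr
#>      <int>    <int>         <int>       <dbl>
#> 1     1499     1496           484        0.15
pipe$directions
#> # A tibble: 3 × 8
#>   event_type cell_type treatment n_sig n_pos   ppe binom_p label
#>   <chr>      <chr>     <chr>     <int> <int> <dbl>   <dbl> <chr>
#> 1 AFE        CT1       T1          157    77 0.490   0.873 none
#> 2 RI         CT1       T1          157    76 0.484   0.750 none
#> 3 SE         CT1       T1          170    94 0.553   0.192 none
glance(pipe$classifier)
#> # A tibble: 1 × 7
#>   n_events cv_auc cv_auc_max lambda_1se lambda_max_auc n_nonzero alpha
#>      <int>  <dbl>      <dbl>      <dbl>          <dbl>     <int> <dbl>
#> 1      157      1          1      0.830          0.830         3     0.5
```

Of ~1,500 simulated events, 484 are called significant at the default
15% BH threshold (the generator plants true shifts in 30% of events by
default, and the cohort is deep enough to find most of them). No
environment is labelled directionally enriched (`label = none`): the
generator's default directional bias is the 50:50 null, so the exact
binomial test correctly finds nothing. The AFE direction classifier is
fit on the 157 significant AFE shifts and reaches a cross-validated
AUC of 1.0 because the synthetic footprint landscape couples
footprint-count imbalance to direction strongly (`coupling = 0.8` by
default) — with three causal motifs among thirty, `tidy(pipe$classifier)`
shows exactly those three carrying nonzero coefficients at
`lambda.1se`. `autoplot()` methods on the calls, the classifier and
the enrichment model give the standard diagnostic figures, and
`tidy()`/`glance()` follow broom conventions throughout.

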