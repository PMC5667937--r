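---
title: "Detecting environment-induced RNA-processing shifts: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting environment-induced RNA-processing shifts: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceshift)
library(dplyr)
```

## The problem

Cells respond to environmental perturbations — drugs, hormones,
nutrients, metals — by changing not only transcript abundance but which
isoforms they produce. Given exon-centric read counts from panels of
treated versus vehicle-control RNA-seq libraries (several cell types,
several individuals, controls in technical replicates), `spliceshift`
answers three questions: which alternative-processing events shift
under which treatment; whether shifts of a given type move coherently
in one biological direction, suggesting trans-acting regulation; and
whether binding of specific trans factors near the event predicts and
explains the shift.

This vignette documents the models, the parameters that matter, the
numerical decisions, and what the synthetic cohort does and does not
emulate.

## Per-event model

Each event is summarized by two counts per library: reads unique to
the inclusion isoform (`n_inc`) and reads unique to the exclusion
isoform (`n_exc`). For tandem 3' UTRs, where the short isoform is a
strict subset of the long one, `n_inc` counts reads specific to the
longer isoform and `n_exc` the remaining informative reads. With a
Beta(a, b) prior on the percent spliced in (PSI), the posterior is
Beta(a + n_inc, b + n_exc); the package defaults to the uniform
Beta(1, 1) prior, configurable where a stronger prior is justified.

A treatment-vs-control comparison in one individual yields
`delta_psi` (difference of posterior means) and a Bayes factor for
the two-independent-PSI model against the shared-PSI model. Because
the binomial coefficients cancel, the Bayes factor is a ratio of Beta
functions and is computed in closed form on the log scale
(`psi_log_bf()`); extreme counts can push `exp(log_bf)` past floating
range, so all downstream calibration works with log Bayes factors.
The closed form is verified in the test suite against numeric
integration of the marginal likelihoods at relative error 1e-6.

Comparisons are only trusted at adequate coverage: for all types
except tandem UTRs both samples need at least 2 reads per isoform and
10 informative reads; tandem UTRs need 5 long-isoform reads and 10
informative reads in both samples. Failing comparisons are kept as
typed rejections (`filter_pass = FALSE` with a reason), never
silently dropped, because the "measurable in at least 2 of 3
individuals" rule downstream needs to know why a comparison is absent.

## Direction conventions

Five event types carry a global direction; positive oriented
`delta_psi` always means: skipped-exon inclusion up, intron retention
up, the longer tandem UTR, the upstream alternative first exon, or the
downstream alternative last exon — on the transcribed strand. SE, RI
and TandemUTR counts already follow this convention; AFE and ALE are
flipped per event when isoform 1 of the annotation is not the
upstream-first/downstream-last isoform, with "upstream" meaning the
larger genomic coordinate on the minus strand. Alternative splice
sites and mutually exclusive exons have no global direction and are
flagged `directional = FALSE`. `orient_delta()` is idempotent
(tracked via an `oriented` flag) so pipelines can re-run safely.

## Empirical null and shift calling

The null distribution of the Bayes factor depends on coverage,
overdispersion and event type, so no analytic reference is trusted.
Instead, comparisons between two vehicle controls (CO2 vs CO1) in the
same individual and batch — which pass the identical filters — supply
an empirical null per event type. Each treatment comparison gets the
add-one empirical p-value `p = (1 + #{null >= BF}) / (1 + n)`, chosen
so p is never 0 and the normal quantile stays finite; ties count as
exceedances. The default minimum null size is 500 per event type;
below that the package asks for more control-vs-control data rather
than extrapolating.

Each p-value becomes `Z = sign(delta_psi) * |qnorm(p/2)|`, individuals
are combined by Stouffer's method (`sum(Z) / sqrt(k)`, requiring
k >= 2 of the 3 individuals; fewer is an exclusion, not an error), and
two-sided normal p-values from the combined Z are BH-corrected within
each event type across all environments jointly. The per-type family
was chosen because each event type has its own null and its own
tested-event universe; pooling across environments mirrors a single
ranked table per type. An event is a significant shift at q < 0.15.

## Global directional statistics

Per environment and directional event type, the package reports the
number of significant shifts, the percent positive events (PPE =
positive significant / all significant), an exact two-sided binomial
test against 50:50 (exact rather than normal-approximate because
environments with only tens of significant events are common; labels
at p < 0.05), and a two-sample Kolmogorov–Smirnov comparison of *all*
delta-PSI values — not only significant ones — against the
control-vs-control delta-PSI distribution. Environment summaries are
reported when at least 10 significant shifts exist.

Event-type composition is modelled by logistic regression
`significant ~ treatment * event_type + cell_type`; the interaction
Wald p-values flag treatments enriched for an event type beyond the
marginal rates. Per-treatment event-type proportions among significant
events are computed by reweighting fitted probabilities by the number
of events tested in each cell (the model states the goal, not the
arithmetic; this Bayes-consistent reweighting was the design choice).
With a single cell type the cell-type term is dropped; under complete
separation the package falls back to a ridge-stabilized glmnet fit for
coefficients, with a warning and no Wald p-values.

## Trans-factor association and direction prediction

Factor-level association correlates a factor's log-fold expression
change with PPE across environments (Spearman, BH within one event
type's family of factors, never across types; at least 10 environments
required to keep the rank test meaningful). Gene-level association
correlates log-fold change with the event's mean delta-PSI across
individuals, within treatment-by-type groups of at least 30 shifts.
Log-fold changes are inputs; differential-expression estimation is
deliberately out of scope.

Direction prediction uses an elastic-net logistic model (glmnet,
alpha = 0.5 by default; the mixing parameter is not dictated by the
method, so it is exposed). Features are binary motif-by-region
indicators for SE and RI — the five regions being the alternative
unit, its two flanks, and the 100 bp windows either side of the
relevant splice site (3' splice site for SE, 5' for RI), defined on
the transcribed strand, with a hit straddling a boundary setting both
windows — and, for AFE, the per-motif difference in footprint counts
within 1000 bp (closed interval, footprint midpoint) of the upstream
versus downstream TSS. An indicator (not a count) is used per region
because presence/absence is the level at which motif calls are
trustworthy. Cross-validation is 10-fold, stratified by label and
seeded; the reported model is at `lambda.1se`, the sparsest model
within one cross-validated standard error of the maximal AUC. The
inclusion rule (at least 100 significant events, both classes present)
is enforced as a refusal, matching the analysis the model implements.

## ATAC-seq validation arm

Fragments are reduced to Tn5 insertion sites 4 bp inside each 5' end
(`start + 4`, `end − 5` in 0-based coordinates) and to length bins
39–99, 100–139, 140–179, 180–250. Accessibility profiles around the
treatment-preferred versus non-preferred TSS of shifted AFE events
(relaxed q < 0.25 set, ±500 bp, fragments 30–140 bp) are normalized to
library totals, making them invariant to sequencing depth. The
per-motif test forms, for each footprint within 500 bp of a classified
TSS, the treatment/control ratio of normalized fragment counts in the
footprint's ±100 bp window (any overlap; a pseudocount of 1 on both
sides guards zero counts) and compares preferred- versus
non-preferred-class ratios with a two-tailed t-test — Welch by
default, pooled-variance available by flag since either reading of
"Student's t-test" is defensible — with BH across motifs at 5%.
Because the ratios are normalized per library, a global accessibility
change cancels and only *differential* change between the TSS classes
is detected; the t statistic is invariant to common positive scaling
of all ratios.

## AFE QTL arm

Per-event PSI across individuals is residualized on lab and population
indicators and on the first five principal components of the
covariate-residualized, mean-imputed PSI matrix (imputation is used
only to extract PCs, never for association), then inverse-normal
quantile normalized with offset `(rank − 0.5)/n`. Events must be
observed in at least 200 individuals. The scan is ordinary least
squares of normalized PSI on dosage for SNPs within 10 kb of either
TSS with minor-allele count at least 10; monomorphic SNPs are skipped.
Enrichment of binding-disrupting SNPs among QTLs is a Fisher exact
test on the 2×2 table of QTL-significance (nominal p < 0.05 by
default — the threshold feeding the table is not fixed by the method,
so it is configurable) against the binding flag, with sorted p-values
exported per class for QQ plots.

## The synthetic cohort

`cohort_config()` + `simulate_cohort()` emulate the study design:
cell types × treatments × 3 individuals, two or more vehicle controls
each applied in three technical replicates whose reads are pooled
before comparison. Key defaults and why:

* `read_depth = 300` informative reads per event per comparison
  sample; each control replicate draws depth/3 so the pooled control
  matches the treatment library depth. This equalization is what makes
  control-vs-control comparisons exchangeable with null
  treatment-vs-control comparisons — the property the empirical-null
  calibration relies on.
* `rho = 0.01` beta-binomial overdispersion of library-level PSI
  around the individual baseline, with one PSI realization per
  biological condition shared by its technical replicates. Pure
  binomial counts would make the empirical null trivially analytic;
  overdispersion makes the calibration an honest test.
* `effect_fraction = 0.3` of event-environment pairs carry a true
  shift with |delta-PSI| uniform on [0.15, 0.4], the same sign across
  individuals (trans-factor-like coherence); `pi_pos = 0.5` by
  default — directional bias is a planted condition, not a default.
* Baseline PSI is Beta(2, 2) mapped to [0.05, 0.95]; individual
  baselines overdisperse around it (`rho_individual = 0.01`).

The downstream arms plant their own truth: the footprint landscape
couples the upstream-minus-downstream footprint-count difference of
designated causal motifs to the event's direction with tunable
strength; the ATAC generator plants TSS-level and motif-level
treatment depletion (defaults mimic an overall accessibility loss
that is milder at the preferred TSS); the QTL panel plants logit-scale
dosage effects with binding-affecting SNPs enriched for nonzero
effects at configurable odds. Every generated dataset is accompanied
by its planted truth, and one global seed drives derived per-module
streams, so partial regeneration is reproducible.

What the generator does *not* emulate: read alignment and mapping
bias, isoform-length read-assignment corrections (counts are assumed
already isoform-unique), correlated effects across events in the same
gene, linkage disequilibrium between SNPs, and chromatin structure
beyond the planted depletion. Passing tests therefore demonstrate the
statistical machinery — calibration, FDR control, power, recovery of
planted couplings — not robustness to alignment artifacts of real
libraries.

## Numerical choices and degenerate inputs

* All internal coordinates are 0-based half-open; GFF I/O converts at
  the boundary (1-based inclusive on disk). A single internal
  convention prevents off-by-one drift.
* Log-scale Bayes factors throughout; `empirical_pvalue()` rejects
  NaN inputs and cannot return 0 by the add-one rule.
* `signed_z()` maps p = 1 to Z = 0 and errors on p outside (0, 1].
* Ties in the empirical null count as exceedances (conservative).
* Constant covariates are dropped with a warning in the QTL
  normalization; constant PPE vectors or expression vectors are
  excluded from correlation with a recorded reason; degenerate
  variance in the ATAC ratio test reports p = 1 with a flag.
* Significant events with delta-PSI exactly 0 (possible only through
  ties) are excluded from direction-classifier labels.

## Problem sizes used in the checks

The test suite and the acceptance script exercise the pipeline at
desk scale, chosen so each statistical check is stable: 5,000 events
per event type and 20 independent cohorts for the false-discovery
calibration; 5,000 events for the null-Z normality check; 20 seeds for
each power check (directional binomial, enrichment GLM, classifier,
ATAC, QTL); 100 replicates for the QTL coverage check. A full
calibration run completes in a few minutes on one CPU.

## Known limitations

The Bayes factor's absolute scale depends on the Beta prior and on
the counts being isoform-unique; it is therefore never interpreted
directly, only through the empirical null. BH across events assumes
exchangeability within an event type; cross-individual random effects
and hierarchical shrinkage of delta-PSI are out of scope. The
enrichment model's ridge fallback provides coefficients but no
hypothesis tests. The QTL arm takes population labels as given and
performs no structure inference or genotype imputation.
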