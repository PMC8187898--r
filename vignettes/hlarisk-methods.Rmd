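---
title: "Carrier-based HLA risk analysis: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carrier-based HLA risk analysis: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlarisk)
```

## The problem

Aromatic antiepileptic drugs — carbamazepine (CBZ), lamotrigine (LTG) and
oxcarbazepine (OXC) — are a leading cause of cutaneous adverse drug
reactions. The mildest common form, maculopapular exanthema (MPE), still
forces drug discontinuation, and specific HLA class I/II alleles raise its
risk in a drug- and population-specific way. hlarisk implements the
statistical pipeline of a case-control pharmacogenomic study of this
design: patients who developed MPE on a drug (cases) versus patients who
tolerated the same drug for months (drug-tolerant controls), both typed at
HLA-A, -B, -C and -DRB1 at two-field resolution.

The unit of analysis throughout is **carriage**: an individual carries an
allele if at least one of the two calls at that locus equals it, and
homozygotes count once. Carrier status, not allele dose, is what a
pre-prescription screening test would act on, and it is the quantity the
field's published tables report.

## Association scans

For each allele the package forms the 2x2 carrier table

|          | carrier | non-carrier |
|----------|---------|-------------|
| cases    | a       | b           |
| controls | c       | d           |

with denominators counting only individuals typed at that locus — DNA
shortfalls make denominators differ across loci within one cohort, and
shrinking per locus wastes less information than dropping whole records.

Carrier rates are compared by the 2-by-2 chi-square test. Published studies
of this design rarely state their small-sample convention, so the package
makes it explicit and automatic: the **Yates continuity correction is
applied iff any expected cell count is below 5**, otherwise the uncorrected
Pearson statistic is used (`select_test()`). This single rule reproduces
every carrier-rate p-value in the motivating study's tables, including the
sparse DRB1\*04:06 table where the uncorrected statistic would overstate
significance by a factor of ~3. Fisher's exact test is available
(`fisher_exact()`) as a diagnostic for very sparse tables, but its
two-sided p does not reproduce those published values, which is why it is
not in the automatic rule.

Odds ratios use the cross-product with the Woolf log-scale interval,

\[
\mathrm{CI} = \exp\!\left(\ln\frac{ad}{bc} \pm z\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\right),
\]

with `z = 1.959964` rather than the textbook 1.96: the extra digits matter
at the extreme upper bounds of sparse tables (they are what makes a printed
bound like 142.72 reproduce exactly). Tables with a zero cell receive the
Haldane–Anscombe +0.5 on all four cells, flagged in the output; an allele
absent from both arms has no estimable OR and is reported as undefined
rather than silently corrected.

Multiple testing is corrected per locus by Bonferroni, where the
multiplicity is the number of **distinct alleles observed at that locus in
that drug cohort, cases and controls combined** — the full enumerated
count, even when rare alleles (default: fewer than 3 pooled carriers,
`min_carriers`) are excluded from testing. This inference about the
multiplicity universe matches the per-locus allele counts the motivating
study prints; protective alleles (OR < 1) are retained in scans.

When cohorts for several drugs are pooled, individuals tolerant to more
than one drug are counted once (de-duplication by sample id). The source
data do not state how a case-for-one-drug / control-for-another conflict
was resolved; the package keeps such individuals as cases — the phenotype
"developed MPE on an aromatic AED" is established by either record — and
reports the conflict rather than resolving it silently.

## Screening metrics

Sensitivity and specificity come from the carrier table
(`a/case_total`, `1 - c/control_total`). Because the case:control ratio is
a design artefact, PPV and NPV are computed at an **external prevalence**
of the reaction supplied per drug; the defaults (`MPE_PREVALENCE`: CBZ
3.7%, LTG 4.8%, OXC 9%, pooled 2.8%) are literature incidence estimates.
The number needed to test is `1/(prevalence x sensitivity)`, reported as
the next whole person (ceiling): a screening programme cannot test a
fractional individual, and this rounding reproduces the published NNT
column (218, 162, 646, 848, 333, 71, 86) with a single convention. The one
published value it does not hit is the pooled DRB1\*04:06 row (544.12
prints as 544 there), which no single rounding rule can reconcile with the
rest of that column.

`predictive_values()` has a `digits` argument because published tables in
this field typically combine the *rounded percentage* sensitivity and
specificity (e.g. 15.69% and 98.94%) rather than the exact fractions;
`digits = 4` on the proportion scale reproduces that printed arithmetic
(the exact-fraction PPV differs in the first decimal). Analysis use should
leave it unset.

Allele sets are screened as a union ("carrier of any"). With incomplete
typing the middle case matters: an individual who carries none of the set
at the typed loci but is untyped at another relevant locus *might* carry
there, so such individuals are excluded from the denominators (as are the
fully untyped); a carrier at any typed locus counts regardless of other
loci. This is the only reading consistent with the published combined
A\*24:02/B\*38:02 denominators, which equal the doubly-typed subset rather
than the per-locus totals.

## Two-locus interaction

`build_joint_table()` cross-classifies carriage of two alleles at different
loci into four strata, excluding individuals untyped at either locus.
Stratum odds ratios take the double-negative stratum as reference. The
decomposition contrasts the observed joint OR with its no-interaction
expectation on two scales:

* multiplicative: expected OR\_joint = OR\_A x OR\_B; the interaction ratio
  is OR\_joint divided by that expectation;
* additive: expected OR\_joint = OR\_A + OR\_B − 1; the excess risk is
  OR\_joint minus that expectation.

`decompose_interaction(rounding = 2)` first rounds the component ORs to two
decimals, reproducing published footnote arithmetic (2.95 = 1.40 x 2.11
style); unrounded combination differs by at most one unit in the last
printed decimal and is the default for analysis.

The accompanying logistic model is fit on the grouped data (binomial counts
per stratum) with indicator main effects and a product term; grouped and
per-individual likelihoods have the same MLE, and the grouped fit is
deterministic and cheap. With four strata and four parameters the model is
saturated, so fitted ORs equal the empirical cross-product ratios — the
test suite uses this identity as an internal oracle. Perfect separation (a
non-empty stratum containing only cases or only controls) is detected and
flagged instead of reporting a spuriously converged fit.

## Meta-analysis

Per-study effects are Woolf log-ORs with variance `1/a+1/b+1/c+1/d`;
studies containing a zero cell get +0.5 on all four cells (flagged). The
fixed-effect pool is Mantel–Haenszel on the uncorrected counts with the
Robins–Breslow–Greenland variance; the random-effects pool is
DerSimonian–Laird. These are the defaults of the review software named by
the motivating study, which reports only "fixed model"/"random model";
since the inverse-variance fixed pool is occasionally meant instead, the
reduction `pool_random_dl(tau2 = 0)` provides it, and the output records
which methods were used.

Heterogeneity is quantified by Cochran's Q (chi-square, k−1 df), I² =
max(0, (Q−(k−1))/Q)·100 and the DL moment estimator of τ². The
model-selection rule — **random effects iff Q's p < 0.1 AND I² > 50%** —
is read as a conjunction; both sub-conditions are reported separately so a
disjunctive reading can be audited on any result.

The motivating study's forest plots cannot be reproduced desk-side (its
per-study counts are not printed), so the meta stage is validated by
properties instead: single-study identities, zero heterogeneity on
identical studies, agreement with an independent reference implementation
(metafor) on fixed data, the type-I error of Q at its 0.1 screening level,
recovery of a planted common OR, and random-effects CI coverage under
planted heterogeneity. The bundled study CSV is synthetic and labelled so.

## The synthetic cohort generator

The generator exists so every stage is testable without the (undeposited)
raw genotypes. It emulates:

* **Hardy–Weinberg genotypes**: two independent draws per locus from a
  per-locus allele-frequency profile; loci independent (the motivating
  cohort showed no haplotype clustering among its risk alleles, so linkage
  is deliberately not modelled). Frequencies not modelled individually go
  to a per-locus catch-all allele (`*00:00`).
* **Disease**: Bernoulli with logit risk from carrier indicators —
  configurable intercept, per-allele log-ORs and an optional two-allele
  product term.
* **Case-control ascertainment**: a source population is simulated at the
  intercept-implied prevalence and exactly n cases / n controls are drawn
  from it, reproducing the retrospective design (the carrier OR is
  invariant to this sampling; the intercept is not recoverable).
* **Missingness**: per locus, both calls of an individual are removed with
  the configured probability, emulating insufficient-DNA dropout
  (default 3%).
* **Between-study heterogeneity**: per-study true log-ORs drawn
  Normal(mu, tau²) with binomial carrier counts for the meta stage.

Defaults are calibrated to the motivating study's conditions: arm sizes
54/133 (its OXC arm), risk-allele frequencies chosen so Hardy–Weinberg
carrier rates match its tolerant-arm carrier rates (DRB1\*04:06 at the 2.1%
population frequency it cites), a single DRB1\*04:06 effect of OR 17.3,
and an intercept at the 9% OXC reaction incidence. Background alleles at
plausible East Asian frequencies pad each locus so that enumerated allele
counts — and hence Bonferroni multiplicities — are realistic.

What the generator does **not** emulate: population structure and
relatedness, linkage between HLA loci, genotyping error, G/P ambiguity
groups, covariates (age, sex, dose), and secular recruitment effects.
Passing recovery tests therefore shows the estimators are correct under
the design's own assumptions, not that real cohorts satisfy them.

Every generator takes one integer seed; derived stages use fixed offsets
from it, and the RNG state is scoped so generators never perturb the
caller's stream. Identical (config, seed) gives identical bytes on disk.

## Numerical conventions and degenerate inputs

* Chi-square tests refuse degenerate margins (an empty row or column).
  In locus scans, a universally carried allele (single-allele locus)
  yields an NA p rather than an error, keeping the rest of the scan.
* `carrier_table` validates non-negative integers, positive totals and
  carriers <= totals at construction, so downstream code never sees an
  inconsistent table.
* GLM convergence tolerance 1e-12 (deviance), max 100 IRLS iterations;
  the saturated four-stratum fit converges in a handful.
* τ² is floored at 0; I² is reported in [0, 100].
* Allele names accept `HLA-A*24:02`, `A*24:02`, and bare `24:02` with an
  explicit locus; higher-resolution names are truncated to two fields with
  a warning (synonymous fields are irrelevant to carriage); malformed
  names error with the offending token.

## Validation problem sizes

The test suite exercises the simulation-based properties at sizes chosen to
keep the whole suite fast while leaving comfortable statistical margins:
null calibration at 150/arm over 400 replicates, meta operating
characteristics over 300–500 replicates of 8–12 studies, single-allele OR
recovery at 5 000/arm, and product-term recovery at 80 000 individuals
(200 replicates of 4 000 for the mean-recovery check). The acceptance
script re-derives the published-table statistics from the printed counts
and re-runs the simulation checks at 500 replicates.

## Known limitations

* Crude 2x2 comparisons only: no covariate adjustment, no permutation or
  exact multiplicity control, no haplotype-level tests.
* Screening metrics carry no confidence intervals (the published design
  reports none); treat PPV/NPV/NNT as point summaries conditional on the
  external prevalence estimate.
* The additive-scale excess risk is a contrast of odds ratios, the
  customary approximation in this literature; it equals a risk-scale
  contrast only for rare outcomes.
* DerSimonian–Laird coverage is known to run slightly below nominal at
  moderate k with large τ² — visible in the coverage check — which is a
  property of the estimator, not of this implementation.
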