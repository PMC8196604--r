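---
title: "Evaluating stability and pathogenicity predictors on cancer missense variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating stability and pathogenicity predictors on cancer missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varstab)
```

## The problem

A missense variant in a cancer-related gene can act through many
mechanisms; one of the most common is the loss of thermodynamic stability
of the folded protein. Two kinds of computational scores are in routine
use: predictors of the folding free energy change
$\Delta\Delta G_f = \Delta G_f^{mut} - \Delta G_f^{wt}$ (kcal/mol, positive
= destabilizing), and pathogenicity meta-predictors that return a
probability-like score in $[0,1]$. `varstab` evaluates both kinds of score
against two ground truths on a curated variant table: experimentally
measured $\Delta\Delta G_f$, and driver-evidence annotations from the
COSMIC Cancer Mutation Census (CMC), where Tier 1–3 variants are treated
as putative cancer-driving variants (PCVs) and "Other" as benign.

The package runs four analyses:

1. **Stability regression** — Pearson, Spearman and Kendall tau-b
   correlations plus RMSE and MAE between predicted and experimental
   $\Delta\Delta G_f$, pooled, after outlier exclusion, and per protein
   group.
2. **Destabilization classification** — each score as a binary classifier
   of highly destabilizing variants
   ($\Delta\Delta G_f > 2$ kcal/mol), with fixed, optimized and
   cross-validated thresholds.
3. **Driver (PCV) classification** — the same machinery against Tier 1–3
   membership on the annotated subset, with predictor-training variants
   removed.
4. **Enrichment** — Fisher exact association of driver annotation with
   destabilization, Kolmogorov–Smirnov comparison and class means of the
   pathogenicity score by tier, buried/exposed fractions, and one-sided
   exact binomial tests in the four corners of two feature planes
   (burial $\times$ conservation; destabilization $\times$ pathogenicity).

## Conventions that matter

All binary decisions in the package use a single strict-inequality rule:
a score predicts positive iff it is strictly greater than the threshold,
and a variant is destabilizing iff its $\Delta\Delta G_f$ is strictly
greater than the 2.0 kcal/mol cut. A value exactly at a cut is therefore
negative/low. The feature-plane boundary rules are configurable per axis,
with defaults *buried* = RSA $\le 0.2$ (the boundary value is buried) and
*conserved* = $f_{WT} > 50\%$ (the boundary value is not conserved).
The literature writes the burial cut both as "RSA $\le$ 0.2" and
"RSA < 20%"; we adopt the inclusive form and expose
`quadrant_spec(x_boundary=)` for the alternative.

Threshold optimization balances the true positive and true negative
rates: candidates are the midpoints between consecutive sorted unique
scores plus one candidate below the minimum and one above the maximum,
and the candidate minimizing $|TPR - TNR|$ wins. Ties are broken by
larger MCC, then by smaller threshold, which makes the search
deterministic and independent of input order.

Cross-validated threshold selection uses stratified folds (each class is
permuted under the caller's seed and dealt round-robin). The literature
does not state how per-fold thresholds combine; we take the median of the
$k$ fold thresholds and then report metrics once on all data at that
threshold, alongside the full-data optimized threshold, so both readouts
are visible.

Two further conventions: MCC is defined as 0 when any confusion-matrix
marginal is zero, and AUC is the rank-based (Mann–Whitney) probability
that a random positive outscores a random negative with ties counting
one half — hence invariant under any strictly increasing transform of
the scores.

The relation between a pathogenicity score and the destabilization label
can be summarized either as a point-biserial correlation (score vs the
binary label) or as a plain Pearson correlation (score vs continuous
$\Delta\Delta G_f$). Published summaries are ambiguous between the two,
so `run_destab_classification()` reports both and asserts neither as
canonical.

## Statistical tests

- **Fisher exact** (`fisher_2x2`): two-sided under the
  probability-ordering definition — the sum of hypergeometric
  probabilities of all tables with the observed margins that are no more
  probable than the observed table. This is the most common convention
  for the exact test and is what `stats::fisher.test()` computes; the
  test suite additionally verifies it against a full-enumeration oracle
  for small tables.
- **Kolmogorov–Smirnov** (`ks_two_sample`): $D$ is the supremum over the
  pooled sample of the absolute ECDF difference; the p-value is exact for
  tie-free samples with both sizes $\le 25$ and asymptotic (effective-n)
  otherwise.
- **Binomial corner tests** (`binomial_corner_test`): one-sided exact
  tail sums, enrichment $P[X \ge k]$ and depletion $P[X \le k]$ for
  $X \sim \mathrm{Binomial}(n, p_0)$. The background $p_0$ defaults to
  the positive fraction of the analyzed subset (for the study-shaped
  preset, $24/97 \approx 0.247$), overridable. Enrichment and depletion
  are reported separately because both directions are of interest.
- No multiple-testing correction is applied, matching the analysis the
  package reproduces; users combining many slices should correct
  downstream.

## Missing data and bookkeeping

Missing numeric cells are represented as missing and never imputed; each
analysis drops the records lacking its required fields and reports the
drop count (melting-temperature shifts, for example, are typically
available for only a minority of variants). The dataset container keeps a
provenance trail, so the record-count cascade — full set, CMC-annotated
subset, training-excluded evaluation subset — is auditable after any
sequence of filters. Duplicate variant keys are a hard load error, not a
silent merge; the 15 predictor-training variants are identified by a
boolean input column rather than a hard-coded list. The two domains of
p53 (DNA-binding and oligomerization) are distinct protein groups
throughout.

## Structural features

`rsa_from_asa()` normalizes an absolute DSSP accessibility by a
residue-type maximum. Which normalization scale the original analysis
used is not documented, so the default is the theoretical maxima of Tien
et al. (2013) — the most widely used scale — with the Sander–Rost values
available via `scale = "sander1994"`. Small RSA shifts near the 0.2
boundary can move variants between burial classes, which is a known
sensitivity of any such analysis. `wt_frequency()` excludes gap symbols
from the denominator (no published rule exists for this; the choice is
documented here). Running DSSP or building alignments is out of scope:
the primary path reads `rsa` and `f_wt` as precomputed table columns,
and the parsers are conveniences.

## The synthetic generator

`generate_dataset()` draws, per record: Tier 1–3 membership from
Bernoulli($\pi_{PCV}$, default $24/97$); experimental
$\Delta\Delta G_f$ from a class-conditional Gaussian (defaults
$N(3.0, 1.5^2)$ for drivers, $N(1.0, 1.0^2)$ otherwise, chosen so that
roughly a third of variants exceed the 2 kcal/mol cut, matching the
53/164 split of the curated set); a predictor equal to truth plus
Gaussian noise with standard deviation
$\sigma_\varepsilon = \sigma_s \sqrt{1/r^2 - 1}$, the closed form that
makes $\mathrm{corr}(X, X+\varepsilon) = r$ (default target $r = 0.5$);
and pathogenicity, RSA and conservation from class-conditional Beta
distributions parameterized by mean and concentration
($\alpha = \mu\kappa$, $\beta = (1-\mu)\kappa$). Defaults: pathogenicity
means 0.71/0.47 at $\kappa = 8$; RSA means 0.20/0.35 at $\kappa = 5$,
which place ~59% of drivers at RSA $\le 0.2$ and ~74% of benign variants
above it; conservation means 72%/45% at $\kappa = 5$.

`paper_shaped_dataset()` is a preset that forces the bookkeeping of the
curated study set exactly — 164 variants over 11 proteins (12 groups,
p53 split), 97 annotated from 9 proteins, exactly 24 Tier 1–3 and 73
"Other", exactly 53 destabilizing records, 15 training flags (82 after
exclusion), and melting temperatures on 73 records — by sampling label
assignments without replacement instead of Bernoulli draws, so
count-based tests are deterministic. Destabilization slots are drawn
with 4:1 odds in favour of Tier 1–3 records, injecting the
driver–destabilization association; $\Delta\Delta G_f$ values are then
drawn from the class Gaussians truncated at the 2 kcal/mol cut so values
respect the forced split.

Gaussian predictor noise and Beta feature marginals favour testability
over realism. The generator does **not** emulate: the heavy right tail
of force-field prediction errors (the occasional catastrophic outlier),
per-protein differences in $\Delta\Delta G_f$ scale, correlation between
RSA and conservation beyond what the shared class label induces, or
annotation noise in CMC tiers. Tests passing on synthetic data therefore
demonstrate that the machinery is correct under the assumed statistical
structure, not that any predictor performs at a given level on real
variants.

## Problem sizes and determinism

All randomness flows through explicit integer seeds: the generator
requires one, cross-validation records one, and `run_all()` with a fixed
config writes byte-identical reports. The test suite validates each
statistic against an independent oracle (enumeration for Fisher, pmf
summation for binomial tails, exhaustive pair counting for AUC, formula
recomputation for MCC, closed forms for calibration) and checks
generator parameter recovery over 200 replicate study-scale datasets —
sizes chosen to make Monte-Carlo bounds tight while keeping the default
suite fast.

## Worked example

```{r example}
cfg <- analysis_config(seed = 1)
report <- run_all(cfg)
report$stability[report$stability$slice == "pooled", ]
subset(report$enrichment, test == "binomial")
attr(report$enrichment, "class_means")
```

## Limitations

- Real curated variant tables must be supplied by the user in the
  documented format; the package ships no third-party data.
- Accuracy-style metrics are reported on the full slice at the selected
  threshold; held-out-fold metrics are not separately aggregated.
- No confidence intervals on metrics and no ROC plotting beyond the
  (FPR, TPR) pairs recoverable from `confusion_at()` sweeps.
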