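---
title: "Discrete Bayes marker discovery for antidepressant treatment response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete Bayes marker discovery for antidepressant treatment response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respmarker)
```

## The problem

Roughly half of patients with major depressive disorder do not respond to
the first antidepressant they are given, and response cannot currently be
judged until weeks into treatment. A blood-based predictor measured *before*
treatment would let clinicians switch strategies earlier. `respmarker`
implements a complete discovery-and-validation pipeline for such
predictors: screen a pre-treatment blood RNA-seq count matrix for genes
that differ between eventual responders and non-responders, confirm
candidates by absolute qPCR quantification, and build a small, discrete,
interpretable classifier over two or three markers chosen by leave-one-out
frequency voting. Interferon-stimulated genes (ISG15, RSAD2, HERC5, IFIT1,
IFI6, IFI44, IFI44L, IFIT3) are the motivating candidate panel: elevated
interferon signaling in non-responders is one of the more reproducible
signals in this literature.

Response is defined on the Hamilton scale: a participant whose SIGH-D
score improves by at least 50% of the pre-treatment value is a responder
(RES), anyone else a non-responder (NRES). `label_response()` applies this
rule with an inclusive boundary, so a 20 → 10 trajectory is a response.

## Screening model

Counts are normalized between samples by the trimmed mean of M-values.
`compute_tmm_factors()` returns *effective* size factors — library size
times the TMM composition factor, rescaled to geometric mean one — so the
downstream model needs only `log(factor)` as its offset. This convention
makes the factors directly interpretable (two otherwise identical samples
sequenced at 1x and 2x depth get factors in ratio 2) and keeps the
likelihood-ratio test invariant, up to the count likelihood's weak scale
dependence, to rescaling any single sample. The composition part is the
canonical doubly trimmed (30% on M, 5% on A), precision-weighted mean with
the upper-quartile reference rule. Because the precision weights depend on
library size, rescaling a column moves its factor by the scaling constant
only to within ~1%, not exactly; the tests assert the realistic tolerance.

Per gene, `de_test()` compares a one-mean against a two-mean
negative-binomial model by a likelihood-ratio test with a chi-square(1)
reference. The dispersion is estimated per gene by method of moments on
normalized counts, using the correct mean–variance relation for scaled
counts, `Var(y/f) = mu * mean(1/f) + phi * mu^2`. Raw per-gene moment
estimates at 15 samples per group are noisy and skew low, and an
underestimated dispersion makes the chi-square reference anti-conservative:
in null simulations the raw estimator produced a false-positive rate of
about 1.9% at nominal 1%. Each per-gene estimate is therefore floored at
the *median* of all per-gene estimates. This is a floor, not shrinkage:
genes with higher-than-typical dispersion keep their own estimate, so the
adjustment can only make the test more conservative. With the floor the
null rate sits inside the binomial 99% interval around 1% (the acceptance
suite measures it on a 2,000-gene null dataset).

Candidate genes must satisfy `p < 0.01` and a linear fold change above 1.5
in either direction (`2^|log2FC| > 1.5`, so a log2 fold change of −0.6
passes); validation targets are additionally required to have a mean raw
count of at least 50, and the ten smallest p-values are carried to qPCR.
Group means receive a 0.5 pseudo-count before the log-ratio; p-ties are
broken by larger absolute fold change, then gene id, so every ordering in
the package is deterministic.

## qPCR quantification

Each assay is calibrated on a six-point two-fold dilution series (10 down
to 0.3125 fM) by ordinary least squares of Cq on log10 concentration; a
perfect-efficiency assay has slope −3.32 cycles per decade, and a fitted
non-negative slope is flagged rather than used. Unknowns are quantified by
inverting the line, duplicates are quantified individually and averaged on
the concentration scale (the scale of interest; a Cq-mean option exists),
and expression is expressed as the ratio to the B2M internal control,
anchored so the responder mean is exactly 1 per gene. Group differences
use the classical pooled-variance Student's t-test with Holm step-down
correction across the tested gene family.

## The discrete Bayes decision rule

Continuous marker values are discretized into a small number of exclusive
divisions per marker; cut points are equal-frequency quantiles of the
pooled training values, which makes every downstream decision invariant to
strictly monotone transforms of the raw scale. A value exactly at a cut
point falls in the lower division. Two divisions per marker is the
default; the examples worked in the sources use two and three.

For a sample with observed divisions $d_1, \dots, d_m$ the per-class,
per-marker conditional is, with $n_j(d)_i$ the training count of class
$\omega_i$ in division $d$ of marker $j$ and smoothing constant
$\varepsilon$:

$$P(x_j(d_j) \mid \omega_i) = \frac{n_j(d_j)_i + \varepsilon}
{\sum_{k=1}^{m} \left( n_k(d_k)_i + \varepsilon \right)}$$

the class-conditional is the product over markers, and the posterior the
normalized product with equal priors. Note the denominator: it sums the
counts of the *observed divisions across all markers*. This is the rule
exactly as printed in the methodological sources, generalized from two
markers to $m$, and it is the package default
(`conditional = "cross_marker"`). It has two consequences worth knowing:

* with a single marker every conditional is $(n+\varepsilon)/(n+\varepsilon) = 1$,
  so the posterior is uniform and the rule cannot discriminate at all;
* with several markers the likelihood $\prod_j n_j / (\sum_k n_k)^m$ is
  maximized by *balanced* counts regardless of their magnitude, so it
  measures agreement between markers more than evidence mass.

Because of these degeneracies the standard naive-Bayes normalization
(denominator = the marker's own division total,
`conditional = "per_marker"`) is available as a switch and is what the
package's own selection simulations use. The smoothing default
$\varepsilon = 0.5$ keeps posteriors defined on divisions unseen in
training; $\varepsilon = 0$ reproduces the unsmoothed counting rule, with
an informative error when both class likelihoods vanish. Exact posterior
ties are assigned to the responder class and flagged, so every
classification is deterministic.

## Marker-combination selection

`loo_select()` reproduces the leave-one-out voting scheme: each of the
$n$ training samples is left out once; on the remaining $n-1$ sub-training
samples every $\binom{8}{2} = 28$ pair (or $\binom{8}{3} = 56$ triple) is
scored by *re-substitution* — the classifier is fit on the sub-training
samples and reclassifies those same samples — and one combination is
selected per fold, either by maximal sensitivity subject to a specificity
of at least 50% or by maximal F1. The most frequent per-fold choice wins.
Discretization and counting are redone from scratch inside every fold, and
the left-out sample is never touched; the end-to-end pipeline additionally
keeps test-set labels in a sealed container whose access log is part of
the run report, so the firewall is auditable rather than asserted.

Degenerate cases the sources leave open are resolved deterministically:
if no candidate meets the specificity floor the fold falls back to maximal
specificity and is flagged; criterion ties break by higher accuracy, then
lexicographically; frequency ties break by better mean re-substitution F1
across the folds that voted for each candidate, then lexicographically.

### What re-substitution selection can and cannot do

Re-substitution estimates are optimistically biased, and at 30 training
samples the bias is marker-specific: an uninformative marker "explains"
part of the training labels by chance, so a pair of one informative and
one noise marker frequently matches or beats the truly informative pair
in-sample. The package's recovery simulations (two markers planted at
log2 fold change 1.2 in negative-binomial noise, 15 + 15 samples, 8
candidates) recover the planted pair in roughly half of seeded replicates
under the most favorable configuration (three divisions, per-marker
conditionals, F1 criterion) — far above the 1/28 chance level, but far
from certain. The leave-one-out vote cannot rescue this, because folds
share all but one sample and their votes are strongly correlated. This is
a property of the selection procedure itself, not of its implementation,
and it is the main caveat to keep in mind when interpreting a selected
combination from a cohort of this size.

## Performance reporting

`confusion()` tallies with responders positive; `compute_metrics()`
reports accuracy, sensitivity, specificity, precision and F1. Ratios with
zero denominators are reported as 0 and flagged (never `NaN`), which keeps
the selection criteria total. Display rounding is half-up to two decimals,
matching conventional report tables; raw values are retained.

## The synthetic-data generator

Real participant-level expression data for this design are not public, so
the generator produces cohorts with the same statistical skeleton, and
every claim the test suite makes about the pipeline is a claim about data
of this structure:

* counts are negative-binomial with gene-wise means log-uniform on
  `baseline_mean_range` (default 5–500) and one shared dispersion
  (default 0.1, a typical between-subject value for human blood);
* per-sample library-size factors are log-normal with mean 1 and CV 0.2,
  giving TMM genuine composition/depth variation to remove;
* the planted signature defaults to the 19-gene interferon-dominated set
  with log2 fold changes between −0.74 and 1.96 applied multiplicatively
  in the non-responder group; all other genes are identically distributed
  in both groups;
* qPCR plates carry a six-point dilution series per gene, duplicate
  measurements per sample, and Gaussian Cq noise (default sd 0.15 cycles,
  instrument-level); B2M carries no group effect;
* severity scores are constructed so the 50% rule reproduces the simulated
  labels exactly (floor/ceiling keep responders at or above, and
  non-responders strictly below, their drawn improvement).

What the generator does **not** emulate: batch effects, age/sex
confounding, gene–gene correlation beyond the shared library factor,
amplification-efficiency drift, or distribution parameters estimated from
any real cohort — group sizes and effect sizes are structural, the rest
are stand-ins. A green suite therefore demonstrates correctness of the
procedures, calibration under the stated noise model, and recovery power
under that model; it does not certify performance on clinical data.

For marker-level simulations (recovery tests, the worked pipeline runs)
the baseline mean range is raised to 50–500, mirroring the pipeline's own
validation-target rule that candidate markers must average at least 50
counts.

## Numerical and design choices

* Effective TMM factors (library size included, geometric mean 1) with
  `log(factor)` offsets, as motivated above.
* Dispersion floor at the across-gene median of moment estimates; floor
  1e-8 for degenerate cases; genes with all-zero counts get p = 1 and
  log2FC = 0 so result tables are total.
* Pseudo-count 0.5 on group means before log-ratios; it only matters for
  near-zero genes.
* Quantile discretization with type-7 quantiles; values at cuts go low;
  a marker with fewer distinct values than divisions is an error, not a
  silent merge.
* All tie-breaks (classification, per-fold selection, frequency voting,
  result ordering) are deterministic and documented, so identical inputs
  and seeds give byte-identical outputs.
* Problem sizes in the tests and acceptance script — 1,200–3,000 genes,
  15 + 15 and 22 + 12 cohorts, 50-replicate recovery runs — were chosen to
  estimate each property stably while keeping a full run of the suite in
  the low minutes on a single core.

## Known limitations

* The cross-marker normalization is implemented exactly as printed, and
  its degeneracies (uniform single-marker posteriors, balance-seeking
  likelihoods) are inherited by design; use `per_marker` when you want a
  standard naive Bayes.
* Scale invariance of the screen is approximate (precision-weighted TMM
  and a non-scale-equivariant count likelihood), at the ~1% level on
  factors.
* Re-substitution-based selection has limited power at n = 30, as
  quantified above.
* The pipeline is two-group, single-factor; no covariates, no multi-class
  designs, no empirical-Bayes dispersion sharing.
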