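---
title: "Methods: dual-contrast hormone sensitivity and GO enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-contrast hormone sensitivity and GO enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `sensigo`, the choices
made where the design was genuinely open, and what the synthetic-data tests
do and do not establish about behaviour on real arrays.

## Study design and model

The design is two tissues (an androgen-responsive muscle, the levator ani,
and prostate) by four conditions — sham-operated, castrated (`cx`),
castrated + testosterone (`cx_T`), castrated + follistatin (`cx_F`) — with
at least four replicates per group. All analyses are stratified by tissue;
conditions are never pooled across tissues because the scientific question
is precisely how the two tissues differ.

Per gene and tissue the expression model is a cell-means model on the log2
scale: sham mean `b`, castration shifts it by `d_cx`, and the two treatments
act on the castrated state (`cx_T` adds `d_T`, `cx_F` adds `d_F`).
"Androgen-sensitive" operationalizes a gene whose castration response is
reversed by testosterone; "follistatin-sensitive" one whose castration
response is reversed by follistatin. The decision rule is purely
q-value-based (see below), so the model's role is to motivate the three
contrasts, not to constrain signs.

## RMA preprocessing

`rma()` composes, in this order: background correction, quantile
normalization, log2, median-polish summarization. The order matters and is
guarded by a test.

* **Background correction** assumes observed intensity = exponential signal
  + normal optical background. Parameters are estimated per array: the
  background mean is the kernel-density mode of the intensities, the
  background sd comes from a half-normal fit to the intensities below the
  mode (scaled by sqrt(2) because only the lower half is seen), and the
  signal rate is the reciprocal mean exceedance above the mode. The
  corrected value is the posterior mean `E[signal | observed]`, which is
  strictly positive by construction. When the estimated background sd is
  numerically zero the correction degenerates to mode subtraction (floored
  at a small positive value).
* **Quantile normalization** maps each column onto the mean of the sorted
  columns. Ties within a column receive the mean of the reference values
  over the tied ranks — deterministic and invariant to row permutation. On
  tie-free data the procedure is exactly idempotent and equalizes the
  column distributions to machine precision; with ties the tied entries are
  averaged, which slightly perturbs the shared distribution (this is the
  standard trade-off, and real intensity data are effectively tie-free).
* **Median polish** alternates probe-median and sample-median sweeps
  (midpoint convention for even counts) until the sum of absolute residuals
  changes by less than 1% relative, or 10 full sweep pairs — the
  conventional RMA stopping rule. The probeset value is overall + sample
  effect; probe effects are nuisance. Single-probe probesets pass through
  unchanged. The implementation delegates the sweeps to
  `stats::medpolish()`; tests verify it against an independently written
  naive sweep loop to 1e-8 and exactly on additive tables.

## Moderated differential expression

Each comparison is a two-group fit: `b_g` = difference of group means,
`s_g^2` = pooled within-group variance with `d_g = n1 + n2 - 2` df,
`u_g = sqrt(1/n1 + 1/n2)`. The empirical-Bayes prior
`sigma_g^2 ~ s_0^2 d_0 / chisq(d_0)` is fitted by moment matching on
`log s_g^2`: the bias-corrected values
`e_g = log s_g^2 - digamma(d_g/2) + log(d_g/2)` have mean `log s_0^2 +
log(d_0/2) - digamma(d_0/2)` and excess variance `trigamma(d_0/2)`, so `d_0`
is recovered by a Newton inversion of the trigamma function. Edge cases:

* genes with `d_g = 0` or `s_g^2 = 0` are excluded from estimation (no
  variance information; shrinkage still covers them at test time);
* exactly equal variances give `d_0 = Inf` with `s_0^2` equal to the common
  value (a point prior);
* when the excess variance is non-positive, `d_0 = Inf` and
  `s_0^2 = exp(mean(e))`;
* fully noise-free data (all `s_g^2 = 0`, possible only in simulation)
  yield a point prior at zero and the degenerate limit p = 0 for any
  nonzero fold change, p = 1 otherwise.

The moderated statistic divides `b_g` by `u_g` times the square root of the
shrunken variance and is referred to a t-distribution with `d_0 + d_g` df
(normal when `d_0 = Inf`). At `d_0 = 0` this reduces exactly to the pooled
two-sample t-test, which is tested numerically. The test suite also
cross-checks the whole chain against `limma` (`lmFit`/`eBayes`) on random
data.

**q-values.** Multiplicity correction is Benjamini–Hochberg step-up
(`stats::p.adjust`), validated against a brute-force suffix-minimum oracle.
The adjusted p-values are called q-values throughout. Storey-type q-values
are a different estimand and are deliberately not substituted: BH is the
stated adjustment, and the classification threshold (0.2) was defined
against it.

## Classification

`classify_sensitivity()` implements the rule verbatim with a strict
inequality: androgen-sensitive iff `q < 0.2` in *both* cx-vs-sham and
T-vs-cx; follistatin-sensitive iff `q < 0.2` in both cx-vs-sham and
F-vs-cx. The shared castration contrast means both calls fail together for
genes that do not respond to castration. No fold-change sign consistency is
required by default, because the rule is defined purely on q-values; a
`require_direction` flag adds the biologically natural requirement that the
restoration contrast oppose the castration contrast, for users who want the
stricter signature. Lowering the threshold can only shrink the called sets
(tested as a monotonicity property).

## GO enrichment

The engine is self-contained: an OBO parser (term stanzas; obsolete terms
and non-biological_process namespaces dropped together with their edges; a
single root and acyclicity are enforced), a GAF 2.x parser (17 columns, NOT
qualifiers excluded, duplicate pairs collapsed), and is_a-closure
propagation so that each gene is annotated to every ancestor of its direct
terms — making the root annotated to all annotated genes. Only is_a edges
are traversed; part_of/regulates relations are out of scope, matching the
plain parent–child subsumption the analysis is built on.

Counts for the frequency filter (> 5 and < 300 genes per term, strict, on
propagated counts) are taken over the *measured annotated universe*, i.e.
after restriction to genes present in the analysis — the filter is meant to
remove terms too generic or too rare to be informative in this dataset, so
dataset-relative counts are the right basis. The hypergeometric upper tail
is accumulated in log space (log-binomial coefficients with max-shift
exponentiation) to remain stable for large universes; it is validated
against exhaustive enumeration for all universes up to n = 12 and against
`phyper` at realistic sizes. Adjustment across retained terms is BH by
default (consistent with the expression analysis) with Bonferroni as an
option, and the reporting threshold is adjusted p < e^-3 — interpreted as
the mathematical constant e to the power -3 (~0.0498) and configurable.
Probesets mapping to one gene can be collapsed to the best-q representative
(`collapse_probesets()`) before selection, so counting is gene-level.

No parent–child decorrelation (elim/weight-style) is attempted: the method
is the plain hypergeometric on propagated counts, so parent terms of a
truly enriched term will often co-appear; readers of the result tables
should interpret related terms jointly.

## The synthetic-data generator

The generator emulates exactly the statistical structure the analysis
assumes, with defaults fixed at the study conditions:

* 10,000 genes, 2 tissues, 4 conditions x 4 replicates;
* per-tissue sensitive-gene fractions mirroring the observed Venn structure
  (muscle: 8.52% androgen-sensitive with ~46% follistatin overlap plus
  3.87% follistatin-only; prostate: 5.93% androgen-sensitive, near-zero
  follistatin response) so that the tissue-asymmetry headline is a
  recoverable planted truth;
* effect sizes `|delta| ~ Uniform[0.5, 2]` log2 with random sign, and
  restoration effects opposing the castration effect;
* residual sds from a scaled inverse-chi-square prior with `d_0 = 4`,
  `s_0^2 = 0.04` (typical residual sd ~0.2 log2 units, in line with
  RMA-summarized Affymetrix data and with commonly reported
  empirical-Bayes prior fits);
* 11 probes per probeset with N(0, 0.4^2) log2 affinities, and intensities
  `2^(expr + affinity) + N(100, 20^2)` background — i.e. the convolution
  model the background correction fits;
* one base seed drives every sub-generator through fixed offsets
  (expression +0, probes +1, ontology +2, annotations +3), so runs are
  bit-reproducible and stages can be regenerated independently.

The synthetic ontology is a random rooted DAG (each non-root term has 1–2
parents among earlier terms) with sparse direct annotations (90% of genes
annotated, 1–3 direct terms each).

What the generator does **not** emulate: spatial array artifacts, batch and
dye effects, probe-sequence-specific (GC) affinity structure,
cross-hybridization, correlated gene modules, and annotation bias toward
well-studied genes. Passing the recovery tests therefore shows that the
pipeline is correct under its own model assumptions and calibrated at
realistic noise levels — not that it is robust to every failure mode of
real arrays.

## Problem sizes and numerical tolerances

The test suite exercises the generator-driven checks at the study scale
where the property demands it (10,000 genes for null-FDR and recovery runs,
1e5 genes for hyperparameter recovery, 50 null replicates) and at reduced
scale elsewhere; the analysis scripts run the full 10,000-gene, 110,000-probe
simulation. Oracle agreements are required to 1e-12 (hypergeometric vs
enumeration), exactly (BH vs suffix minima), and 1e-8 (median polish vs
naive sweeps); distributional equalities after quantile normalization hold
to 1e-12. Recovery-style checks use bounds (>= 80% sensitivity, <= 30%
empirical FDR, asymmetry ratios) rather than point equalities, since they
are sampling-variable.

## Known limitations

* The background-parameter estimator needs enough probes per array for a
  stable density mode; very small probe sets (hundreds) estimate it
  coarsely.
* Two-group fits only; covariates beyond condition are not modelled.
* The enrichment universe is the annotated measured gene set; results are
  not comparable across runs with different universes.
* OBO parsing covers the term-stanza subset sufficient for GO-style
  biological_process hierarchies, not the full OBO 1.4 grammar.
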