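---
title: "Ranking copy-number driver genes by trans-expression mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking copy-number driver genes by trans-expression mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivermed)
```

## The problem and the model

A focal somatic copy-number alteration (SCNA) changes the dosage of every
gene in its peak at once, so expression of those *cis* genes rises
(amplification) or falls (deletion) together, and differential expression
alone cannot tell the driver apart from its passengers. `drivermed` uses
the alteration's *trans* footprint — the genes outside the peak whose
expression also tracks the alteration — as the arbiter: a driver should
*mediate* the alteration's effect on its trans targets, a passenger should
not.

For each triplet (alteration status X, cis gene expression C, trans gene
expression T) the package fits three ordinary least-squares models:
T ~ X gives the total effect τ; T ~ X + C gives the direct effect τ′ and
the mediator path b̂; C ~ X gives the path â. The mediated effect is
Δτ = τ − τ′, which for nested OLS equals â·b̂ exactly — the package's test
suite asserts this identity to 10⁻⁹, because it exercises all three
regressions jointly. Significance uses the first-order Sobel standard
error, SE = √(b̂²SE(â)² + â²SE(b̂)²), with t = Δτ/SE referred to the
standard normal. The "pooled standard error" of the classical Sobel test
is not uniquely defined in the literature; we use the first-order delta
method form, which is the common choice and matches the normal reference
distribution.

Each significant trans gene is then assigned to at most one cis gene — the
one with the smallest mediation FDR, with deterministic tie-breaks (larger
|Δτ|, then lexicographic gene name) so reruns are bit-identical. The
assignment is weighted by the mediated fraction w = Δτ/τ, clipped to
[0, 1]. We use the ratio Δτ/τ rather than Δτ/|τ| deliberately: Δτ and τ
share sign under genuine mediation, so the signed ratio makes full
mediation score 1 for deletions (negative τ) as well as amplifications,
while Δτ/|τ| would clip every deletion-mediated weight to 0. A cis gene's
score is the Weighted Fraction of Trans Mediation,
WFTM_i = Σ_j w_ij I_ij / m, with m the total number of significant trans
genes (assigned or not). The largest WFTM wins Rank-1 — the candidate
driver.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| amplitude threshold | 0.1 | strict binarization cutoff: amplified if t > 0.1, deleted if t < −0.1; the boundary value is *not* altered |
| cis DE filter | FC > 1.2, FDR < 0.25 | one-sided in the expected direction (up for amplifications, down for deletions) |
| trans DE filter | FC > 1.5, FDR < 0.01 | two-sided; indirect effects can repress or activate |
| `de.moderation` | TRUE | limma empirical-Bayes moderated t over the (alteration, role) gene batch; FALSE gives the closed-form pooled t |
| `mediation.assign_fdr_max` | 0.25 | FDR below which a trans gene counts as mediated at all; mirrors the lenient cis filter and is configurable because no canonical value exists |
| `mediation.trans_restrict` | none | optional gene set restricting which trans genes enter WFTM (numerator and denominator) |
| enrichment report / subtype FDR | 0.25 / 0.05 | reporting filters for gene-set and subtype Fisher tests |

Fold change is defined as 2^|Δmean of log2 expression|, since inputs are
log2 and the filters above are on the natural scale. FDR families are per
(alteration, role) for differential expression and per alteration for
mediation triplets, matching the per-alteration reporting the method is
built around. The DE step routes through limma when moderation is on; with
moderation off every statistic has a closed form the tests verify against
`t.test(var.equal = TRUE)`.

## The forward simulator

Two generative systems produce labeled instances for evaluating the Sobel
test. True positives follow the causal chain Y = α₁ + β₁X + N(0, σ₁²),
Z = α₂ + β₂Y + N(0, σ₂²) (total mediation — no direct X→Z path). True
negatives replace the chain with a common cause: Y and Z are each
generated from X directly, so Y ⟂ Z | X. Both default to β₁ = β₂ = 0.7
with balanced binary X. Sensitivity and specificity are fractions called
at p < 0.05; AUC is the Mann–Whitney probability (ties credited ½) that a
positive's p-value is smaller than a negative's — exact and free of ROC
interpolation. Noise is converted to a correlation axis with the exact
closed form r = β₁·sd(X)/√(β₁²var(X) + σ₁²) for balanced binary X
(var(X) = ¼) rather than a smoother fit to empirical correlations: the
closed form is its expectation and is deterministic.

Under the common-cause null with a strong X→Y path, the Sobel statistic
t ≈ sign(â)·t_b̂ is asymptotically standard normal, so specificity sits
essentially *at* 1 − p_cut rather than above it; conservativeness (and the
test's well-known loss of power) appears when both paths are weak.
Sensitivity drops at small n and large σ; the monotonicity of power in
both axes is tested with common random numbers — the noise draws are
shared across a σ ladder because `rnorm(n, 0, s)` scales one underlying
standard-normal stream.

## The synthetic-study generator

`generate_synthetic_study()` emulates the full input bundle: a log2
expression matrix, binarized alterations with cis membership, gene sets,
a driver reference, and the planted truth. Per alteration it plants one
(or, via `driver_split`, several near-tied) driver cis genes following
C = ±β_cis·X + ε, trans genes 80% of which follow T = β_trans·C + ε
through the driver, the remainder responding to X directly, plus decoy cis
genes that track X but are conditionally independent of every trans gene,
and background noise genes. Defaults — 300 samples, status→cis effect 1.0
log2 units, cis→trans effect 0.8, noise sd 0.5, altered fraction 0.5 —
were chosen once as a realistic strong-focal-SCNA regime: the implied
trans fold change of 2^0.8 ≈ 1.74 clears the 1.5 filter the way a real
alteration's responsive trans genes must to enter mediation at all.

What the generator does *not* emulate: correlated noise between genes,
batch effects, overlapping peaks sharing cis genes, partial mediation, and
confounding of cis and trans by unmodeled covariates. Passing the planted
recovery tests therefore shows the machinery is correct and well-powered
under the stated model, not that real tumors satisfy that model.

## Bootstrap reproducibility

`bootstrap_rank1()` resamples samples with replacement (original size,
default B = 100), reruns differential expression and mediation, and scores
each *original* Rank-1 gene by its inclusion fraction across usable
resamples; resamples in which an alteration's status becomes constant are
skipped and its denominator reduced. Genes that become Rank-1 only in
resamples are listed separately, never scored — the score is defined for
the original predictions. Each alteration also gets the Shannon entropy
(base 2; the base only rescales) of its WFTM profile: a single dominant
mediator gives entropy near 0 and high inclusion, near-tied mediators give
high entropy and unstable Rank-1 calls. Inclusion is regressed on WFTM and
on entropy with a two-sided slope t-test at 0.05.

## Numerical choices and degenerate inputs

* Zero pooled variance in a two-group test: p = 1 when the mean difference
  is 0, else p → 0, with a degeneracy flag.
* A cis gene collinear with status (zero residual variance given X) makes
  the two-regressor normal equations singular; the triplet is excluded
  with a flag rather than inverted unstably.
* τ = 0 leaves the weight undefined; such triplets are excluded (in
  practice trans genes enter only when significantly associated with X).
* Alterations whose binarized status is constant are retained in the data
  structure but flagged unusable and excluded from every test.
* Samples altered opposite to a peak's direction (e.g. deleted at an
  amplification peak) fall into the 0 group of the strict binarization.
* All rankings break ties deterministically, so a fixed configuration and
  seed reproduce every output file byte for byte.

## Problem sizes in the test suite

The packaged tests run the simulator at 1000+1000 replicates for the
operating-characteristic checks, 400 replicates per cell for the power
monotonicity ladders, 20 seeded studies (two alterations each) for planted
recovery, and B = 25/15 for the bootstrap checks — sizes at which every
assertion is stable across seeds while the whole suite stays fast on one
CPU.

## Limitations

The mediation model is observational: a decoy whose expression influences
trans genes through a path other than dosage would be indistinguishable
from a driver. Only single-mediator assignment is supported ("at most one
cis gene per trans gene"), matching the method's simplifying assumption;
multi-mediator and sensitivity analyses are out of scope. Cis membership
is consumed as given — no genomic-coordinate arithmetic is performed — and
trans genes on the same chromosome arm as the alteration are not excluded.
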