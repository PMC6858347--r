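# drivermed

Somatic copy-number alterations (SCNAs) recurrently amplify or delete
regions containing tens of genes, but usually only one or a few of those
genes drive the tumor phenotype. `drivermed` integrates a binary alteration
profile (e.g. GISTIC2-style focal SCNA calls) with matched log2
gene-expression data to prioritize the *cis* genes of each alteration — the
genes inside the altered region — by how much of the alteration's
downstream (*trans*) transcriptional footprint each one statistically
mediates. It is aimed at cancer genomicists who have per-sample alteration
calls, an expression matrix, and a list of wide-peak (cis) genes per
alteration, and want a ranked list of candidate driver genes per
alteration plus diagnostics for how trustworthy each call is.

## The model

For each alteration with binary status X, the package:

1. Tests every gene for differential expression against X
   (limma-moderated or closed-form pooled t): cis genes one-sided in the
   expected direction (up for amplifications, down for deletions) with
   FDR < 0.25 and fold change > 1.2; trans genes two-sided with FDR < 0.01
   and fold change > 1.5. FDR is Benjamini–Hochberg within each
   (alteration, role) family.
2. For every significant (cis, trans) pair fits the mediation triple of
   OLS regressions

   - trans ~ X              → total effect τ
   - trans ~ X + cis        → direct effect τ′ and mediator path b̂
   - cis ~ X                → path â

   and applies the Sobel test: Δτ = τ − τ′ (= â·b̂), SE =
   √(b̂²SE(â)² + â²SE(b̂)²), t = Δτ/SE referred to the standard normal.
3. Assigns each trans gene its single best mediator (smallest mediation
   FDR), weights it by the mediated fraction w = Δτ/τ clipped to [0, 1],
   and scores each cis gene by the Weighted Fraction of Trans Mediation,

   WFTM_i = Σ_j w_ij I_ij / m,

   with m the number of significant trans genes. The cis gene with the
   largest WFTM is the **Rank-1** candidate driver of the alteration.

Around this core the package provides hypergeometric gene-set enrichment
of the alteration signatures, Fisher-test validation of Rank-1 calls
against driver-gene references and dependency screens, a forward simulator
measuring the Sobel test's AUC/sensitivity/specificity over sample-size ×
noise grids, and bootstrap resampling that scores each Rank-1 call by its
inclusion fraction and relates it to the WFTM entropy of the alteration.

## Worked example

The built-in generator plants known mediation structure (per alteration:
one driver cis gene mediating 80% of 30 trans genes, four decoy cis genes
that track the alteration but mediate nothing, 300 samples):

```r
library(drivermed)
study <- generate_synthetic_study(seed = 1)
h     <- match_samples(study$expr, study$alts)
res   <- run_pipeline(h$expr, h$alts, "demo_out", gene_sets = study$gene_sets)
res$summary
#> # A tibble: 2 × 6
#>   alt_id n_cis_significant n_trans_significant     m rank1_gene  rank1_wftm
#> 1 alt01                  5                  30    30 alt01_cis01      0.758
#> 2 alt02                  5                  30    30 alt02_cis01      0.774
```

All five cis genes of `alt01` pass the cis differential-expression filter
(they all track the alteration), and all 30 trans genes are significant,
so m = 30. The mediation step separates driver from decoys:

```r
res$fits[["alt01"]]$ranking
#>   alt_id cis_gene    n_trans_mediated    wftm  rank is_rank1
#> 1 alt01  alt01_cis01               24 0.758       1 TRUE
#> 2 alt01  alt01_cis05                1 0.00627     2 FALSE
#> 3 alt01  alt01_cis04                1 0           3 FALSE
#> ...
```

The planted driver `alt01_cis01` is called Rank-1: it is assigned 24 of
the 30 trans genes with near-total mediation weights (WFTM 0.758 ≈ the
planted 80% mediated fraction), while the decoys mediate essentially
nothing. `tidy()`/`glance()` expose the triplet table and one-row
summaries; `autoplot()` draws the WFTM ranking, DE volcanoes, simulation
heatmaps and bootstrap scatter plots. A thin CLI wrapping these functions
is installed at `inst/scripts/drivermed` (subcommands `run`, `bootstrap`,
`simulate-grid`, `make-study`, `validate-drivers`).

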