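# ibmtlr

Differential-expression and gene-set inference for small paired
expression studies, built around two ideas from the microarray
literature:

1. **Intensity-based moderated t (IBMT).** Per-gene residual variances
   from a handful of subject pairs are unstable. They are shrunk toward
   an empirical-Bayes prior whose scale depends smoothly on mean log2
   intensity: with per-gene contrast `b_g`, residual variance `s_g^2` on
   `d_g` degrees of freedom and a prior `sigma_g^2 ~ d0 s0^2(a_g) /
   chisq(d0)`, the moderated statistic is

   ```
   t_g = b_g / (u_g * s_tilde_g),   s_tilde_g^2 = (d0 s0g^2 + d_g s_g^2) / (d0 + d_g)
   ```

   referred to a t distribution on `d0 + d_g` df. The prior trend
   `s0^2(a)` is a local regression of bias-corrected log variances on
   intensity; `d0` solves a trigamma moment equation by bisection.
   `d0 = 0` recovers the ordinary t, `d0 = Inf` full shrinkage.

2. **Directional LRpath enrichment.** Instead of thresholding genes,
   set membership is modelled over the whole measured universe as
   `logit P(g in S) = b0 + b1 * x_g` with the signed score
   `x_g = sign(fold) * (-ln p_g)`; a two-sided Wald test on `b1` gives
   the set p-value and `sign(b1)` the coordinated direction.
   Benjamini–Hochberg FDR (step-up, implemented and cross-checked
   against a brute-force oracle) controls both the gene and the set
   family; enriched terms are collapsed over a GO-style parent/child
   DAG (single qualifying child displaces its parent; two or more
   siblings are displaced by it).

The package also provides quantile normalization, relative qPCR
quantification by `2^-ddCt` with reference-gene normalization and
Spearman cross-platform concordance, a synthetic-study generator that
emulates a paired bilateral exercise design (sex-by-time groups,
intensity-dependent variance, planted set-level effects, toy term DAG,
duplicate-well Ct panels) with full ground truth, and a deterministic
five-comparison pipeline driver with a machine-readable manifest.

It is aimed at analysts working with pre-summarized log2 expression
matrices from small paired designs, and at anyone who wants a tested,
reproducible reference implementation of the IBMT/LRpath chain.

## Worked example

```r
library(ibmtlr)

cfg  <- simulation_config(n_probes = 5000, n_sets = 40,
                          set_size_range = c(15L, 60L),
                          de_fraction = 0.1, delta = 1, seed = 2026)
sim  <- generate_study(cfg)              # paired study + per-probe truth
anno <- generate_gene_sets_and_dag(cfg)  # GMT-style sets + term DAG

st <- fit_gene_stats(sim$study, default_comparisons()[[5]])  # female, 24 h
hy <- estimate_eb_hyperparameters(st)
hy
#> eb_hyper: d0 = 3.925976  span = 0.75  median s0^2 = 0.05152

mo <- moderated_test(st, hy)
sum(mo$q < 0.05)
#> [1] 120

en <- run_lrpath(build_significance_scores(mo), anno$sets)
head(en[order(en$p), c("set_id","n","beta1","direction","p","fdr","enriched")], 3)
#>    set_id  n   beta1 direction        p      fdr enriched
#> 7    T007 57 -0.5685      down 1.07e-54 4.26e-53     TRUE
#> 3    T003 26  0.4757        up 4.25e-32 8.50e-31     TRUE
#> 30   T030 34 -0.1818      down 4.52e-04 6.02e-03     TRUE

ddct_fold(20, 18, 22, 19)$fold   # qPCR: ddCt = -1
#> [1] 2
```

The estimated prior (`d0` near 4, median prior variance near 0.05)
matches the generator's configuration; 120 of 5,000 probes pass q <
0.05; the top enriched sets are planted "loaded" sets recovered with
their planted directions; and the worked Ct quartet gives the exact
two-fold change. `run_pipeline(pipeline_config(...))` chains all stages
over the default five comparisons (baseline male-vs-female plus
exercised-vs-control per sex and time point) and writes per-comparison
TSVs, the signed enrichment matrix and a manifest.

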