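---
title: "Intensity-moderated t-statistics and logistic-regression enrichment: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity-moderated t-statistics and logistic-regression enrichment: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibmtlr)
```

## The problem

Small paired expression studies — here, a bilateral resistance-exercise
design in which each subject contributes one exercised-arm and one
control-arm muscle sample — give per-gene variance estimates on only a
handful of degrees of freedom. The two classical failure modes are well
known: genes with accidentally tiny sample variance dominate the top of
an ordinary t-ranking, and hard significance cutoffs upstream of gene-set
enrichment make the biological conclusions depend on an arbitrary
threshold. `ibmtlr` implements a chain that addresses both: an
empirical-Bayes moderated t whose variance prior depends on mean log2
intensity, a cutoff-free gene-set enrichment by logistic regression on
signed log significance scores, redundancy collapsing of enriched
ontology terms, and relative qPCR quantification for cross-platform
validation. A synthetic-study generator with known ground truth drives
all tests.

## Per-gene contrasts

For a paired comparison, per-subject differences $D_{gs} = x^{ex}_{gs} -
x^{ctl}_{gs}$ remove all subject-level effects; the per-gene summary is
$b_g = \bar D_g$, $s_g^2 = \mathrm{var}(D_{g\cdot})$, $d_g = n - 1$ and
the unscaled standard error $u_g = 1/\sqrt{n}$. The unpaired
(male-vs-female baseline) mode uses the pooled two-sample variance with
$d_g = n_1 + n_2 - 2$, $u_g = \sqrt{1/n_1 + 1/n_2}$. The mean log2
intensity $a_g$ over the comparison's samples is carried along as the
covariate of the variance prior. The ordinary t is $b_g/(u_g s_g)$.

## The intensity-based moderated t

The hierarchical model is the standard scaled-inverse-chi-square
variance prior, with the single extension that the prior scale is a
smooth function of intensity:

$$ s_g^2 \mid \sigma_g^2 \sim \sigma_g^2\,\chi^2_{d_g}/d_g,
   \qquad \sigma_g^2 \sim d_0\, s_0^2(a_g) / \chi^2_{d_0}. $$

Hyperparameters are estimated by method of moments on the
bias-corrected log variance $e_g = \log s_g^2 - \psi(d_g/2) +
\log(d_g/2)$, which satisfies $E[e_g] = \log s_0^2(a_g) + \log(d_0/2) -
\psi(d_0/2)$ and $\mathrm{var}(e_g) = \psi'(d_g/2) + \psi'(d_0/2)$. A
local linear regression of $e_g$ on $a_g$ (`stats::lowess`, `iter = 0`,
span 0.75 by default) gives the trend $\hat e(a)$; the prior degrees of
freedom solve

$$ \psi'(d_0/2) = \frac{m}{m-1}\,\overline{r_g^2} -
   \overline{\psi'(d_g/2)}, \qquad r_g = e_g - \hat e(a_g), $$

by bisection on $d_0 \in [0.01, 10^6]$ (tolerance $10^{-8}$; $\psi'$ is
strictly decreasing so the root is unique). A non-positive right-hand
side — residual spread fully explained by chi-square sampling noise —
gives $d_0 = \infty$. The per-gene prior variance is $s_{0g}^2 =
\exp\{\hat e(a_g) + \psi(d_0/2) - \log(d_0/2)\}$ ($\exp \hat e(a_g)$ at
$d_0=\infty$). The robustness iterations of the smoother are switched
off deliberately: $e_g$ has a long-tailed log-chi-square distribution
and a robust fit would trim exactly the tail the moment identities
account for, biasing the trend.

The posterior variance is the df-weighted convex combination
$\tilde s_g^2 = (d_0 s_{0g}^2 + d_g s_g^2)/(d_0 + d_g)$ and
$\tilde t_g = b_g/(u_g \tilde s_g)$ is referred to $t_{d_0 + d_g}$
(standard normal at $d_0 = \infty$). Setting $d_0 = 0$ recovers the
ordinary t exactly, which the tests use as a reduction check. P-values
are two-sided throughout and floored at $10^{-300}$; direction is
carried separately as $\mathrm{sign}(b_g)$. Probes with $s_g^2 = 0$ are
excluded from hyperparameter fitting but still moderated through
$s_{0g}^2$. Multiple testing uses the Benjamini–Hochberg step-up
$q_{(i)} = \min_{j \ge i} p_{(j)} m / j$ with $m$ = the number of tested
probes in the comparison (not the full array), recorded in the run
manifest.

## Directional enrichment by logistic regression

Each gene's enrichment covariate is the signed log significance score
$x_g = \mathrm{sign}(b_g)\,(-\ln p_g)$: strongly up-regulated genes get
large positive scores, strongly down-regulated genes large negative
ones, and $p = 1$ contributes zero either way. For every gene set $S$
the model

$$ \mathrm{logit}\, P(g \in S) = \beta_0 + \beta_1 x_g $$

is fitted over the whole measured universe, so no differential-expression
cutoff is ever applied; $\beta_1$ is tested by a two-sided Wald test and
$\mathrm{sign}(\beta_1)$ reports whether the set is coordinately up- or
down-regulated. The natural log is used for the score (the base only
rescales $\beta_1$ and leaves the Wald p invariant; odds ratios are per
ln-p unit). Nondirectional mode substitutes the unsigned score
$-\ln p_g$. Set-level FDR is again Benjamini–Hochberg, with the family
being all sets tested in one run, and the enriched flag defaults to
FDR < 0.01. The signed cross-condition matrix used for clustering holds
$\mathrm{sign}(\beta_1) \cdot (-\log_{10} p_S)$ with zeros for untested
term–comparison pairs.

Numerics: the two-parameter IRLS solves the weighted normal equations in
closed form, converges on a maximum coefficient change below $10^{-10}$
(at most 50 iterations), and guards each Newton step by deviance-based
step-halving. The guard matters in practice: signed scores can span
several hundred ln-p units in strongly powered comparisons, and an
unguarded Newton step then overshoots into numerical divergence for
exactly the most strongly loaded sets. Fits ending with
$|\beta_1| > 20$ (effective separation) or without convergence are
flagged `unstable` and report no p-value rather than a misleading one.
Sets are restricted to a configurable size window, default [10, 500],
after intersection with the universe. At gene level, genes measured by
several probes are represented by the probe with the highest mean
intensity; both probe- and gene-level universes are exposed since the
choice is a genuine free parameter.

## Term redundancy collapsing

Ontology annotation propagates from child to parent, so an enriched
specific term usually drags its parents along. The collapse rule
operates on the significant list over a child-to-parent DAG: for each
significant parent, its significant direct children with membership
Jaccard at or above a threshold (default 0.7, on measured-universe
memberships) are found; exactly one such child displaces the parent
(the more specific term wins), two or more qualifying siblings are
displaced by the parent (the more general term wins). The rule runs
leaves-first and repeats to a fixed point, so nested chains resolve
deterministically, and every drop is logged with the kept relative and
the Jaccard value. "A similar group of genes" has no canonical numeric
definition, so the threshold is an explicit, logged parameter rather
than a hidden constant. The procedure is idempotent on its own output.

## qPCR relative quantification and concordance

Relative quantification assumes amplification efficiency exactly 2
(validated by serial dilution in the assay designs this emulates, and
out of scope here). Duplicate wells are averaged, the target Ct is
normalized to the reference gene within each condition, and
$\mathrm{fold} = 2^{-\Delta\Delta C_t}$. Because the reference gene is
measured in the same well group, any condition-wide Ct shift (loading,
input amount) cancels exactly — a property the tests assert. Per-gene
folds across subjects are summarized as the arithmetic mean of
per-subject log2 folds, exponentiated; the weighting of the average is
not canonical, and the geometric-mean choice keeps the summary
symmetric in up- and down-regulation. Cross-platform agreement pairs
the array-side fold $2^{b_g}$ of each gene's representative probe with
the qPCR-side fold and reports Spearman's rho (average-tie ranks,
t-approximation p on $n-2$ df; an exact permutation null is available
for $n \le 9$).

## The synthetic generator

The generator emulates the statistical structure the chain assumes, with
defaults mirroring the emulated study design: sex-by-time groups of
3, 3, 4, 4 subjects (6 male and 8 female control arms for the baseline
contrast), two samples per subject, mean intensities uniform on
[4, 14] log2 units, prior degrees of freedom 4, prior scale 0.05 at the
intensity-range centre with a log-linear slope of −0.2 per log2 unit
(variance decreasing with intensity, as on oligonucleotide arrays),
subject random-effect SD 0.3, a 5% differential fraction at |log2
fold| = 1 by default, and a 2% baseline sex-effect fraction. The
gene-level variance $\sigma_g^2$ is drawn from the scaled-inverse-chi-
square prior *at the within-subject contrast level*: each arm sample
receives noise variance $\sigma_g^2/2$, so paired differences have
variance exactly $\sigma_g^2$ and the fitted residual variances are
marginally $s_0^2\,F(d_g, d_0)$ — the distributional assumption the
moderation step makes, which the test suite checks by a
Kolmogorov–Smirnov test on 50,000 genes. Sex effects are planted on
every sample of male subjects: a sex effect is a property of the
subject, not of one arm, and planting it on a single arm would alias it
into the paired exercise contrasts. Effects are additive on the log2
scale. One root seed drives fixed per-component substreams, so adding
probes does not perturb subject effects and every artifact is exactly
reproducible from `(config, seed)`.

Gene sets are emitted with planted structure: "loaded" sets draw a
configurable fraction (default 0.8) of members from differential probes
of one condition and direction, null sets draw uniformly, and a
structured tail provides one parent/child pair at Jaccard 0.9 and one
parent with two 0.75-overlap siblings for the collapse rule. The qPCR
generator emits duplicate wells with technical noise (default SD 0.1
Ct), matched reference wells, and a shared per-sample loading shift.

What the generator does *not* emulate — probe-level effects,
cross-hybridization, batch and spatial artifacts, correlated genes
within sets beyond the planted mean shifts, non-normal noise — bounds
what passing tests show: they validate the inference machinery under
its own model, not robustness to real-array pathologies.

## Problem sizes and runtime choices

The test suite exercises hyperparameter recovery at 50,000 genes
(20 replicates), null calibration at 20,000 probes, power ordering on
100 replicates of 2,000-probe studies, enrichment calibration on 2,000
single-set replicates over a 2,000-gene universe, and the full
five-comparison pipeline on 25 replicates of 2,000-probe, 60-set
studies — sizes chosen so each property is measured with useful
precision while the whole suite runs in about a minute on one core.
The acceptance script recomputes the same quantities at comparable
sizes from a user-supplied seed.

## Known limitations

Only two-group contrasts are supported (no covariates, array weights or
multi-coefficient models); missing expression values are rejected
rather than imputed; the collapse rule sees only direct parent–child
edges per pass (transitive redundancy resolves through repeated passes,
not through ancestor look-ahead); and the enrichment model treats genes
as exchangeable given their scores, ignoring inter-gene correlation,
which can make set-level p-values optimistic on strongly co-expressed
real data.
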