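---
title: "Genotype-by-tissue interaction analysis: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-by-tissue interaction analysis: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxtissue)
```

## The question

When the same small set of genes is profiled across many tissues under
several conditions, differences in expression can come from three sources:
the gene itself (genotype main effect), the tissue (environment main
effect), and the gene × tissue interaction. Plant breeding has a mature
statistical toolkit for exactly this data shape — multi-environment trials
— and this package transfers three of its instruments to tissue panels of
qPCR relative expression: split-split-plot ANOVA, AMMI, and GGE biplots.
The packaged dataset (`load_takifugu_cold()`) is a cold-stress experiment
on tiger puffer: four cold-resistance genes × nine tissues × four water
temperatures, n = 3, stored as per-cell mean ± SD.

## Working from sufficient statistics

Every two-way analysis here needs only the cell means, the per-cell SDs
and the replicate count. For a balanced design the treatment sums of
squares are functions of the cell means alone, and the pooled error SS is
recovered exactly as

$$SS_{error} = \sum_{cells} (n - 1)\,sd^2,\qquad df = \sum_{cells}(n-1),$$

which is why a published summary table is a complete input. The sample SD
uses the n − 1 denominator throughout; with any other convention the error
SS recovered from a summary would not match the replicate-level residual
SS. When a replicate-level method is wanted, `expand_summary()` emits
pseudo-replicates whose sample mean and SD match each cell *exactly*
(seeded standard-normal draws, affinely adjusted), so
`summarize_expression()` ∘ `expand_summary()` is the identity on summary
tables up to floating-point error.

Expression stays on the raw fold-change scale: no log transform is applied
by default, because the SS magnitudes and percent attributions of the
companion analyses are only meaningful on that scale. Users who prefer
variance-stabilized input can transform before summarizing.

## Split-split-plot ANOVA

The design randomizes temperature on main plots within complete blocks,
tissue on sub-plots and gene on sub-sub-plots:

$$y_{ihjk} = \mu + b_k + d_{ihj} + f_{ik} + g_{ihk} + e_{ihjk},$$

with three error strata $f_{ik}\sim N(0,\sigma_f^2)$,
$g_{ihk}\sim N(0,\sigma_g^2)$, $e_{ihjk}\sim N(0,\sigma^2)$. Each fixed
term is tested against the stratum of its own tier: temperature against
the main-plot error (df $(b-1)(t-1)$), tissue and temperature × tissue
against the sub-plot error (df $t(b-1)(s-1)$), and all gene-involving
terms against the residual (df $ts(b-1)(g-1)$). Blocks are a replication
factor and get no F test; no block × treatment interactions beyond the
designated error strata are fitted. The implementation is validated in
three ways: the degrees-of-freedom ledger, agreement of every stratum SS
with `stats::aov` with explicit `Error()` strata on the same data, and a
2000-replicate null Monte-Carlo confirming that each fixed-term test holds
its nominal 5 % size. A degenerate zero-variance stratum (possible in
noise-free synthetic data) yields `NA` for F and p rather than an error.

## AMMI

At one temperature the $g \times e$ table of cell means is

$$y_{ge} = \mu + \alpha_g + \beta_e +
  \sum_{n=1}^{N}\lambda_n\gamma_{gn}\delta_{en} + \theta_{ge},$$

fitted by double-centering and SVD; $N = \min(g-1, e-1)$. Choices that
deserve justification:

* **IPCA sum of squares** is $r\lambda_n^2$ — the SVD lives on cell means
  but the ANOVA is on the observation scale, so every SS is multiplied by
  the replicate count.
* **IPCA degrees of freedom** follow Gollob, $g + e - 1 - 2n$. They sum to
  $(g-1)(e-1)$ over all axes, which is the structural check the tests
  assert; with $g=4, e=9$ this gives 10, 8, 6 for the three axes.
* **F denominators**: the pooled within-cell error mean square, with its
  $\sum(n-1)$ df. This is a liberal choice relative to
  cross-validation-based axis assessment, but it is the conventional one
  for summary-statistics input and the one consistent with the packaged
  dataset's published analysis.
* **Percent of total SS** uses total = treatment + error, so the three
  attribution percentages (gene, tissue, interaction) do not sum to 100 —
  the remainder is replicate noise.
* **Sign convention**: each axis is flipped so the gene with the largest
  $\alpha_g$ has a non-negative score, removing the SVD's sign ambiguity
  from tests and plots.

Two reported axes is the default (`n_axes = 2`); further axes are pooled
into the residual row but remain available in the returned object.

## GGE biplots

GGE removes only the tissue main effect (column centering) and biplots the
first two axes of what is left — genotype main effect *plus* interaction.
The default configuration is tissue-centered, **unscaled**, with
**symmetric** singular-value partition ($\lambda^{1/2}$ to each side).
Unscaled, because the packaged study's winners track raw-scale magnitudes
(one gene dominates almost everywhere), which per-tissue SD scaling would
erase; symmetric SVP, because it is the customary compromise when both
gene and tissue views are read off one plot. Both options are exposed in
`gge_config()`.

The four views are computed, not drawn (plots are a thin optional layer):

* *Tissue relationships*: cosines between tissue vectors approximate
  expression correlations between tissues; in the full-rank
  environment-partition space the cosine equals the gene-wise Pearson
  correlation exactly (column centering makes each column zero-mean),
  which the tests verify. Vector length measures discriminating ability.
* *Which-won-where*: the convex hull of the gene points with perpendicular
  rays through the origin partitions tissues into sectors. The winner
  assignment is computed as the argmax over genes of the rank-2
  reconstructed centered expression, which coincides with the geometric
  sector winner (a linear functional is maximized at a hull vertex) and is
  invariant to the SVP choice. Ties are broken toward the larger PC1
  score; a tissue exactly on a boundary therefore resolves
  deterministically.
* *Mean vs stability*: the average-tissue axis (ATA) is the direction of
  the mean tissue vector; signed projections of gene points onto it rank
  mean performance, perpendicular deviations rank instability.
* *Ideal gene*: on the ATA at the maximum observed mean score with zero
  instability — a definition made explicit here because verbal
  descriptions of "ideal" vary; Euclidean distance to it gives the
  comprehensive ranking.

A caution on invariance: winners and the mean-performance ordering are
SVP-invariant (they derive from inner products in which the two
$\lambda$ exponents recombine), but stability and ideal-distance rankings
are **not** — rescaling the axes by different powers of $\lambda$ changes
perpendicular distances. On the packaged data the default configuration
reproduces the reference mean and stability orderings at all four
temperatures and the comprehensive orderings at 5 and 18 °C; at 13 °C the
reference comprehensive ordering appears under the environment-focused
partition instead, and at 8 °C the reference ordering's last two genes
(whose biplot points nearly coincide) are reproduced by no configuration —
`run_pipeline("reproduce")` lists both as explicit discrepancies rather
than forcing them.

## Curve families over temperature

For each gene × tissue series across the four temperatures, three families
are fitted: a power law $y = ax^b$ (log-log least squares) and quadratic
and cubic polynomials. With four points a cubic interpolates exactly, so
selection needs a parsimony rule: the smallest family whose $r^2$ reaches
$1-\tau$ is chosen ($\tau = 0.01$ by default), considering families in
order of parameter count (power, quadratic, cubic) and judging the power
family by its log-space $r^2$. The threshold is deliberately strict; on
the packaged data most series fall through to the cubic, and the scan
reports all three $r^2$ values so users can apply their own judgment. The
comparison report treats the reference family labels as a best-effort
target and lists every mismatch.

## Synthetic data

Two seeded generators mirror the two models exactly. `simulate_ammi()`
draws $r$ Gaussian replicates around
$\mu + \alpha_g + \beta_e + \sum\lambda_n\gamma_{gn}\delta_{en}$, with
orthonormal zero-sum score matrices built by column-centering Gaussian
draws and QR orthonormalization (centering first, so the columns stay in
the zero-sum subspace) — this makes noiseless recovery exact, which the
tests exploit at 1e-6 tolerance. `simulate_ssp()` draws each error stratum
at its own tier. Defaults emulate the packaged study's geometry
(4 genes × 9 tissues × 3 replicates; unit noise SD).

What the generators deliberately do **not** model: the strong mean–variance
coupling visible in real qPCR fold-changes (cells with large means have
large SDs). Both forward models are homoscedastic, matching the ANOVA
assumptions of the analyses they feed. Passing recovery and size tests on
this synthetic data therefore validates the arithmetic and the error-strata
bookkeeping, not robustness to heteroscedasticity — on real data the F
tests should be read with that caveat.

## Problem sizes and determinism

The validation suite uses a 2000-replicate null simulation at the study's
own replication (b = 3, t = 4, s = 9, g = 4) for the type-I-error check,
500 replicates for the null-interaction calibration of the AMMI F, and
1000 replicates for the expected-mean-square check of the main-plot error
stratum; all are seeded and deterministic, as are both generators (the
global RNG state is saved and restored around every seeded draw).

## Known limitations

* Balanced, complete designs only; no REML path for missing cells.
* The AMMI F tests use the pooled-error denominator; no cross-validation
  or robust alternatives for axis retention.
* Biplot interpretations (cosine ≈ correlation, 2-PC sector winners) are
  approximations whose quality degrades as PC1+PC2 capture less of the
  G+GE SS; the model reports that percentage so users can check it.
* Stability and ideal-gene rankings depend on the centering/scaling/SVP
  configuration; the configuration is always recorded in the model object
  and the run log.
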