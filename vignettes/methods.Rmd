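---
title: "Survival-based gene set enrichment: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival-based gene set enrichment: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survenrich)
```

## The question and the two rankings

Preranked gene set enrichment needs only a ranked gene list; any signed
per-gene statistic can stand where the log fold change usually does. This
package provides two rankings over the same enrichment back end:

* **Survival mode.** Each gene's normalized expression $x$ enters a
  univariate Cox proportional-hazards model
  $h(t, x) = h_0(t)\,e^{\beta x}$, and genes are ranked by the estimated
  log hazard ratio $\beta$. A positive $\beta$ means patients with higher
  expression of that gene die at a higher instantaneous rate, at all times,
  under the proportional-hazards assumption. The model is semi-parametric:
  $h_0(t)$ cancels in the partial likelihood and no distributional
  assumption is placed on event times. Right-censored follow-up is handled
  naturally. Consequently, pathways with positive NES are enriched in
  mortality-associated genes and pathways with negative NES in
  survival-associated genes.
* **Fold-change mode.** The classical case-vs-control analysis: genes are
  ranked by a two-group negative-binomial log$_2$ fold change with
  median-of-ratios size factors.

## Normalization

Counts are filtered and transformed before the Cox fits:

* **Low-expression filter.** A gene is kept when its mean reads per sample
  is at least `min_mean_reads` (default 0.1, i.e. one read per ten samples
  on average). The boundary is inclusive; a gene exactly at the threshold
  survives.
* **log$_2$-CPM.** $x = \log_2\!\big((y + 0.5)/(L + 1) \times 10^6\big)$
  with $L$ the sample's total raw count. Library sizes are computed on the
  *pre-filter* matrix and held fixed through filtering; the genes a filter
  removes carry almost no reads, so the choice is numerically immaterial,
  but fixing the order makes results reproducible to the bit.
* **Precision weights.** `mean_variance_weights()` estimates the
  mean–variance trend of the log-CPM values (lowess of the square-root
  standard deviation on the per-gene mean, converted to inverse-variance
  weights $1/\max(s,\text{floor})^4$). The weights are reported for
  diagnostic use only: the hazard model above is unweighted, so the Cox
  fits deliberately do not consume them. Feeding observation weights into
  a partial likelihood is a different estimator with different sampling
  properties, and nothing in the reference model calls for it.

## The Cox fits

Per gene, Newton–Raphson with step-halving maximizes the Efron-tied partial
likelihood (Breslow available via `ties = "breslow"`; the two coincide
exactly when no event times are tied). Numerical constants: convergence
when the step is below $10^{-9}$ or the relative log-likelihood change is
below $10^{-12}$, at most 50 iterations, covariates centered before
iteration. Degenerate genes are *excluded from the ranking* rather than
assigned $\beta = 0$ — a fabricated zero would sit in the middle of the
ranked list and distort the enrichment null — but remain in the statistics
table with a flag:

* `zero_variance` — constant expression, no information;
* `monotone_likelihood` — $|\beta| > 15$ during iteration
  (quasi-complete separation, the finite maximizer does not exist);
* `nonconverged` — iteration cap reached.

The ranking statistic is the raw $\beta$ (the log hazard ratio itself);
`rank_stat = "z"` switches to the Wald statistic for users who prefer
variance-standardized ranking. Exact ties in the statistic are broken by
gene id ascending so rankings are deterministic.

## The fold-change fits

The estimator is deliberately simple, and that simplicity is a documented
deviation surface: per-gene method-of-moments dispersion
$\hat\alpha = \max\{0, (\hat v - \hat m)/\hat m^2\}$ pooled across groups,
and a log$_2$ fold change equal to the ratio of size-factor-normalized
group means, with a Wald standard error from the negative-binomial Fisher
information at the fitted means. There is no empirical-Bayes dispersion
shrinkage, no shrunken fold changes, and no outlier handling, so borderline
log$_2$FC values can differ from shrinkage-based pipelines. Two exact
properties anchor the estimator: with equal size factors it *is* the NB
(and Poisson, at $\alpha = 0$) maximum-likelihood estimate; and rescaling
all counts of one sample leaves every log$_2$FC unchanged once
median-of-ratios factors are re-estimated, because the rescaling moves all
normalized counts by a common factor that cancels in the ratio. An
offset-GLM maximum-likelihood fit would trade the second property for a
slightly different weighting of unequal-depth samples; the normalized-means
form was chosen because a normalization step that does not absorb a
sample's sequencing depth is a silent failure mode.

## Enrichment score, null, NES, p-values

With ranked statistics $r_1 \ge \dots \ge r_N$ and a set $S$ of size $k$,
the running sum gains $|r_i|^p / \sum_{j \in S} |r_j|^p$ at members and
loses $1/(N-k)$ elsewhere; the enrichment score is the signed extremum of
largest magnitude and the leading edge contains the members at or before
(positive ES) or at or after (negative ES) the extremum. Defaults follow
GSEA convention: exponent $p = 1$, set sizes 15–500 retained, 10,000
permutations. The $p = 1$ weighting is sensitive to the statistic's scale,
not only its ranks — a property test guards against accidental rank-only
scoring.

Two numerical choices deserve note:

* **Sign ties.** The positive and negative extrema can have exactly equal
  magnitude (e.g. $\pm 2/7$ in a 10-gene universe): the score resolves to
  the positive side, with a relative-tolerance comparison applied
  identically in the full-curve path and the subset-only fast path used
  for permutations, so floating-point summation order can never decide a
  sign.
* **Degenerate weights.** If every member statistic is exactly zero the
  hit increments fall back to $1/k$ with a warning.

The null is the plain gene-set permutation scheme: for each distinct set
size, the ES of `n_perm` uniformly sampled gene subsets (computed once and
cached per size). NES normalizes by the mean magnitude of same-sign null
scores; the p-value is add-one corrected,
$(1 + \#\{|ES_{null}| \ge |ES|,\ \text{same sign}\})/(1 + n_{same})$, with
ties counted as exceedances (conservative) — so p-values are never 0 and
saturate at about $1/(n_{perm}+1)$. No adaptive/multilevel refinement of
extreme p-values is attempted; users who need $p \ll 10^{-4}$ resolution
should raise `n_perm`. Benjamini–Hochberg adjustment runs jointly across
all retained pathways, and the conventional 15% FDR threshold is the
default notion of "significant" in summaries, top tables and the
`compare_significant()` Venn counts.

## The synthetic-data generator

The generator emulates exactly the structure the method assumes, which
makes it the right instrument for validating the estimators and the wrong
instrument for claiming real-data performance:

* counts are NB with gene means log-uniform on $[2, 500]$ and common
  dispersion 0.2 (typical bulk RNA-seq magnitudes);
* event times are exponential with rate
  $h_0 \exp\big(\sum_g \beta_g z_g\big)$ over the planted genes' per-gene
  standardized log-CPM $z_g$ ($h_0 = 0.1$) — proportional hazards by
  construction, sampled in closed form;
* censoring is uniform on $(0, c)$ with $c$ calibrated by bisection to a
  target fraction (default 30%, realized within a few points at
  $n \ge 200$);
* defaults plant two 30-gene pathways at per-gene $\beta = 0.8$
  (log$_2$FC 1 in the two-group mode) among 2000 genes and 300 samples,
  with 20 thirty-gene decoy sets disjoint from the planted genes.

What the generator does **not** emulate: gene–gene correlation beyond the
shared hazard, batch effects, varying sequencing depth profiles,
non-proportional hazards, informative censoring, and outlier counts.
Passing the recovery tests therefore demonstrates correctness of the
estimators under the model's own assumptions, not robustness to their
violation.

One behaviour of gene-set permutation nulls is visible even in synthetic
data: when a large block of genes carries strong signal, random subsets
(which may include signal genes) and signal-free decoy sets are not
exchangeable, so decoys can drift toward significantly *negative* scores.
This is a property of the null scheme shared by all preranked GSEA
implementations, strongest when the signal fraction is large.

## Validation problem sizes

The shipped test suite validates, among other things: agreement of every
Cox fit with a brute-force 1-D partial-likelihood maximizer (50 random
datasets, $n \le 30$, to $10^{-4}$) and with an independent reference
implementation (to $10^{-6}$); exact agreement of the enrichment score
with a literal running-sum walk (200 random instances); Monte-Carlo
p-values against exhaustive enumeration of all $\binom{10}{3}$ subsets
within three binomial standard errors; p-value calibration on 100 fully
null rankings of 2000 genes $\times$ 50 sets (fraction below 0.05 within
$0.05 \pm 0.02$); and planted-pathway recovery across 50 replicates of the
default generator conditions (positive NES at FDR 15% in $\ge 90\%$ of
planted sets, decoys $\le 20\%$), plus the mirror-image check that flipping
every planted $\beta$ flips the planted NES signs. Permutation counts in
these runs (1000–10,000) are chosen for the resolution each threshold
needs, not as recommendations; the package default stays 10,000.

## Known limitations

* Univariate hazard models only: no covariate adjustment, stratification,
  time-varying effects, or proportional-hazards diagnostics.
* The fold-change contrast is unpaired two-group only.
* Identifier handling is strict: duplicate gene ids are rejected, not
  aggregated, and no identifier translation is attempted — the GMT must
  use the same identifiers as the count matrix.
* p-values saturate at the permutation floor; extremely small adjusted
  p-values are reported at that floor, not extrapolated.
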