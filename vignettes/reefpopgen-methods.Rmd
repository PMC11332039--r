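---
title: "Methods: population-genomic divergence and genotype-environment association in reef corals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genomic divergence and genotype-environment association in reef corals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`reefpopgen` implements the inference chain used to ask whether thermal
history shapes species divergence in broadly distributed reef corals: from a
filtered SNP matrix through clone removal, population structure, windowed
differentiation, f-statistics, distance-based correlation tests, a
genotype-environment association scan and a divergent-selection scan, to a
final synthesis that asks how temperature-associated SNPs, islands of
differentiation and selection signals overlap. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic data generator does and does not emulate.

## The synthetic study design

Real datasets of this kind are jointly genotyped colonies from on the order
of eleven islands, about three sites per island and a handful of colonies
per site, with several morphologically cryptic species mixed across islands.
`simulate_dataset()` emulates exactly this layout with a two-level
Balding-Nichols model:

* a locus's ancestral frequency is `p ~ Uniform(0.05, 0.95)`;
* each species' frequency is a Beta draw around `p` with an FST-scale drift
  parameter `f_species` (default 0.15, the magnitude typical of sibling
  coral species);
* each island-within-species frequency is a further Beta draw at `f_island`
  (default 0.02, weak within-species structure);
* genotypes are `Binomial(2, p_island)` — Hardy-Weinberg within demes.

For the `n_selected` environment-associated loci, the island frequency is
shifted on the logit scale by `cline_slope` times the island's standardized
position on a latent thermal gradient, which keeps frequencies inside (0,1)
and matches the logistic parameterization of the selection scan. The paper
trail gives no per-species effect sizes for such clines, so the default
slope is chosen for testability (planted loci are detectable but not
trivially so), not biological calibration.

Temperature descriptors (default 63 per site) are noisy affine images of a
single latent island gradient plus site-level noise. This reproduces the one
property that matters downstream — heavy mutual correlation that justifies
PCA reduction — and nothing else about real sea-surface-temperature
summaries. Clonal replicates are exact genotype copies between two samples
of the same species and island; QUAL values are drawn in [30, 60] so the
default quality filter passes everything deterministically and the filter
logic is exercised by construction, not by accident.

The generator does **not** simulate reads, linkage beyond positional
adjacency, coalescent genealogies, or selection dynamics over time. Passing
tests therefore demonstrate the correctness and calibration of the
estimators under the stated generative model, not robustness to every
property of real data (e.g. background LD, batch missingness, or reference
bias).

## Filters and LD pruning

`apply_site_filters()` keeps biallelic sites with minor allele frequency
>= 0.05 (computed on non-missing calls, boundary inclusive), QUAL >= 30 and
missing fraction <= 0 by default. The three criteria are independent, so the
filter is idempotent and order-insensitive.

`ld_prune()` makes a single left-to-right pass per contig and discards a
site whose squared Pearson correlation of dosages (composite LD on unphased
genotypes) with any of the most recently *retained* `window - 1` sites
reaches `r2 >= 0.2`. Two numerical choices deserve note. First, the window
is counted over retained sites: counting over raw input indices would make
the pass non-idempotent, because removals renumber the window on a re-run.
Second, integer dosage vectors can produce r-squared values that are
*exactly* 0.2, where floating-point noise would otherwise make the
keep/drop decision platform-dependent; the comparison therefore carries a
1e-9 slack. r-squared against a monomorphic site is defined as 0, and the
earlier site of an offending pair is always the one kept.

## Clone detection

`pairwise_distance()` is the allele-sharing (Prevosti) distance: the mean
over co-typed sites of `|d_i - d_j| / 2`. Exact clones are at distance 0;
sequencing-free simulation makes this exact, while real data would show a
small positive clonal mode. `detect_clone_threshold()` formalizes the usual
visual rule — "cut at the gap after the clonal mode" — as the left edge of
the first empty Freedman-Diaconis histogram bin, returning 0 when no pair
falls below 10% of the median distance. Multilocus lineages are the
connected components of the graph joining pairs at or below the threshold
(single linkage, computed via `hclust`), with the lexicographically
smallest sample as the deterministic representative.

## Population structure

`gt_pca()` operates on column-centered, unscaled dosages (allele-count PCA).
`estimate_ancestry()` is a deliberately simplified least-squares stand-in
for sparse nonnegative matrix factorization of one-hot-encoded genotypes:
minimize `||W * (X - QG)||^2 + alpha ||G||^2` with admixture rows `Q` on the
probability simplex, ancestral genotype-class frequencies `G` in [0, 1], and
ridge weight `alpha = 10` (the regularization strength used by the original
tool; its mapping onto this objective is heuristic). Optimization uses
projected-gradient block updates with Lipschitz step sizes, which guarantees
a monotonically non-increasing objective — an invariant the tests check.
Random restarts (default 10) are initialized from k-means clusterings of the
PCA scores; this matters, because a near-uniform start is a symmetric
stationary point where all ancestral profiles collapse onto the pooled
frequencies.

`choose_K()` masks 5% of genotype entries, fits each candidate K on the
unmasked data, and scores the masked entries by cross-entropy. Predictions
use ancestral class frequencies re-estimated from `Q` with a one-observation
pseudo-count toward the pooled frequencies: the ridge-shrunk `G` from the
fit can contain exact zeros, and a single impossible held-out genotype would
otherwise dominate the criterion. Exact ties break toward the smaller K.
The acceptance surface of this module is cluster-recovery behaviour (does
the criterion find the simulated number of species; do well-separated
species get >= 0.95 coefficients), not coefficient-for-coefficient equality
with any published tool.

## Differentiation and f-statistics

`wc_fst_site()` implements the Weir-Cockerham (1984) two-population
variance components a, b, c from genotype counts; the site estimator is
`theta = a / (a + b + c)`. Windows (`window_fst()`) are non-overlapping 500
bp bins aggregated as a ratio of sums `sum(a) / sum(a+b+c)` — the standard
choice, since mean-of-ratios is biased at low per-site information;
negative site components are retained, not clamped. Genomic islands of
differentiation (`call_gids()`) are the top `ceiling(0.01 * W)` bins by mean
among-lineage FST, with ties at the cut broken by genomic position so the
count is reproducible.

`f2_stat()` uses the bias-corrected estimator
`(pA - pB)^2 - pA(1-pA)/(nA-1) - pB(1-pB)/(nB-1)` over allele counts, with
`f2(A, A) = 0` by definition. `f4_stat()` is computed through the f2
decomposition `f4 = (f2(A,D) + f2(B,C) - f2(A,C) - f2(B,D)) / 2`, under
which the sampling corrections cancel when the four groups are distinct and
the identities `f4(A,B;C,C) = 0`, antisymmetry, and `f4(A,B;A,B) = f2(A,B)`
hold exactly. Standard errors come from a delete-one block jackknife over
contiguous blocks of 500 SNPs (appropriate for LD-pruned input; a
base-pair block option would be needed for linked data), and `|Z| >= 3` is
flagged as significant.

## Distance matrices and Mantel tests

Genetic distances are linearized as `FST / (1 - FST)`. Geographic distances
are great-circle (haversine, R = 6371 km) between island coordinates taken
as the mean of site coordinates; overwater routing around land is
deliberately out of scope, a documented divergence from field practice for
archipelago data. Environmental distances are Euclidean on the scores of a
standardized-descriptor PCA that keeps the smallest number of components
reaching 80% cumulative variance, capped at 5. Mantel tests (via
`vegan::mantel`) use Pearson correlation of lower triangles and a one-sided
"greater" permutation p-value `(1 + #{r* >= r}) / (1 + n_perm)` — the +1
smoothing avoids p = 0, and the one-sided alternative reflects that
isolation-by-distance is directional.

## RDA genotype-environment association

`fit_rda()` regresses the centered (unscaled) dosage matrix on sample-level
environment predictors — each sample inherits its site's retained
environment PCs — and eigen-decomposes the fitted values (via
`vegan::rda`). The number of axes used downstream is chosen by the
broken-stick rule (all constrained axes above expectation, minimum 1), a
point the underlying protocol leaves to the analyst. `outlier_scan()`
scales per-SNP loadings per axis and computes their squared Mahalanobis
distance with a classical mean/covariance; the cited protocol's robust
covariance estimator is not used, a choice that matters little here because
the genomic inflation factor `lambda = median(D2) / qchisq(0.5, df)`
rescales the statistic before p-values are taken from the upper chi-squared
tail. q-values are Benjamini-Hochberg; outliers are `q < 0.1`; the top-100
set ranks by p with ties broken by larger D2 and then genomic position.
The per-genus significance cutoffs reported for real data are consequences
of the top-100 rule, and the scan derives its own cutoff the same way.

## The F-model selection scan

The scan decomposes locus-by-population differentiation on the logistic
scale: `F_{l,p} = plogis(alpha_l + beta_p)`, with `alpha_l` a
locus-specific (selection) effect and `beta_p` a population-specific
(drift) effect. Population allele frequencies are Balding-Nichols draws
around locus ancestral frequencies `pbar_l` with shape total
`theta = (1 - F) / F = exp(-(alpha_l + beta_p))`, and observed ALT counts
are binomial. Rather than sampling latent frequencies, the likelihood is
marginalized to a beta-binomial — exact, faster, and easier to verify.

`alpha_l` carries a spike-and-slab prior (point mass at 0 with prior
inclusion 0.1; Gaussian slab, SD 2) so the posterior probability of
divergent selection `P(delta = 1, alpha > 0)` is sampled directly; this
replaces the reversible-jump machinery of the original software with
equivalent inclusion-probability semantics. Updates are
Metropolis-within-Gibbs, vectorized across loci (independent given `beta`)
and across populations, with a logit random walk for `pbar` (uniform prior,
Jacobian included) and a birth/death proposal for the spike-slab toggle.
Convergence is monitored by split-R-hat on each `beta_p`. Desk-scale runs
use a few thousand iterations on a few hundred loci; the original software's
production settings (hundreds of thousands of iterations per contig, with
demographic parameters fixed from converged first-pass runs) are mirrored
structurally by the `fixed_beta` two-pass mode, and the module asserts
calibration properties — null false-discovery control, effect-size
monotonicity, planted-effect ranking — not numeric equality with any
published sampler.

`call_selection()` ranks loci by posterior probability of divergent
selection and flags the largest prefix whose mean posterior neutrality
`(1 - P)` stays at or below the FDR target — the posterior-alpha FDR rule.

## Enrichment synthesis

`build_report()` joins three per-SNP annotations on one SNP universe: the
outlier table, GID membership (half-open 0-based windows; a SNP at 1-based
position P is in `[s, e)` iff `s <= P-1 < e`), and the selection call. It
reports the counts and percentages of temperature outliers, top outliers in
GIDs, top outliers under selection, and the enrichment ratios of those
proportions over the genome-wide selected fraction. Percentages are
recomputed exactly from counts and rounded half-up to 2 decimals for
display (base `round()`'s half-to-even would mis-print tabulated
proportions); raw fractions are always carried alongside. The outlier
percentage denominator is the unlinked (pruned) SNP count.

## Problem sizes and determinism

All stochastic functions take explicit seeds and one seed drives a whole
simulated dataset; identical seeds give byte-identical outputs. The test
and acceptance workloads use desk-scale problem sizes chosen to make each
property measurable with comfortable margins: 2e4 sites x 99 samples for
drift recovery, 2,000-site datasets for RDA calibration (10 null seeds),
200 loci x 10 populations x 2,000 iterations for null selection-scan
calibration and 150 x 14 x 30 diploids for planted-effect ranking, 1,000
null replicates for Mantel type-I error, and 30 seeded replicates for
K-recovery. A single admixed genotype is weakly informative, so the hybrid
ancestry check uses 2,000 sites and 40 samples per parental species.

## Known limitations

* The ancestry module is a least-squares factorization, not a likelihood
  method; its cross-entropy criterion inherits the flat-curve behaviour of
  such objectives when divergence is weak, and ties resolve to smaller K.
* The selection scan fits one hierarchy level at a time (populations within
  one comparison); the original nested group/population/higher-hierarchy
  sampler is out of scope, so results are behavioural, not numerical,
  analogues.
* Great-circle distances understate separation for islands whose shortest
  overwater route detours around land.
* The LD pruner's retention rule (keep the earlier site) is one of several
  defensible conventions; tools differ, and pruned site lists are not
  expected to match any particular external pruner site-for-site.
* Window FST uses non-overlapping bins; a step smaller than the window
  would need an explicit tiling rule for the GID quantile.
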