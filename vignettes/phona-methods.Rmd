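---
title: "Phenotype-OTU network analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-OTU network analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the package computes

`phona` builds **phenotype-anchored microbial association networks** from
OTU count tables. The pipeline has two statistical arms that are merged
into a single graph:

1. **OTU-OTU arm.** Pairwise associations among OTUs are estimated with
   SparCC, a correlation estimator designed for compositional sequencing
   data, and screened for significance with a bootstrap null. Pairs with
   |rho| > 0.5 and p < 0.05 (both strict) become signed edges.
2. **OTU-phenotype arm.** A continuous phenotype (for instance
   marketable yield) is regressed on all OTUs' standardised relative
   abundances under an L1 penalty; the OTUs with nonzero coefficients at
   the tuned penalty are refit in an unpenalised Gaussian GLM whose
   coefficient signs become the phenotype links.

The merged graph contains one phenotype node; OTUs selected by the
regression arm are linked to it, whether or not they also participate in
OTU-OTU edges. The graph is then summarised (node degree, density,
negative/positive edge ratio), partitioned into modules by simulated
annealing, and every node is assigned one of the four topological roles
defined by within-module degree and among-module connectivity.

Supporting community statistics — alpha diversity, Bray-Curtis
dissimilarity with PERMANOVA, and per-OTU negative-binomial differential
abundance — round out the analysis, since network structure should
always be read against the community's composition.

## The SparCC estimator

Counts from amplicon sequencing are compositional: each sample's counts
are constrained to its sequencing depth, so naive correlations of
proportions are distorted (a genuinely independent pair can appear
negatively correlated simply because a third taxon bloomed). SparCC
works on log-ratios, which are invariant to the per-sample total.

For fractions $f_i$ the log-ratio variance of a pair is
$t_{ij} = \mathrm{var}\,\log(f_i/f_j)$. Writing $\omega_i^2$ for the
latent *basis variance* of taxon $i$ (the variance of its absolute log
abundance), $t_{ij} = \omega_i^2 + \omega_j^2 - 2\rho_{ij}\omega_i\omega_j$.
Under the sparsity assumption — most true correlations are near zero —
summing over each taxon's partners gives a linear system in the
$\omega_i^2$, and the correlation estimate follows as

$$\rho_{ij} = \frac{\omega_i^2 + \omega_j^2 - t_{ij}}{2\,\omega_i\omega_j},$$

clipped to $[-1, 1]$. Pairs that clearly violate sparsity (currently the
strongest $|\rho|$ above the `exclusion_threshold`, default 0.1) are
iteratively excluded from the system and the basis variances re-solved,
up to `n_exclusion_rounds` (default 10) times. Exclusion stops short of
stripping a taxon below two partners, where its row equation would
degenerate; non-positive solutions are floored at $10^{-12}$ and any
degenerate pair's correlation is set to 0 with a warning.

Counting noise is propagated by resampling fractions from each sample's
posterior Dirichlet(counts + 1) and averaging the correlation estimate
over `n_iterations` (default 20) such draws. The add-one prior also
resolves zero counts, which the log-ratios require. We read the
conventional "iterations" of this estimator as Dirichlet draws, with the
exclusion rounds a separate parameter; both are exposed.

**Bootstrap significance.** The null is built by resampling each OTU's
counts over samples with replacement, independently per OTU. This
destroys all inter-OTU association while preserving every OTU's marginal
distribution and the depth structure. SparCC is re-run on each of
`n_bootstraps` (default 500) such tables — with a single Dirichlet draw
each, for tractability — and the two-sided p-value for a pair is
$(1 + \#\{|\rho_{\mathrm{null}}| \ge |\rho_{\mathrm{obs}}|\})/(1 + B)$.
The add-one form avoids p = 0; the smallest attainable p is $1/(B+1)$,
i.e. 1/501 at the default. Under an association-free generator the
fraction of pairs with p < 0.05 sits in the nominal band (the test suite
checks 0.02–0.09).

## Phenotype-predictive OTU selection

Predictors are relative abundances (counts over the rarefied depth),
each column standardised to mean 0, sd 1 so the L1 penalty treats OTUs
equally regardless of abundance scale. The penalty lambda is tuned on a
grid of 100 values log-spaced from $\lambda_{\max}$ (the smallest lambda
zeroing all coefficients) down to $10^{-4}\lambda_{\max}$, by k-fold
cross-validation (default 5 folds) repeated `n_repeats` times (default
500), scoring held-out squared error.

**Selection rule.** Three rules are implemented. The default is the
one-standard-error rule (`min_mean_1se`): the sparsest lambda whose mean
CV error is within one SE of the minimum, with the SE measuring
fold-resampling uncertainty (averaged over repeats — deliberately *not*
divided by the repeat count, so the rule does not collapse onto the CV
minimum as repeats grow). The alternatives `min_mean_cv` (the CV-error
minimum) and `min_cv_variance` (the lambda whose CV error varies least
across repeats) are selectable. The one-SE default was chosen after
measuring both alternatives on null phenotypes: the CV minimum rewards
chance in-sample correlations and selects spurious OTUs in roughly half
of pure-noise datasets at these sample sizes, and the minimum-variance
reading behaves similarly; the one-SE rule returns the empty model under
the null while still recovering planted drivers at signal-to-noise
ratios of 5 and above (both behaviours are asserted in the test suite).

OTUs with nonzero coefficients are refit in an ordinary Gaussian GLM
with intercept. Its per-OTU coefficient signs and Wald p-values define
the phenotype links. Aliased columns in a rank-deficient design are
dropped with a warning. No train/test split is performed by default —
the aim is attributable predictors, not out-of-sample accuracy — and an
empty selection is legitimate: the pipeline completes with a phenotype
node of degree zero.

When sample metadata defines treatment-by-compartment subsets, the whole
two-arm analysis runs separately within each subset (`subset_by` in the
pipeline configuration), since both the association structure and the
phenotype relation are expected to be condition-specific.

## Graph summaries, modules, and roles

`derived_attributes()` reports node degree as **edges/nodes** (half the
conventional mean degree, which is also exported as `mean_degree`),
density as edges over unordered pairs $n(n-1)/2$, and the
negative/positive edge ratio, rounded to 1, 2 and 2 decimals
respectively — the convention used in published summary tables of this
kind of network, which the tests reproduce row by row.

**Modules** maximise Newman-Girvan modularity
$Q = \sum_s (e_s/m - (d_s/2m)^2)$ by simulated annealing over the
unsigned, unweighted skeleton (role analysis ignores link types, and
standard Q is unsigned). The search (compiled, `src/sa_modularity.cpp`)
proposes single-node moves — to a random neighbour's module or,
occasionally, a fresh singleton — plus whole-module merges once per
sweep, with Metropolis acceptance and geometric cooling (defaults
t0 = 1.0, factor 0.995 per sweep, $10^4 \cdot n$ proposals), and
finishes with a greedy local polish to a move-stable optimum. The seed
is mandatory; results are deterministic given it. A zero-edge graph
yields singleton modules with Q = 0. Known closed forms (two disjoint
5-cliques: two modules, Q = 1/2) and planted two-block graphs are
recovered exactly in the tests.

**Roles** use within-module degree $z_i = (k_{i,s} - \bar k_s)/s_{k_s}$
(sample sd over the module's members; z = 0 where the sd vanishes) and
the participation coefficient $P_i = 1 - \sum_s (k_{i,s}/k_i)^2$. The
four categories split at z = 2.5 and P = 0.62 with inclusive boundaries:
network hub (both reached), module hub (z only), connector (P only),
peripheral (neither). Isolated nodes are peripheral with z = P = 0.

## Community statistics

- **Alpha diversity**: observed richness and Shannon entropy in nats on
  the rarefied table; $H \le \ln(\text{richness})$ with equality only
  for uniform counts.
- **Bray-Curtis** $d = \sum|a_i - b_i| / \sum(a_i + b_i)$ on counts; a
  semimetric (no triangle inequality), bounded in [0, 1]; pairs of
  all-zero samples are defined as 0 with a warning.
- **PERMANOVA** partitions the distance matrix sequentially over the
  model terms with p-values from free label permutation (default 1000
  permutations, via vegan's `adonis2`). Block-restricted permutation is
  not applied by default.
- **Differential abundance** fits, per OTU and contrast, a
  negative-binomial GLM with log link and log library-size offset on the
  two groups' samples, so that counts are modelled as implicit
  proportions. The dispersion is estimated per OTU by maximum likelihood
  (method-of-moments fallback where ML diverges, e.g. variance at or
  below the mean), with no information sharing across OTUs; the group
  effect is a 1-df deviance LRT at the fitted dispersion, and q-values
  are BH-adjusted within each contrast family (default FDR 0.01).
  Status calls (`enriched`/`depleted`) follow the fold-change sign at
  q below the threshold. Contrast controls may pool several levels
  (e.g. self-graft and nongraft controls against a hybrid rootstock).
  Non-convergent OTUs are flagged and excluded from the BH family. This
  estimator was chosen after measuring alternatives: re-estimating the
  dispersion under the null is markedly conservative for true effects,
  while the shared-dispersion LRT is calibrated at the nominal level
  (null fraction p < 0.05 around 0.06–0.08) and keeps its mild deep-tail
  inflation well inside the false-discovery headroom of BH at 0.01.

A fixed-effects one-way comparison of diversity across groups is
provided for synthetic-pipeline summaries; field designs with random
site and year effects call for a mixed model, which is outside this
package's scope.

## The synthetic-data generator

`synth_config()` + `generate_counts()` emulate the statistical structure
the pipeline assumes, so every stage is testable without sequencing
data:

- latent per-sample log basis abundances are multivariate normal with a
  sparse, user-planted correlation structure (identity elsewhere;
  non-positive-definite specifications are repaired by eigenvalue
  flooring with a warning);
- per-OTU mean log abundances are drawn N(0, 1.5) by default — the
  strongly uneven abundance distribution typical of ITS communities —
  and the per-OTU log sd defaults to 1.5, letting taxa fluctuate over
  roughly an order of magnitude between samples;
- observed counts are multinomial(depth, softmax of the latent
  abundances). This last step makes the data genuinely compositional:
  naive Pearson correlations of proportions are distorted, and the
  package's tests require SparCC to estimate a planted correlation more
  accurately than Pearson-on-proportions on the same data;
- the phenotype is a linear function of chosen OTUs' standardised
  relative abundances plus Gaussian noise;
- treatment designs are balanced factorials with planted per-OTU log2
  fold changes applied to the latent means before the compositional
  draw.

Ground truth (planted pairs, driver OTUs and signs, design) is always
returned alongside, and written as a sidecar file by the pipeline; tests
never re-derive truth from data. Identical seed and configuration give
bit-identical output.

What the generator does **not** emulate: taxonomic structure, read-level
error, chimeras, zero-inflation beyond the compositional draw,
rank-abundance shapes other than log-normal, and spatial or temporal
autocorrelation among samples. Passing tests therefore demonstrate
correctness of the estimators under the assumed generative model, not
performance guarantees on arbitrary field data.

A note on planted treatment effects: boosting abundant OTUs shifts every
other taxon's relative abundance downward (and, with variable library
sizes, shifts the offset), so large effects planted on dominant taxa
make null OTUs genuinely "depleted" in the compositional sense. The
differential-abundance fixtures therefore plant effects on minor taxa;
users simulating treatment effects should keep this coupling in mind —
it is a property of compositional data, not an artefact.

## Preprocessing and numerical choices

- Samples are rows and OTUs columns everywhere, matching the regression
  design matrix.
- Rare-OTU removal drops OTUs whose **total** count across samples is
  below `min_total` (default 10); the threshold is community-level, not
  per-sample, since the curated OTU tally it produces is a single
  community-level number.
- Rarefaction subsamples without replacement (multivariate
  hypergeometric), the convention of the standard amplicon pipelines;
  the default depth 6698 reflects a typical lowest-sample depth, and the
  pipeline caps it at the actual minimum row sum. The pipeline filters
  first and rarefies second; the two orders are *not* equivalent and the
  order is a documented configuration property, not an asserted fact.
- All randomness flows through explicit integer seeds, recorded in the
  run manifest; `seed = NULL` draws from the ambient RNG stream (used
  internally by the bootstrap loop).
- Lasso ties between equal-criterion lambdas resolve toward the sparser
  model; coefficients below 1e-10 after the final refit are treated as
  exact zeros (path-boundary numerical dust).
- Edge filtering uses strict inequalities on both |rho| and p, so a
  correlation of exactly 0.5 is excluded.

## Problem sizes used in the checks

The test suite and the acceptance script run at deliberately modest
sizes — e.g. 200 samples by 22 OTUs for planted-correlation recovery,
500 bootstrap tables over 20 OTUs for null calibration, 20 repeated
datasets of 100 samples by 60 OTUs at 50 CV repeats for support
recovery, 200 replicates for PERMANOVA type-I error — chosen so the
whole validation runs in minutes on one core while keeping each check's
sampling error well inside its asserted band.

## Known limitations

- SparCC point estimates attenuate somewhat for planted correlations
  involving rare taxa (the Dirichlet prior adds noise of order 1/count
  to their log fractions); the recovery tests budget for this.
- Per-OTU dispersion estimation at 10 samples per group is noisy; the
  differential-abundance test's deep tail is mildly anticonservative,
  which BH at FDR 0.01 absorbs but single-OTU p-values near 1e-3 should
  not be over-read.
- Modularity maximisation is NP-hard; simulated annealing with a fixed
  seed gives reproducible, near-optimal partitions, not certified
  optima, and module counts on real networks should be read with the
  usual resolution-limit caveats.
- The phenotype arm models a single continuous phenotype with a
  Gaussian identity link; other families are a configuration extension
  point, not yet implemented.
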