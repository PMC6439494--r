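---
title: "Landscape resistance and the allele-frequency covariance model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape resistance and the allele-frequency covariance model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resistgen)
```

# The problem

Crop-associated insects disperse through agricultural landscapes whose
composition has changed continuously since the nineteenth century. For a
pest that uses one crop as its dispersal conduit, the question is whether
*historical* or *contemporary* crop cover better explains the genetic
differentiation observed among present-day populations. resistgen
implements the full chain of analysis needed to ask that question with
county-level census data and SNP genotypes:

1. harmonize historic county census values onto a modern county layout
   (county boundaries change between censuses);
2. convert each era's crop-cover map into a pairwise landscape resistance
   between sampling sites;
3. fit a hierarchical Bayesian model of allele-frequency covariance in
   which geographic distance and per-era landscape resistance compete to
   explain differentiation;
4. compare the per-era effect sizes with an ANOVA/Tukey-HSD battery, and
   supply supporting statistics (pairwise FST, nucleotide diversity,
   observed heterozygosity, folded site frequency spectra, residual
   regressions).

A synthetic-data module generates county landscapes, census tables, sites
and genotypes under the model's own generative assumptions, so every stage
of the pipeline is exercised end to end without any external data.

# Census harmonization

Crop cover is represented as the proportion `p` of county area under the
crop (this absorbs differences in county size). When historic county
boundaries differ from the reference (modern) layout, `harmonize()`
transfers values by areal interpolation. The default `"printed"` mode
computes, for reference county $R$,

$$\sum_{i=1}^{n} a_i\, p_i, \qquad a_i = \frac{\mathrm{area}(i \cap R)}{\mathrm{area}(i)},$$

the sum over historic counties $i$ that overlap $R$ of the historic
proportion weighted by the fraction of the historic county inside $R$.
This quantity is faithful to the published form of the resampling rule but
is not a proper area-weighted mean: merging two fully-covered historic
counties into one reference county yields $p_1 + p_2$, which can exceed 1
(such values are reported as-is and logged). The `"weighted"` mode,
selectable everywhere, computes the true areal mean
$\sum_i \mathrm{area}(i \cap R)\, p_i / \mathrm{area}(R)$, clipped to
$[0, 1]$. Every harmonized output records its mode.

Geometry is deliberately minimal: all inputs must share one planar
projection in meters (coordinate ranges that look like longitude/latitude
are rejected with an explanatory error; the package never reprojects).
Intersection areas are computed by exact polygon clipping when at least
one of the two polygons is convex — which covers rectangular county grids
and most administrative units — and by a logged grid estimate otherwise.

# Landscape resistance to transmission

The resistance between two sites is computed on the straight line between
them ("shortest path line"): the transect is decomposed into segments by
county, and

$$\mathrm{LRT} = \frac{1}{\sum_{i=1}^{n} Z_i\, L_i / L_T},$$

where $Z_i$ is county $i$'s crop-cover proportion for the era, $L_i$ the
transect length inside the county and $L_T$ the total length. The
denominator is the length-weighted mean cover along the transect, so
$\mathrm{LRT} \ge 1$ whenever cover proportions are at most 1, and raising
any county's cover can only decrease the resistance. Transect pieces
covered by no county contribute $Z = 0$ — absence of the host crop is
resistance. A transect that crosses no cover at all has infinite
resistance; this is reported as `Inf` with a log message, and the model
layer replaces infinities by ten times the largest finite entry (a
configurable, prominently-warned policy in `finite_resistance()`) before
standardization. A transect piece lying exactly on a shared county
boundary is assigned to the county with the lexicographically smaller id,
a deterministic, logged tie-break.

Distance and resistance matrices are standardized by dividing by the
standard deviation of their off-diagonal upper triangle. Standardization
is per matrix (each era separately); the alternative — pooling the SD
across eras — is not used, and this choice is flagged here because the
source analyses do not state it.

# The allele-frequency covariance model

For locus $l$ with ancestral frequency $\mu_l$, the vector of latent
population frequencies $f_l \in [0,1]^K$ is multivariate normal,

$$f_l \sim \mathcal{N}\!\left(\mu_l \mathbf{1},\; \mu_l (1 - \mu_l)\,\Omega\right)
\quad \text{truncated to } [0,1]^K,$$

with covariance

$$\Omega_{ij} = \frac{1}{\alpha_0}
  \exp\!\left(-\big(\alpha_D D_{ij} + \textstyle\sum_k \alpha_{E_k} E_{k,ij}\big)^{\alpha_2}\right),
\qquad \Omega_{ii} = \frac{1}{\alpha_0}.$$

Observed alternate-allele counts are beta-binomial around $f_l$ with
per-population concentration $\theta_j$ (larger $\theta$ means closer to
binomial sampling). The quantity of scientific interest is the ratio
$\alpha_E/\alpha_D$ per era: how strongly landscape resistance structures
allele frequencies relative to plain geographic distance.

## Priors and identifiability

On SD-standardized predictors, effect sizes are order-one quantities. The
effect sizes $\alpha_D$ and $\alpha_{E_k}$ therefore carry standard
exponential priors (mean 1), and $\alpha_0$ and the dispersions carry
bounded log-uniform priors (support $e^{\pm 15}$). The exponential choice
is substantive, not cosmetic: under a scale-free log-uniform prior on the
effect sizes, nearly all prior mass lies in the degenerate region where
some single effect is large enough to annihilate every off-diagonal
covariance entry (the "no-covariance plateau"); at realistic locus counts
the likelihood cannot overcome that volume, and inference is unstable.
The shape exponent $\alpha_2$ is fixed at 1 by default and can be sampled
(support $(0, 2]$) by configuration. When a resistance matrix is nearly
collinear with distance ($|r| > 0.99$ over pairs), the ratio is not
identifiable and the model warns.

## Sampling scheme

`run_chain()` is a Metropolis-within-Gibbs sampler (compiled core) with
the following update mix per step:

* single-site random walks on each log hyperparameter, using the identity
  $\sum_l d_l' (s_l \Omega)^{-1} d_l = \mathrm{tr}(\Omega^{-1} S)$ with
  $S = \sum_l d_l d_l'/s_l$, so a hyperparameter proposal costs
  $O(K^2)$ regardless of the number of loci;
* locus-wise joint latent updates: independence proposals from the
  Gaussian approximation to the latent full conditional (multivariate
  normal prior combined with a Gaussian expansion of the beta-binomial
  around the observed frequency), accepted with an exact
  Metropolis-Hastings correction. These dominate latent mixing; a few
  single-site random-walk refinements are kept alongside;
* an interweaving move (sufficiency parameterization): a covariance
  parameter is proposed while the *whitened* latent field
  $z_l = L_c^{-1} d_l / \sqrt{s_l}$ is held fixed, so the latent field
  deforms coherently with the proposed covariance; its acceptance ratio
  reduces to the beta-binomial difference. The proposal is a mixture of a
  local random walk and a uniform independence draw over the prior
  support, which lets chains hop between posterior basins instead of
  sticking in whichever one they first reach;
* random-scan updates of the per-population dispersions and
  independence-proposal updates of the ancestral frequencies $\mu_l$
  (beta proposals centered on the pooled empirical frequency).

Truncation of the latent field to $[0,1]^K$ is enforced by rejecting
proposals outside the box. The dependence of the truncation normalizing
constant on the hyperparameters is neglected in hyperparameter updates;
with typical frequencies away from the boundary this constant is very
close to 1, and the approximation is shared by the standard
implementations of this model family.

Each chain starts with a latent warm-up (50 joint-update sweeps over all
loci at the initial hyperparameters) so the covariance parameters see a
coherent latent field from the first step rather than raw sampling noise.
Proposal scales adapt toward a 20–70% acceptance band during an initial
discarded tuning window (first 20% of the chain, adaptation capped at 2.5
log units), then freeze; acceptance rates outside the band after tuning
are warned about, not fatal. Chains are bit-reproducible given the
configuration seed and chain id.

## Estimates and summaries

The per-chain estimate of $\alpha_E/\alpha_D$ is the posterior *median* of
the sampled ratio over the retained window (the second half of the stored
trace). The median, not the mean, is the per-chain location estimate
because the sampled ratio is heavy-tailed — occasional excursions toward
the prior bounds would otherwise dominate a within-chain mean.
`effect_summary()` then reports the mean and standard error of the
per-chain estimates across chains (the familiar table shape), with Tukey
HSD letters from a one-way ANOVA across chains computed on the *log* of
the per-chain ratios — the natural scale for a ratio-valued quantity and
the variance-stabilizing one. Convergence is assessed with
`gelman_rubin()`, the potential scale reduction factor
$\sqrt{((n-1)/n\,W + B/n)/W}$ with its upper 95% bound.

Desk-scale defaults are 4 chains of 50,000 steps (thinning 10); the
original analyses of this kind run 30 chains of several million steps, and
those scales are plain configuration changes.

# Supporting statistics

* **Pairwise FST** is the two-deme Weir–Cockerham moment estimator with
  sample-size correction, combined across loci as a ratio of averages
  (`sum(a) / sum(a+b+c)`); it can be slightly negative near zero
  differentiation. The test suite validates it to `1e-10` against an
  independently coded nested-ANOVA implementation.
* **Nucleotide diversity** is the unbiased per-locus mean pairwise
  difference `2p(1-p)·2n/(2n-1)` averaged over a caller-supplied
  `total_sites` that includes monomorphic sites — the count of genotyped
  sites is data the pipeline cannot reconstruct from a SNP matrix alone,
  so it is a configuration input.
* **Observed heterozygosity** is the fraction of heterozygous calls per
  locus averaged over the same denominator.
* **Folded SFS** is the histogram of per-locus minor-allele counts,
  requiring a uniform allele number across loci (impute first).
* **Filters**: minor-allele-frequency (pooled across populations,
  boundary retained) and per-locus missingness (boundary retained).
  Missing genotypes are imputed by the modal genotype within the
  individual's population (ties toward the smaller code); this
  deterministic single-marker rule replaces haplotype-clustering
  imputation, for which no linkage model is reconstructible at this
  package's scope.
* **Regressions**: FST is regressed on standardized distance, then the
  residuals on standardized resistance — plain OLS over vectorized upper
  triangles, exactly as in the source analyses even though pairwise
  entries are not independent; a Mantel-style permutation p-value is
  available behind `permutations =` and off by default. "Average
  nucleotide diversity between sites" is read as the mean of the two
  site values.

# The synthetic-data generator

`simulation_spec()` defines a rectangular county grid (axis-aligned so
transect segment lengths have closed forms and the resistance code can be
checked against exact oracles), per-era cover models (uniform, gradient
along either grid axis, or a rectangular patch), sites placed in the
interiors of distinct counties, and the generative model above: ancestral
frequencies uniform on $[0.05, 0.95]$, truncated-normal latent
frequencies (rejection with a cap of 100 tries, then logged clipping),
beta-binomial genotypes, and missing calls injected completely at random.

Defaults mirror the sampling design the pipeline targets: 8 populations
of 12 diploid individuals, counties 30 km across, thousands of loci
(fixtures use 500), true $\alpha_0 = 20$ (latent frequency spread of
roughly 0.1, i.e. modest FST), dispersion $\theta = 100$ (mild
overdispersion), 2% missing calls. Three canned scenarios are exposed by
`simulate_scenario()`/`make_fixture()`: `null` (no landscape effect),
`ibr_strong` (one era, true $\alpha_E/\alpha_D = 10$), and `era_contrast`
(three eras with cover maps varying along different grid axes; genotypes
respond to the third era's resistance only). The era-contrast cover maps
are deliberately low-correlation across eras — with strongly correlated
resistance matrices the per-era attribution is unidentifiable, which is
precisely the situation the all-era model exists to diagnose.

What the generator does *not* emulate: linkage between loci, selection,
spatially explicit dispersal, unequal sample sizes, or real county
geometries (multi-part and non-convex polygons appear in tests but not in
generated landscapes). Passing tests therefore demonstrate correctness of
the estimators and the inference machinery under the model's own
assumptions, not robustness to violations of them.

# Numerical choices and limitations

* Intersection areas: exact Sutherland–Hodgman clipping requires one
  convex polygon; non-convex/non-convex pairs fall back to a logged
  400×400 grid estimate. Self-intersecting rings are retained with a
  warning and handled by the grid path.
* The covariance matrix receives a diagonal jitter (logged) when its
  smallest eigenvalue falls below `1e-10`; non-positive-definite
  proposals are rejected.
* Posterior multimodality is real at small locus counts: a structured
  basin and a no-covariance plateau coexist. The exponential effect-size
  priors, the interweaving mode-hopping move and the warm-up together
  make desk-scale inference reproducible, but single chains can still
  linger in the wrong basin — always run several chains and check
  `gelman_rubin()`.
* Problem sizes in the shipped tests (500 loci, 8 populations, 4–10
  chains of 50k–100k steps; 20 recovery replicates) were chosen as the
  smallest sizes at which the recovery properties hold comfortably.
* The pairwise regressions inherit the non-independence of pairwise
  data; interpret their p-values accordingly or enable permutations.
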