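---
title: "Methods: population structure, diversity and LD for dominant marker panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population structure, diversity and LD for dominant marker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dartpop)
```

# Scope and data model

dartpop analyses panels of *dominant* biallelic markers — DArT-style
band presence/absence scores — from collections of selfing crop
varieties. Because such varieties are effectively homozygous, each
genotype carries a single band state per marker and the data reduce to
a genotypes × markers matrix over {present, absent, missing}. This
haploid scoring assumption runs through every method in the package and
is the main modelling decision: the admixture likelihood, r²
computation, gene diversity and PIC all treat a genotype's call as one
allele draw rather than a dominant mask over two. For outcrossing or
heterozygous material the package's estimators would be biased and a
diploid dominance model would be needed; that mode is deliberately out
of scope.

The central container is `DartPanel`, a `SummarizedExperiment` with
markers as rows, a single integer assay `calls` (1/0/`NA`), genetic-map
annotation (`chrom`, `pos` in centiMorgans) in `rowData`, and group
labels in `colData`. All analysis functions accept a `DartPanel` and
operate on the genotypes × markers orientation returned by
`markerCalls()`.

# The admixture model and K selection

`runAdmixture()` fits the Bayesian admixture model by Gibbs sampling.
For genotype $i$ and marker $l$ with band state $x_{il}$:

$$z_{il} \mid q_i \sim \mathrm{Categorical}(q_i), \qquad
  x_{il} \mid z_{il}=k \sim \mathrm{Bernoulli}(p_{kl}),$$

with conjugate priors $p_{kl} \sim \mathrm{Beta}(1,1)$ (independent
frequencies across populations) and
$q_i \sim \mathrm{Dirichlet}(\alpha,\dots,\alpha)$. The concentration
$\alpha$ has a uniform prior on $(0, 10]$ and is updated by a
Metropolis random walk (normal proposal, sd 0.25, reflected at zero,
initial value 1). Missing calls contribute no likelihood and are
skipped in the $z$ updates. Every 10th post-burn-in iteration is
recorded (thinning keeps traces small; all estimators are defined on
recorded samples).

The model evidence is estimated as
$\ln \Pr(X \mid K) \approx m - v/2$, where $m$ and $v$ are the mean and
variance of the recorded data log-likelihoods — the usual harmonic
approximation reported by admixture software as the log probability of
the data. The recorded log-likelihood is the *mixture* likelihood
$\sum_{il} \log \sum_k q_{ik} \Pr(x_{il} \mid p_{kl})$ with the latent
origins integrated out. This matters: the log-likelihood conditional on
the sampled $z$ has a within-chain variance an order of magnitude
larger (the $z$ field is resampled each sweep), which inflates $v$ for
every $K \ge 2$ and systematically drives the $m - v/2$ estimate toward
$K = 1$. With the mixture form, replicate chains at the same $K$ agree
to within tens of log units and the evidence curve is interpretable.

`selectKEvanno()` chooses $K$ by the second-order rate of change of the
evidence over replicate runs:
$\Delta K = |L(K{+}1) - 2L(K) + L(K{-}1)| / \mathrm{sd}(L(K))$,
computed on replicate means, defined for interior $K$ only. A zero
replicate standard deviation leaves $\Delta K$ undefined for that $K$;
it is excluded from the argmax rather than treated as infinite.
`assignGroups()` takes the argmax membership, breaking exact ties
toward the lowest group index, and flags genotypes with maximum
membership below 0.6 as admixed — a reporting convention, not a
removal rule.

Because the admixture model assumes unlinked loci, `pruneByLd()`
reduces a mapped marker set greedily: markers are scanned in
(chromosome, position) order and kept only if their permutation r² test
against every already-kept marker on the same chromosome is
non-significant. The scan order is a declared convention; a different
order gives a slightly different (equally valid) set, so retained-set
sizes are reproducible only under a fixed order and seed.

# Distance, ordination and marker detection

`jaccardDistance()` implements the dominant-marker dissimilarity
$d = (M_{01} + M_{10}) / (M_{01} + M_{10} + M_{11})$ over markers where
both genotypes have calls; shared absences are ignored because a double
absence is uninformative for dominant markers. The matrix feeds
`runPcoa()` (classical scaling: double-centred $-\tfrac12 d^2$,
eigendecomposition, coordinates scaled by $\sqrt{\lambda}$). Jaccard
dissimilarities are non-Euclidean, so negative eigenvalues occur; they
are dropped from the explained-fraction denominator and reported in
`eigenvalues` for inspection.

`runPca()` runs PCA on centred, unscaled 0/1 columns (all markers share
the same scale, so variance scaling would only amplify
near-monomorphic noise), imputing missing calls by the marker band
frequency. `topLoadingMarkers()` ranks markers by absolute loading on
one axis (default the first, the group-separating axis) and returns the
top 5% by default. `markerGroupAssociation()` scores each marker's
2×2 presence-by-group table with a continuity-corrected chi-square
test, switching to Fisher's exact test when any expected cell is below
5, and reports Benjamini–Hochberg q-values alongside raw p-values —
with a thousand-plus markers tested, unadjusted significance would be
misleading.

Outlier flagging (`flagOutliers()`) marks genotypes whose distance from
the centroid of the first two axes exceeds 4 × the radial spread
$\sqrt{\mathrm{sd}_1^2 + \mathrm{sd}_2^2}$. The spread is deliberately
*not* a median-based robust scale: on a structured panel the median
spread reflects the majority cluster alone, and a robust rule flags an
entire minority subpopulation as "outliers" (verified on simulated
two-group panels, where a median rule removed the whole smaller group).
The sd-based spread absorbs between-cluster separation, so ordinary
structure is tolerated while a genuinely aberrant genotype — e.g. a
failed assay lying far outside both clusters — is still caught. At
$k = 4$ a homogeneous Gaussian cloud of 92 genotypes yields no flags in
well over 95% of panels.

# Diversity and AMOVA

Gene diversity per marker is $h = 2f(1-f)$ with $f$ the band frequency
among non-missing calls; `geneDiversity()` reports the mean over the
analysis markers, pooled and per group. No small-sample $n/(n-1)$
correction is applied; the estimator is the plain gene-diversity form
appropriate when comparing groups of similar size.

`amova()` partitions squared Euclidean distances between 0/1 profiles
(the standard treatment of binary data in distance AMOVA). Missing
cells are handled pairwise: each pair's mismatch count is rescaled by
(total markers / comparable markers). With $N$ genotypes in $G$ groups:

$$SS_{tot} = \tfrac1N \sum_{i<j} d^2_{ij}, \quad
  SS_{w} = \sum_g \tfrac1{n_g} \sum_{i<j \in g} d^2_{ij}, \quad
  \sigma^2_w = \frac{SS_w}{N-G}, \quad
  \sigma^2_a = \frac{SS_a/(G-1) - \sigma^2_w}{n_0},$$

with $n_0 = (N - \sum_g n_g^2/N)/(G-1)$, and
$\Phi_{PT} = \sigma^2_a / (\sigma^2_a + \sigma^2_w)$. Significance
comes from permuting genotype labels among groups with the
add-one correction $p = (1 + \#\{\Phi^* \ge \Phi\})/(1 + n_{perm})$,
so $p$ is never exactly zero and the default 999 permutations resolve
$p = 0.001$. A negative $\sigma^2_a$ is reported as estimated together
with a clamped-at-zero $\Phi$ (`phiPtClamped`); clamping silently would
hide information useful for diagnostics. On Balding–Nichols panels
$\Phi_{PT}$ is an essentially unbiased estimate of the generating
$F_{ST}$, which the test suite verifies at $F_{ST} \in \{0.05, 0.13,
0.25\}$.

# LD decay

`pairR2()` computes, for every same-chromosome pair of mapped markers,
the squared Pearson correlation of the two call vectors over genotypes
non-missing at both — under haploid scoring this equals the
haplotype-count statistic $D^2/(p_A p_a p_B p_b)$, an identity the
tests assert to $10^{-12}$. Comparison-wise significance uses
permutations of one marker's complete-case calls with the same add-one
correction. Pairs more than 50 cM apart are labelled unlinked (a pair
at exactly 50 cM is linked); `backgroundLd()` takes the 95th percentile
of unlinked r² using linear interpolation between order statistics
(quantile type 7 — "95th percentile" has several conventions and this
one is documented and tested).

`fitDecay()` fits a locally weighted quadratic (degree-2, tricube
weights) regression of significant-pair r² on distance, evaluates it on
a 0.5 cM grid from zero to the largest significant-pair distance, and
reports the first grid point where the curve falls to or below the
background — a grid intercept rather than root finding, because the
loess curve is defined pointwise. When the curve never reaches
background the result records "no intercept" and the curve's terminal
extent; this is a real outcome (it occurs for subgroups with extensive
LD), not an error. The loess span defaults to 0.5 and is recorded in
the result; the degree is fixed at 2.

# The synthetic generator

`simulatePanel()` draws panels under the Balding–Nichols $F$-model:
marker ancestral frequencies $p \sim U(0.05, 0.95)$, group frequencies
$p_g \sim \mathrm{Beta}$ with mean $p$ and variance $p(1-p)F_{ST}$, and
genotype bands as single Bernoulli draws (haploid scoring). This is the
standard generative counterpart of the admixture prior, chosen because
the target analyses summarize differentiation by a single fixation
index. Defaults encode the study conditions the package is calibrated
against: 92 genotypes in groups of 26 and 66, about 1,400 markers on
the 21 wheat chromosomes with the B > A > D genome asymmetry (96/66/38
markers per chromosome of each genome), 160 cM chromosomes with a 67 cM
marker desert on 4D, $F_{ST} = 0.13$, 3% missing calls, and one
strongly differentiated block on 2D (band frequencies 0.9 vs 0.1
between groups over 15–35 cM) mimicking a selected dwarfing-locus
region. Truth labels and truth frequencies travel with the panel so
recovery can be scored.

`simulateLdBlock()` generates distance-dependent LD: each chromosome is
a stationary symmetric two-state Markov walk along the map, so the
implied correlation between markers $d$ cM apart is
$\rho^2(d) = e^{-cd}$, with $c$ calibrated from a target r² at a
reference distance. This is a testing device for the decay estimator —
it makes no claim about real haplotype structure (no recombination
hotspots, no allele-frequency spectrum, marginal frequencies pinned at
½). `ldDecayTarget()` returns the distance where the implied curve
crosses a given background, the ground truth for recovery experiments.

What passing tests on these panels shows — and what it does not: the
estimators recover the parameters of data generated under their own
assumptions (exchangeable genotypes, unlinked or Markov-linked loci, a
single differentiation scale). Real panels add genotyping error beyond
missingness, related genotypes, clustered markers and selection at many
loci; performance there depends on how far those features stray from
the model, and no simulation result here certifies it.

# Numerical and testing choices

* All stochastic functions take explicit integer seeds; pipeline stages
  derive their seeds from one master seed, so a run is reproducible
  byte-for-byte, including written tables.
* Recovery experiments in the test suite run at the default panel scale
  (92 × 1,400, 20 seeds for Φ recovery, 10 pipeline replicates for ΔK)
  with shortened chains of 2,000 burn-in + 2,000 sampling iterations,
  which replicate-agreement checks show is enough for this panel size;
  decay recovery uses 150 genotypes × 240 markers on three 150 cM
  chromosomes, where the significance-selection bias of the published
  decay-estimation recipe (fitting only significant pairs) is small
  relative to the ±30% recovery band.
* Degenerate inputs are contracts, not crashes: markers with all calls
  missing are flagged unassessable; genotype pairs with no comparable
  informative markers give `NA` distances with a warning; chromosomes
  with fewer than two markers contribute no gaps; a singleton group is
  an error for AMOVA.
* `K = 1` is a valid admixture fit (single-population Beta–Bernoulli),
  so the Evanno table always has its left endpoint.

# Limitations

Only one-level AMOVA is provided (the analyses partition at a single
grouping). The admixture sampler implements independent allele
frequencies — no correlated-frequencies or linkage model — and no
multi-run consensus beyond greedy column alignment. LD is
intra-chromosomal r² only; D′ and haplotype phasing are out of scope.
The marker-scale statistics (PIC, diversity) assume the homozygous,
haploid-scored setting throughout.
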