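---
title: "Methods: network models of macrophage activation spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network models of macrophage activation spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macnet)
```

# The scientific problem

Macrophages respond to their microenvironment with profound transcriptional
reprogramming. The classical description distinguishes two poles — M1
(classical, IFN-γ-driven) and M2 (alternative, IL-4-driven) activation — but
transcriptome panels spanning many stimulation conditions show a much richer
picture: a *spectrum* of activation programs, of which the M1/M2 axis is
only one dimension. `macnet` implements the analysis chain used to
establish and exploit such a spectrum view on bulk expression panels:

1. **Coregulation analysis (CRA)** — a sample–sample Pearson correlation
   graph, Markov clustering, and a 3D force-directed layout.
2. **Condition correlation matrix (CCM)** — condition-level Pearson
   correlations over the most variable genes, hierarchically clustered into
   activation clusters.
3. **Spectrum vectors** — per-cluster mean displacement of sample
   coordinates from the baseline-macrophage centroid; the baseline is the
   origin by construction, and pairwise angles quantify how far the
   activation landscape departs from a single bipolar axis.
4. **SOM portraits and exclusive markers** — self-organizing-map clustering
   of per-condition expression portraits, and selection of genes elevated
   in exactly one condition.
5. **Weighted coexpression modules** — soft-thresholded correlation
   networks, topological overlap, module detection, module eigengenes, and
   eigengene-to-condition correlation.
6. **Modules-as-gene-sets GSEA** — the detected modules become gene sets
   for enrichment analysis of any contrast, with NES/p volcano summaries.
7. **Mutual-information reverse engineering** — all-vs-all MI with a
   permutation-calibrated significance threshold, data-processing-inequality
   pruning, hub extraction, and first-neighbor networks of the most
   expressed hub transcription factors.

Every stage is exercised end-to-end on a bundled synthetic-data generator
with planted ground truth, so each method's recovery behavior is testable
without any external download.

# The synthetic-data generator

`simulate_expression()` draws log2 intensities
$x_{gs} = \mu_g + \sum_c e_{m(g),c}\,\mathbb{1}[\text{cond}(s) = c] + \varepsilon_{gs}$,
with $\mu_g \sim N(\mu_0, \sigma_g^2)$ a per-gene baseline level,
$e_{m,c}$ the signed log2 effect of condition $c$ on module $m$, and
$\varepsilon \sim N(0, \sigma^2)$ i.i.d. noise. Defaults: $\mu_0 = 8$,
$\sigma_g = 2$, $\sigma = 0.5$ — the scale of log2 microarray intensities,
where between-gene level differences dominate within-gene noise. The
between-gene spread is what makes any two samples of the same tissue
correlate strongly (r ≈ 0.9), as real transcriptomes do; without it the
sample correlation graph would be empty at realistic thresholds.

Because module genes share the binary condition indicator with unit
loading, the within-module gene–gene correlation has the closed form
$r = e^2 v / (e^2 v + \sigma^2)$, with $v$ the variance of the indicator
across samples. This is the oracle the generator tests assert against. With
the default six conditions × 10 replicates and effect/noise = 4, planted
modules sit at $r \approx 0.69$ — strong but far from degenerate.

Signed per-condition effects let one module encode *antagonistic* programs
(e.g. +2 under an M1-like stimulus, −2 under an M2-like one). This is how
the generator emulates the bipolar-axis geometry that the spectrum stage
must reproduce, and it is the reason effects are signed rather than a
single scalar per module.

`simulate_hub_network_data()` draws from a Gaussian graphical model whose
precision matrix encodes a sparse graph with designated hubs. Off-diagonal
entries are $\pm 0.9 / \max(d_i, d_j)$ with diagonal
$1.02 \sum_j |\omega_{ij}|$ — forced diagonal dominance, hence a valid
covariance. Hub degree defaults to 5: diagonal dominance caps the sum of a
node's incident partial correlations below one, so very high hub degrees
would make every individual edge marginally undetectable at any realistic
sample size. That is a property of the model class, not of the estimator,
and the default is chosen so each true edge carries a marginal correlation
of roughly 0.15–0.3 at the bundled scale (50 genes, 1,000 samples).

**What the generator does not emulate:** platform/batch structure, probe
effects, count noise, donor covariance, correlated background genes, or
heavy-tailed intensity distributions. Passing tests therefore demonstrate
correctness of the algorithms and their calibration under the stated noise
model — not performance on any specific real microarray panel.

# Stage-by-stage notes and parameter choices

## Preprocessing

* **Quantile normalization** maps every column onto the row-mean of the
  sorted columns; ties break by first occurrence, which makes the transform
  exactly idempotent. (Tie handling is also why the implementation is local
  rather than delegated: the tie-averaging variants are not idempotent. On
  tie-free input it agrees with `limma::normalizeQuantiles` to 1e-12, which
  the tests verify.)
* **Detection filter**: bead-level background controls are not available to
  a reanalysis, so background is defined empirically as the 0.25 quantile
  of all values, and a gene counts as present in a condition when its
  condition mean exceeds background by 0.5 log2 units. Both knobs are
  config-exposed; raising the margin can only shrink the expressed set
  (monotonicity is tested).
* **Differential screens**: per-gene Welch t for two-group contrasts (fold
  change is always the difference of log2 means, exponentiated — never a
  ratio of raw means) and a classic equal-variance one-way F across all
  conditions, both BH-corrected. Constant genes get p = 1 with a flag, not
  NaN. The F test was chosen over resampling ANOVA for determinism; on
  simulated Gaussian noise its raw p < 0.05 rate is exact (tested against
  the binomial band over 10,000 null genes).

## Coregulation analysis

The sample graph connects profiles with Pearson r ≥ 0.85 (the threshold is
not printed in the source literature; 0.85 keeps replicate groups connected
at the bundled noise level and is config-exposed). Markov clustering uses
the canonical expansion/inflation iteration with self-loops, inflation 2,
and a 1e-8 convergence tolerance; attractor rows define clusters, so the
procedure is deterministic.

The 3D layout is standard Fruchterman–Reingold with the attraction of each
edge scaled by its correlation, linear cooling, 500 iterations, and natural
spring length $k = n^{-1/3}$ (a two-body system equilibrates at distance
$k w^{-1/3}$ — the layout oracle in the tests). Positions initialize from
classical MDS of the 1 − r distance with seeded jitter: on densely
connected sample graphs random starts occasionally trap the refinement in
local minima that fold one activation program onto another, while the MDS
start preserves the global geometry that the spectrum stage measures.
Random initialization remains the fallback when no correlation matrix is
attached. Everything is deterministic given the seed.

## Condition space and spectrum vectors

Condition profiles are replicate means over the 1,000 most variable genes
(the bundled scenario uses fewer genes, so the cap adapts); the CCM is
their Pearson matrix, clustered by average linkage on 1 − r and cut to k
clusters (k = 10 by default, matching the activation-cluster count of the
motivating analysis; cut by count, not height). The z-scored display copy
is clipped at ±2.78 and never used numerically.

Spectrum vectors are cluster centroids of sample coordinates minus the
baseline-condition centroid. The baseline cluster is pinned to the exact
origin: the anchor is defined by the baseline condition's samples, and any
conditions co-clustered with baseline are reported in a note rather than
allowed to move the origin. Rigid translations of the layout cancel in the
subtraction (tested to 1e-10). Pairwise angles come from unit-vector dot
products; zero vectors are excluded.

On generator scenarios with two antagonistic programs the two non-baseline
vectors separate by far more than 90°, and an additional orthogonal
program yields a vector more than 30° from both — the geometry that
distinguishes a spectrum from a single axis, at the level a synthetic
scenario can establish it.

## SOM portraits and markers

The batch SOM trains on per-gene z-scored condition profiles (shape, not
level, drives clustering) over a 10×10 grid for 50 epochs — the grid and
epoch count are free choices documented here, as the motivating analysis
does not state its own. The Gaussian neighborhood shrinks linearly from
max(w, h)/2 to 0.5 and is truncated at the radius, so the final epochs
update only each best-matching unit: a pure quantization refinement that
cannot worsen the fit on a fixed assignment. Codebooks initialize on the
plane of the first two (sign-normalized) principal components, making
training deterministic without randomness. Unit meta-clusters come from
average-linkage clustering of codebooks.

Marker calling is deliberately margin-based rather than SOM-based: a gene
is an exclusive marker of a condition when its mean there exceeds every
other condition's mean by ≥ 1 log2 unit. This operationalizes "selectively
elevated in only one condition", is anti-symmetric by construction (a gene
can be a marker of at most one condition), and agrees with the SOM
meta-clusters on the planted fixtures. A gene induced equally by two
related stimuli is excluded from both tables.

## Coexpression modules

Unsigned adjacency $|r|^\beta$; the power is the smallest candidate whose
signed scale-free fit reaches R² = 0.85. When no candidate reaches it —
typical for strongly modular data, where the fit index *increases
monotonically* with power while the network degenerates toward a few
isolated cliques — the fallback is the standard sample-size default for
unsigned networks (9 below 20 samples, 8 below 30, 7 below 40, 6
otherwise). An argmax fallback was rejected: on the planted six-module
fixture it selects the largest candidate power and module recovery
collapses (ARI 0 at power 20 versus 1.0 at power 6).

The topological overlap matrix follows the usual normalized
shared-neighbor form, verified entry-for-entry against a brute-force triple
loop. Modules come from average-linkage clustering of 1 − TOM with a
static cut at 0.995 — TOM dissimilarities concentrate near 1, so
meaningful cuts sit close to the top of the tree; 0.995 recovers planted
modules across the tested power range (4–8) on the fixture family.
Branches below 20 genes go to the unassigned module 0, and modules whose
eigengenes correlate above 0.8 merge iteratively to a fixpoint. A static
cut plus eigengene merging replaces dynamic tree cutting — a documented
divergence chosen for implementation transparency; the merging step
compensates for the static cut's tendency to split large modules.

The module eigengene is the first right singular vector of the
gene-standardized submatrix, unit norm, signed to correlate positively with
the module's mean standardized profile; an exactly anti-correlated pair
makes that tie undecidable and is flagged, with the tie broken toward the
first gene. Module–trait association is the Pearson correlation of each
eigengene with each condition's one-hot indicator, Student-t p, BH over the
whole module × condition grid (the correction scope is a package choice;
the source analysis does not state its own).

Note one deliberate semantic: with *unsigned* adjacency, two antagonistic
programs driving the same axis in opposite directions form a single
bipolar module — that is the correct unsigned-network reading of the
bundled M1-like/M2-like pair, not a detection failure.

## GSEA with modules as gene sets

The running sum weights hits by $|s|^p$ (default p = 1, classic GSEA) and
penalizes misses uniformly. The ranking metric is signal-to-noise with each
group standard deviation floored at max(0.2·|mean|, 0.2). Phenotype
permutation is the default; below 7 samples the procedure falls back to
gene-set permutation with a warning, unless phenotype mode is forced for
exhaustive enumeration on tiny balanced designs (when the requested
permutations exceed the number of distinct label assignments, all of them
are enumerated and the flag is recorded). NES divides ES by the mean
|permuted ES| of matching sign; the nominal p is the plain fraction of
same-sign permuted scores at least as extreme; FDR q follows the GSEA
normalized-tail convention rather than BH. All of this is pinned by tests
to a brute-force running-sum oracle, to exhaustive 3v3 enumeration, and to
`fgsea::calcGseaStat` on shared rankings.

Calibration checks use 400 permutations per contrast: with ~50 effective
same-sign permutations the discrete null of the p-value makes
P(p < 0.05) ≈ 0.059 even for a perfect test, which is an artifact of
granularity, not miscalibration; 400 permutations bring the discrete
expectation back to ~0.050.

Over-representation analysis (the stand-in for GO enrichment against a
user-supplied term → gene map) is the upper-tail hypergeometric test with
BH, verified against exact subset enumeration on small universes.

## MI network inference

The default estimator is Gaussian-copula MI: rank-transform both profiles
to normal scores and apply the closed form $-\tfrac12\ln(1-r^2)$. It is
exactly symmetric, rank-invariant, fast enough for all-vs-all use, and has
a clean oracle (at ρ = 0.6 the truth is 0.2231 nats; the estimator's
median error across seeds is well under 5%). A discretized estimator with
Miller–Madow bias correction (bins ∝ n^{1/3}) is available for fidelity to
histogram-based reverse-engineering tools.

The edge threshold comes from a permutation null: MI of randomly permuted
profile pairs, with the Bonferroni-corrected target quantile
(α / C(genes, 2)) reached by an exponential fit to the null tail above its
99th percentile when it lies beyond permutation resolution — brute-force
permutation cannot reach 1e-7-scale quantiles at desk scale, and null MI
tails are approximately exponential. The corrected-α interpretation of the
threshold, the tail-fit parameters, and whether extrapolation occurred are
all recorded on the result. The workflow default is α = 1e-7
(Bonferroni-corrected), the value the motivating analysis used on its
9,498-gene panel; the bundled 50-gene network fixture uses α = 0.05, the
appropriate family-wise level for ~1,200 pairs.

DPI pruning removes, within every fully connected triplet, the weakest
edge when it falls below (1 − tolerance) times the smaller of the other
two, computing all removals against the unpruned network and applying them
simultaneously (tolerance 0.1, common reverse-engineering practice).
Verified against brute-force triplet enumeration on random 20-node graphs.

Hubs are the top 10% of *connected* nodes by degree (the denominator is a
documented choice — connected nodes, not all genes), ties broken
lexicographically, with the hubs' total incident interactions reported.
TF neighborhoods intersect a user-supplied TF list with the hubs, rank by
average expression, keep the top 5, and annotate first neighbors with
per-condition-cluster mean expression.

# Problem sizes and numerical choices

The bundled analyses run at deliberately desk-friendly sizes: the
demonstration panel is 200 genes × 60 samples (six conditions × ten
replicates), module-recovery studies use 300 genes × 60 samples across 20
simulation seeds, the network-recovery fixture is 50 genes × 1,000
samples, and GSEA exactness uses a 3v3 design whose 20 phenotype
relabelings are enumerated exhaustively. Degenerate inputs are contracts,
not crashes: constant genes flag `degenerate`, zero-variance samples are
dropped with a warning and listed, empty graphs cluster to an empty
labeling, and a gene set covering the whole ranked list is rejected
(its miss mass is undefined). Ties everywhere break lexicographically or
by first occurrence so that every stage is reproducible bit-for-bit under
a fixed seed.

# Known limitations

* The synthetic generator's independence assumptions (background genes
  i.i.d., noise homoscedastic) make recovery easier than on real arrays;
  recovery rates reported by the tests are upper bounds in that sense.
* Gene-set permutation p-values are known to be anti-conservative relative
  to phenotype permutation on correlated gene sets; the automatic fallback
  below 7 samples trades that bias for feasibility and is flagged.
* The spectrum construction is descriptive geometry — no significance test
  is attached to vector separations, mirroring its role as a visualization
  model.
* MCL on near-complete, near-uniform graphs can return a single cluster;
  the CCM/cut-based clustering is the robust path for condition grouping.
* Desk-scale guards: the all-vs-all MI stage rejects > 20,000 genes unless
  forced; none of the implementations use blockwise or sparse-matrix
  strategies.
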