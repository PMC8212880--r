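---
title: "Methods: network-based target discovery from vascular proteomics"
author: "graftnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based target discovery from vascular proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftnet)
```

## The problem

A vein implanted into the arterial circulation — a bypass graft or the
venous limb of an arteriovenous fistula — remodels maladaptively: the wall
thickens, macrophages accumulate, and a substantial fraction of grafts fail
within the first year. `graftnet` operationalizes a proteomics-driven
discovery loop for this setting: measure the graft-wall proteome statically
(tissue layers vs control vein) and kinetically (a time course across
lesion development), reduce it to condition- and phase-specific protein
sets, embed those sets in pathway and interactome space, and rank candidate
target proteins by network topology. A final network-medicine step asks
whether the proteomic modules sit close to disease gene modules on the
interactome.

This vignette records the models, the tunable parameters, the synthetic
data used for validation, and the design decisions taken where the
methodology left genuine choices open.

## Static stage: normalization, ANOVA filter, bipartition

Label-free protein quantities (area-under-curve scale, strictly positive,
spanning orders of magnitude) are median-centered per sample: each sample
is rescaled so that its median observed abundance equals the global median
of per-sample medians. This corrects loading differences, preserves
within-sample ranks, and leaves missing values missing — a missing
abundance is a distinct state from an observed zero throughout the package,
because in label-free MS a zero AUC and an unobserved protein mean
different things.

All tests run on the log2 scale (the field norm for AUC abundances; an
observed zero cannot be log-transformed and is demoted to missing with a
warning). The multigroup filter is a per-protein one-way fixed-effects
F-test across sample conditions, computed vectorized over the matrix and
cross-checked in the tests against `stats::oneway.test`. Proteins constant
across all samples, or lacking two groups with two observed values, are
dropped or skipped with warnings rather than silently. q-values come from
the Benjamini–Hochberg step-up rule (`stats::p.adjust`), and the filter
retains q ≤ `fdr_static` (default **0.05**).

The retained proteins are z-scored per protein and bipartitioned by
agglomerative clustering (Ward linkage, Euclidean distance, cut at k = 2).
The linkage is a choice — published heatmaps of this design show a
two-block dendrogram without naming the algorithm — and Ward/Euclidean is
the standard default for expression heatmaps. Orientation is automatic:
`cluster1` is the cluster with the higher mean z over control
(`control_condition`, default `"IVC"`) samples, i.e. the
control-predominant set; `cluster2` is the lesion-predominant complement.

Two-group comparisons use the Welch t-test by default; it reduces to the
pooled test under equal variances (the tests assert F = t² on two-group
designs) and is the safer default for small vascular-tissue designs.

## Kinetic stage: fractional profiles and mixture clustering

The time course (defaults: 4 timepoints D1/D3/W2/W4, 3 biological
replicates, two conditions — graft `VG` and control vein `IVC`) is reduced
to one profile per protein per condition: replicates are averaged per
timepoint, then the trajectory is fractionally normalized, xₜ/Σxₜ. The
fractional profile lives on the simplex, is scale-invariant, and captures
*when* a protein is abundant rather than *how much* — which is what makes
pooling graft and control profiles into a single clustering step
meaningful. All-zero trajectories carry no shape and are excluded with a
warning.

Pooled profiles are clustered with a K-component mixture of T-variate
Gaussians with diagonal covariance, fitted by EM:

- initialization is seeded k-means++; the best of `restarts` (default 5;
  the pipeline uses 3) runs by log-likelihood wins;
- the E-step/M-step loop enforces a variance floor of 1e-6 per dimension,
  which keeps noiseless (zero-variance) clusters proper and handles the
  one-dimensional degeneracy of simplex data without a full-covariance
  model — at T = 4 a diagonal model is also far more stable than a full
  one;
- clusters that empty out are re-seeded at the worst-fit profile;
- the log-likelihood trace is retained and is asserted non-decreasing
  (outside re-seeding events) in the tests;
- hard assignments take the maximum responsibility.

K defaults to **30**, a cluster count typical for 4-point vein-graft trend
analyses; it is fully configurable, and since the analysis fixes its
cluster count a priori no model selection is run by default.

Clusters are then labelled by centroid shape: **flat** when the centroid
range (max − min fraction) is below `flat_range` (default **0.10**; a
perfectly uniform 4-point profile sits at 0.25 per timepoint, so 0.10 is a
40% relative excursion), otherwise **early** when the centroid peaks in
`early_timepoints` (default the first half: D1, D3) and **late** when it
peaks in the second half (W2, W4). The flat threshold formalizes what is
otherwise a visual call on trend plots. Finally `condition_filter` keeps,
per non-flat phase, only the proteins whose *graft* profile sits in a
cluster of that phase: control-vein profiles never contribute, and flat
clusters are omitted entirely, mirroring the removal of control-derived and
minimally changing trends from further analysis.

## Pathway networks and target prioritization

Each protein set (lesion-predominant, control-predominant, early, late) is
tested for overrepresentation against a GMT pathway collection with the
upper-tail hypergeometric distribution: population N = the measured
proteome (the universe is what was quantified, not the collection's gene
space), successes K = the pathway's members inside the universe, draws
n = the query set, observed overlap k, p = P(X ≥ k). BH correction runs
across all tested sets, and nodes enter the network at q ≤ `fdr_network`
(default **0.001**, the conventional gate for network-stage comparisons;
the standalone function defaults to 0.05).

Enriched pathways become nodes sized by their dataset-protein overlap;
an edge joins two pathways iff their overlap members intersect, weighted
by the shared-protein count (minimum 1 — no stricter edge gate is
applied). Centralities are computed on the unweighted topology, per
connected component, normalized to [0, 1]:

- betweenness: shortest-path pair fractions over (n−1)(n−2)/2,
- closeness: (n−1)/Σ distances within the component,
- degree: degree/(n−1).

The `top_k` (default **3**) top-ranked pathways are selected by
betweenness, with deterministic tie-breaks (closeness, then degree, then
lexicographic id) so rankings are reproducible.

Within each top pathway, the interactome subgraph induced on the pathway's
dataset proteins (no first-neighbor expansion — the most conservative
construction) is scored with the same three centralities, and the
consensus most-central protein is called by **Borda aggregation**: dense
ranks per centrality, winner = minimum rank sum. This formalizes as an
explicit, deterministic rule what is otherwise read off three pairwise
centrality scatter plots; it reproduces unanimity cases exactly (a protein
ranked first on all three scores 3), and residual exact ties are broken
lexicographically and flagged.

## Disease-module proximity

The proximity of two protein modules on the interactome uses the closest
distance d(A,B) = mean over a∈A of the minimum shortest-path hops to B;
shared members contribute 0. The statistic is directional, so the
significance and matrix stages use the symmetrized mean of both
directions. The separation score
s = ⟨d_AB⟩ − (⟨d_AA⟩+⟨d_BB⟩)/2 (within-set terms use each node's nearest
other member, so s = 0 when the modules coincide) is available via
`measure = "separation"`; closest distance is the default because it is the
measure most directly matching "network closeness" between a proteomic
module and a disease module.

Significance comes from degree-preserving randomization: nodes are sorted
by degree into contiguous bins of at least `min_bin_size` (default 25, or
5 for graphs under 500 nodes, so bins stay sampleable at typical module
sizes; bins close only at degree boundaries so equal-degree nodes are
never split), and in each of `n_rand` (default **1000**) draws *both*
modules are replaced by bin-matched random node sets of equal size,
sampled without replacement. The empirical p is pseudocounted,
p = (r+1)/(n_rand+1) with r the null draws at or below the observed
distance, so p is never exactly 0; z = (d_obs − mean)/sd of the null. On
small graphs hop distances are coarse, ties between the observed and null
distances are common, and the ≤-counting makes p slightly conservative
(sub-uniform) — a property to keep in mind when reading calibration
checks.

The association matrix runs every unordered module pair, BH-corrects the
empirical p-values as one family (self-pairs excluded), and flags pairs as
*blank* (p > 0.05, the display convention for such matrices) and
*significant* (q ≤ 0.05). Note the interaction between `n_rand` and the
family size: with m pairs the smallest attainable q is m/(n_rand+1), so
shallow randomizations cannot reach significance after correction — one
reason 1000 randomizations is the default.

The proteomic modules fed to this stage are the outputs of the two
upstream arms — the predominance clusters and the early/late phase sets —
plus any user-supplied disease modules (GMT).

## The synthetic study and what it does (not) show

The generators emulate the study design at desk scale with planted truth:

- `synth_kinetic_proteome` (defaults: **1357 proteins**, 4 timepoints, 3
  replicates, two conditions — the scale of a typical quantified label-free
  vein-graft proteome): per protein and condition a trend template is drawn
  uniformly from ten fractional templates (four early-peaking, four
  late-peaking, two flat), and replicate abundances are
  scale·max(0, template + N(0, noise_sd)) with a lognormal per-profile
  scale. `noise_sd` defaults to **0.03** on the fractional scale, at which
  planted labels remain recoverable (ARI ≥ 0.9) while clusters visibly
  overlap; at 0 the fractional profiles equal their templates exactly.
- `synth_static_proteome` (defaults: four groups IVC/NEO/ADV/WT × 3
  samples): log-normal abundances (log2 mean 20, sd 2), planted shifts of
  `effect_log2` (default **2**, a 4-fold change) in the lesion or control
  groups, residual log2 noise **0.25**.
- `synth_interactome`: preferential attachment with `attachment` edges per
  incoming node — connected, simple, exactly attachment·(n−attachment)
  edges, heavy-tailed degrees.
- `synth_pathways`: graph-neighborhood gene sets; at least three are
  anchored on a planted hub (the hub plus direct neighbors), so the hub
  sits on many inter-pathway shared-protein edges and dominates the
  induced subgraph of each of its pathways.
- `synth_modules`: module pairs at controlled proximity — overlapping
  (≥ 30% shared members by construction), neighboring (disjoint,
  adjacent seeds), random (independent uniform draws, the null's reference
  class).
- `synth_bundle` wires everything into one consistent namespace: the
  planted lesion signature is the hub's pathway family (its first-neighbor
  subnetwork) and a disjoint pathway family is planted as the control
  signature, so enrichment, the pathway network, target calls and the
  proximity matrix can all be scored against the plant. One synthetic
  disease module is grown around the hub (the analogue of an allied
  arterialized-vein disease module) and one is random.

What passing these checks shows: the statistics are implemented correctly
(exact oracles), calibrated (null simulations), and the pipeline recovers
planted structure at realistic noise. What it does not show: performance
on real label-free data with heavy-tailed noise, batch effects, missing-
not-at-random dropout, correlated replicates, or curated ontologies —
none of which the generators attempt to model. Parameter defaults are
calibration choices for the synthetic conditions, not claims about any
real dataset.

## Numerical and reproducibility choices

- Identifiers are uppercased at every boundary (mouse/human symbol mixing).
- TSV is the canonical dialect: unquoted, UTF-8, `\n`, rows sorted with a
  locale-independent byte order — identical results serialize
  byte-identically, and the tests assert it.
- Every stochastic function is a pure function of its arguments and an
  integer seed. The pipeline derives stage seeds from the global seed by a
  fixed affine map (`derive_seed`), so changing one stage's parameters
  never shifts another stage's random stream; proximity pairs likewise get
  per-pair derived seeds.
- Degenerate inputs fail loudly with classed conditions
  (`graftnet_format_error`, `graftnet_parameter_error`,
  `graftnet_data_error`, `graftnet_config_error`) rather than coercing;
  recoverable oddities (dropped constants, unreachable nodes, absent
  module members, self-loops) warn, and `run_pipeline` collects every
  warning into the manifest so that data-cleaning decisions are visible
  after the fact.
- The manifest also records the configuration, package version and
  per-file checksums; a stage failure persists partial outputs and a
  manifest naming the failed stage.

## Problem sizes used in validation

The shipped validation suite runs at sizes chosen to exercise each claim
meaningfully on a single core: enrichment against exhaustive enumeration on
universes up to 12; centralities against brute-force path counting on 100
random graphs of up to 8 nodes; FDR behavior over 200 simulations of a
1000-protein, 3×3-sample null; kinetic recovery on 500 proteins (1000
pooled profiles) at K = 10; null calibration over 500 module pairs at 200
randomizations on a 100-node graph; planted-module detection over 50
seeded trials; and end-to-end hub recovery over 10 full pipeline runs at
the default 1357-protein scale.

## Known limitations

- The ANOVA filter assumes approximate log-normality and homoscedastic
  groups; no moderated (empirical-Bayes) variance shrinkage is applied,
  which matters for very small designs on real data.
- The mixture model is diagonal-covariance on simplex data; correlations
  between timepoints within a cluster are not modelled.
- The Borda consensus is one formalization of a multi-centrality
  "consensus"; alternatives (e.g. requiring top rank on 2 of 3 measures)
  can disagree on non-unanimous cases.
- Proximity p-values are conservative on small or coarse graphs (discrete
  hop distances); z-scores are reported alongside for effect direction.
- The pipeline's pathway stage inherits whatever redundancy the supplied
  GMT collection carries; no ontology trimming is performed.
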