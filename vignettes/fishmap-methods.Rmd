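---
title: "Methods: from c-fos point clouds to a functional brain network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from c-fos point clouds to a functional brain network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishmap)
```

`fishmap` covers the computational stages of whole-brain c-fos activity
mapping in adult zebrafish: cleaning detected-cell point clouds,
classifying stain morphology, aggregating counts over an atlas,
time-course statistics, and inference of a functional brain network from
cross-animal count correlations. This vignette records the models, the
parameters that matter, and the numerical decisions, so that every choice
a reviewer might question is stated in one place.

## Candidate deduplication

Automated detection on large light-sheet stacks can emit the same soma
twice. The filter removes candidates closer than a minimum physical
distance, 9 µm by default — about one soma diameter.

Three decisions needed fixing where a simple script would have made them
implicitly:

* **Distance is 3-D Euclidean in micrometres**, after scaling voxel
  indices by the per-axis voxel size (default z, y, x = 3.990, 0.943,
  0.943 µm). With ~4:1 anisotropy a voxel-space distance would have no
  physical meaning.
* **Boundary**: "within 9 µm" is read strictly — a pair at exactly 9 µm
  is retained. Configurable via `min_dist_um`.
* **Which member survives**: a greedy first-come-first-kept scan in input
  order, which is deterministic and matches the natural behaviour of a
  single pass over a detection list. `keep = "intensity"` instead visits
  candidates in decreasing intensity so the brighter member survives.

The greedy scan is quadratic in the worst case but vectorised against the
kept set; tests verify exact agreement with an independently written
O(n²) oracle on 100 random clouds, idempotence, and invariance under
joint rescaling of voxel sizes and threshold.

## Stain-morphology classifier

c-fos signal appears either as a compact bright core (recent nuclear
transcription) or as dimmer soma-filling signal (older cytoplasmic mRNA).
The classifier operates on 11×11×11-voxel cubes centred on each detected
cell; out-of-bounds neighbourhoods are zero-padded.

**Split and augmentation bookkeeping.** The labeled cubes are split
80/20 per class, with `floor(0.8 · n_class)` in training. Each training
cube is expanded exactly 7-fold: identity, horizontal flip, vertical
flip, ±90° in-plane rotations, and ±2-voxel horizontal translations
(vacated planes zero-filled). "Horizontal" is the x axis of the
(z, y, x) cube and rotations act in the xy plane; both are configurable.
The composition of the seven was reconstructed from the arithmetic of
the augmented-set sizes; the 180° rotation is omitted because it equals
the composition of the two flips and would silently duplicate examples.
Test data are never augmented, and tests assert that no test cube shares
a source with any training cube.

**Architecture.** A compact 3-D conv net: 3³ valid convolution (8
filters) → ReLU → 2³ max-pool → 3³ valid convolution (16 filters) → ReLU
→ dense 2-way softmax; for an 11-cube the spatial path is 11 → 9 → 4 → 2.
The layer table lives in a single `stain_model_config()` object so the
architecture can be swapped without touching the training loop. The
network and its training loop (mini-batch Adam, batch 32, learning rate
1e-4, weight decay 5e-4, default 500 epochs) are implemented in the
package with im2col-style matrix operations; backpropagation is verified
against central finite differences in the test suite, and training is
bit-deterministic for a fixed seed. Inputs are standardised by the
training set's global mean and SD, stored with the fitted weights.

**What the accuracy tests mean.** The suite trains on synthetic cubes
whose classes are separable by construction (below) and requires ≥95 %
held-out accuracy at ≤50 epochs, plus chance-level accuracy after label
shuffling. This demonstrates that the architecture, training loop, and
data plumbing work; it says nothing about accuracy on real annotated
cells, which depends on annotation quality and imaging conditions.

## Regional aggregation

Cells are assigned to regions by nearest-voxel lookup in the registered
label volume (registration itself is upstream and out of scope); label 0
is background and leaves a cell unassigned. Count tables retain only
gray-matter regions of the ontology (white-matter and clear labels are
excluded from analysis) and guarantee an identical region set across
subjects, with explicit zero rows.

Entries lost to failed registration (e.g. the olfactory bulbs of
individual brains) are **flagged missing, never zero-filled** — a zero
would be interpreted as "no active cells" and corrupt every correlation
involving that region. Downstream correlation uses pairwise-complete
observations.

Whole-brain density divides a subject's total gray-matter count by brain
volume in mm³; the volume helper counts nonzero-label voxels times the
physical voxel volume. Whether such a density should use whole-brain or
gray-matter-only volume is genuinely underdetermined; the denominator is
explicit in the API so either convention can be supplied.

## Group statistics

* **Two-way ANOVA with η².** Sex × time designs with 3–7 animals per cell
  are rarely balanced, so sums of squares are Type II (each main effect
  adjusted for the other, the interaction for both, via `car::Anova`);
  η² = SS_effect / SS_total. With balanced data this equals the classical
  sequential decomposition, which the tests verify against hand-computed
  sums of squares. A perfect fit (zero residual SS) falls back to the
  sequential table, which is identical in the balanced designs where
  perfect fits arise.
* **Dunnett many-to-one comparisons.** Under the null the comparison t
  statistics are jointly multivariate t with correlation
  √(λ_j λ_k), λ_j = n_j / (n_j + n_0), on the pooled-error degrees of
  freedom; the adjusted p is the tail probability of the maximum absolute
  component (computed with `mvtnorm::pmvt` under a fixed internal seed,
  absolute tolerance 1e-6). Tests compare against a 10⁶-draw Monte-Carlo
  simulation of the max-|t| null.
* **FDR.** Benjamini–Hochberg step-up via `stats::p.adjust`, validated
  against a hand computation. BH is monotone in the p-ranks and capped at
  1; note it is *not* exactly idempotent on already-adjusted inputs
  (e.g. q = (0.02, 0.5) re-adjusts to (0.04, 0.5)), so only monotonicity
  and the cap are asserted.
* **Region-wise tests.** Independent two-sample t-tests use pooled
  variance by default, matching the pooled-SD Cohen's d that accompanies
  them; Welch is available (`welch = TRUE`) but off, and switching it
  changes the per-region t and p values. Paired tests (for within-animal
  comparisons such as punctate vs diffuse counts) match animals by
  subject id and report mean difference over SD of differences as d.
  Regions with fewer than two observations per group, or no variance at
  all, are skipped with a warning, and BH correction runs across the
  tested regions only. Tests are two-sided; "elevated" regions are
  reported by the sign of the effect.

## The functional network

Nodes are gray-matter regions; the adjacency candidate is the Pearson
correlation of counts across the animals of one group (the 15-min group
in the motivating design, where induction peaks). Correlations honour the
missing-data mask through pairwise-complete observations; pairs with
fewer than 3 complete animals, and all pairs of a zero-variance region,
are undefined and can never become edges.

**Thresholding.** The graph keeps the top `round(ρ · n(n−1)/2)` pairs by
|r|. Ties are broken by ascending region-id pair under a stable sort, so
the graph is deterministic. Signed weights are kept as edge attributes
for reporting; every topology metric operates on the unsigned binarized
view. At 143 regions, ρ = 0.025 gives `round(253.8) = 254` edges — the
reproducible value under this rounding rule; an exact edge budget can
always be requested by passing ρ = m / 10153.

**Efficiency-cost optimization.** The quality function is read as
J(ρ) = (E_g + E_l) / ρ — combined global and local efficiency per unit
connection cost — with E_g the mean inverse shortest-path length over
ordered pairs (unreachable pairs contribute 0) and E_l the mean over
nodes of the global efficiency of each neighbour subgraph (degree-<2
nodes contribute 0). The argmax is taken over a density grid; ties go to
the sparser network. Two numerical choices matter:

* The default grid runs in 0.005 steps up to 0.30 but **starts at the
  density giving mean degree 1** (ρ = 2/(n−1)). Below that the
  thresholded graph is a handful of disconnected edges, and J degenerates:
  the first chance triangle contributes a fixed E_l while ρ → 0, so
  J ~ E_l/ρ diverges toward the sparsest clique. Mean degree ≥ 1 keeps
  the criterion in the regime where it behaves as intended (selected mean
  degrees of ~2–5, the range typical of functional brain networks).
* On correlation matrices with very strong, nearly noise-free block
  structure the same degeneracy reappears at any grid: efficiency-per-
  cost prefers one tight clique over a spanning network. This is a
  property of the criterion, not an implementation artefact; it is why
  the recovery tests below evaluate community recovery at a stated fixed
  density rather than through ECO.

Tests verify the whole curve against a brute-force oracle on a worked
4-region example (strong triangle plus weak spokes: J* = 2.5 at ρ = 0.5)
and the efficiencies against exhaustive shortest-path enumeration on
every graph with up to 5 nodes.

**Communities and node roles.** Louvain modularity optimisation runs on
the binarized giant component with 20 seeded restarts, keeping the
best-modularity partition; community counts from Louvain are
restart-dependent on real data, so the partition object (not a specific
community count) is the reproducible product. `giant_only = FALSE`
partitions the whole graph, needed when a planted-structure evaluation
must score nodes outside the giant component. Within-module degree
z-scores use the community **population** SD (σ computed with the 1/n
convention; a zero-spread community collapses to z = 0), and the
participation coefficient is P_i = 1 − Σ_s (K_is/K_i)², 0 for an
all-internal node and for degree-0 nodes (flagged). Role labels collapse
the classical seven-role taxonomy to four: hubs are z ≥ 2.5; among hubs,
connector hubs have P ≥ 0.30; among non-hubs, connectors have P ≥ 0.62.
All three thresholds are arguments.

**Centralities.** Degree on the binarized graph; eigenvector centrality
is the principal eigenvector of the binary adjacency, scaled to maximum
1, computed on the giant component with zeros elsewhere (and a warning)
when the graph is disconnected — sparse ECO-selected networks usually
are.

**Small-worldness.** σ = (C_g/C_rand)/(L_g/L_rand), with C the mean
local clustering coefficient, L the mean shortest path over reachable
ordered pairs of the giant component, and the null references the means
over 1,000 seeded Erdős–Rényi G(n, M) draws with matched node and edge
counts (each draw evaluated with the same conventions, including its own
giant component, since sparse G(n, M) graphs are typically disconnected).
**Clustering convention:** nodes of degree < 2 have no defined local
clustering and are excluded from each graph's average by default
(`clustering_isolates = "exclude"`), which makes the sparse-ensemble mean
converge to the edge probability M/(n(n−1)/2) — for G(143, 256),
≈ 256/10153 ≈ 0.025. The alternative convention (count them as 0)
shrinks the mean by the isolate fraction (≈ 0.022 for the same ensemble)
and is available because both appear in the literature; the two σ values
differ correspondingly, so reported σ should state the convention.
σ errors out rather than returning ±Inf when the null clustering is zero
(too few edges for triangles) — small-worldness is simply undefined
there.

## The synthetic-data generator

The generator exists so every downstream stage has exact ground truth.
It emulates the *structure* of the motivating experiment, not its
physics.

**Count tables.** Counts are Poisson draws from a log-normal latent
rate:

> log λ(animal, region) = baseline_region + log FC(group, region)
> + loading · f(animal, community(region)) + dispersion · ε

with per-region baselines drawn once from N(log 200, 0.7²) (a few
hundred cells per region), standard-normal per-animal community factors
f inducing cross-animal correlation within planted communities, and
log-normal overdispersion ε. Hub regions instead load on the
variance-normalised sum of all community factors, correlating with every
community. No claim is made that real c-fos counts follow this model;
it was chosen because the network stage consumes Pearson correlations of
counts and needs a tunable correlation knob with planted structure.

Defaults are the study conditions of the motivating design: seven groups
(rack and home-tank controls, 5–120 min kill times) with 3–7 animals per
sex and cell (15 min: 7 F + 6 M); fold changes peaking at 3.5× at 15 min
and returning to baseline by 60–120 min; `missing_spec` plants
failed-registration entries, flagged exactly as the aggregation stage
flags them. The correlation knobs default to loading 0.4 / dispersion
0.9: with 13 animals this produces the modest, noisy cross-animal
correlations under which ECO selects sparse mean-degree-2–5 networks —
the regime reported for real functional c-fos networks. (With strong,
nearly noiseless blocks ECO degenerates as described above.)

**Recovery conditions.** The planted-structure tests use one documented
configuration: 40 regions, 4 communities, region 1 a hub with hub
loading 1.0, community loading 0.8, dispersion 0.4, a single 30-animal
group, network thresholded at density 0.25, whole-graph Louvain. The
community ARI is scored over non-hub regions (the hub is deliberately
cross-community and has no single true community), and the hub must rank
in the top 3 by degree. Thirty animals is a validation scale chosen so
that correlation sampling noise (SD ≈ 0.19) does not dominate the
planted signal; it is larger than the 13 animals of the motivating
design, where single-seed recovery would be luck rather than property.

**Point clouds** place base points with guaranteed mutual separation
(9 µm + the largest planted offset + 1 µm), then displace duplicates at
exact physical offsets in uniformly random directions, recording ground
truth pairs; so sub-threshold pairs are exactly the planted ones.
**Volumes** partition a toy atlas into axial slabs with gray / white /
clear classes and render punctate cells as Gaussian cores (σ ≈ 2 px,
peak 12) and diffuse cells as filled somata (radius 4 px, plateau 4,
centre slightly dimmed), over background noise of SD 0.3 around 1. The
classes are separable by construction — the punctate peak is three times
the diffuse plateau — which is what makes the classifier's ≥95 %
property falsifiable rather than vacuous.

What the generator does **not** emulate: microscope optics and PSF
anisotropy, tissue-clearing artefacts, registration deformation fields,
spatially varying background, or biologically realistic region volumes.
Passing tests therefore certify the algorithms and their bookkeeping,
not performance on real imaging data.

## Problem sizes and runtime

The test suite runs at deliberately small scale — 120-cell volumes,
20-epoch training, 40-region networks, 1,000-draw null ensembles,
10⁶-draw Monte-Carlo oracles — completing in about a minute on one CPU;
the same code paths scale to the 143-region, 1,000-null analyses the
package targets, and `scripts/acceptance.R` recomputes the G(143, 256)
null references at full ensemble size in seconds.

## Known limitations

* Registration, template construction, and upstream cell detection are
  consumed, not performed; their failure modes enter only through the
  missing-data mask.
* The conv-net architecture is a documented placeholder of the intended
  family (two conv blocks and a dense head) kept in one swappable config
  object; no claim of architectural equivalence to any external model is
  made.
* Weighted-graph efficiency variants and signed-community detection are
  out of scope: all topology uses the unsigned binarized view, with
  signed weights retained for reporting.
* Dunnett p-values use the equicorrelated many-to-one structure implied
  by a common pooled variance; heteroscedastic designs would need a
  different covariance.
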