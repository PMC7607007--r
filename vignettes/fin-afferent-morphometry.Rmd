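---
title: "Morphometry and fin innervation mapping of pectoral-fin sensory neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry and fin innervation mapping of pectoral-fin sensory neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`finmorph` quantifies traced reconstructions of sensory neurons that
innervate the larval zebrafish pectoral fin. A reconstruction arrives as an
SWC tree (3D node positions in microns, parent links) with a sidecar table
tagging each node's skin surface (`axial`, `fin_medial`, `fin_lateral`), a
per-neuron metadata row (soma area in square microns; signed anteroposterior
soma position in microns relative to the myomere 3/4 boundary, negative =
hindbrain), and one 18-point fin edge landmark set per fish. The pipeline

1. re-segments each arbor into interbranch segments and computes a
   13-parameter feature vector,
2. classifies neurons by Ward agglomerative clustering with
   silhouette-based selection of the cluster count,
3. fits a best-fit plane to the fin landmarks, partitions the fin into
   quadrants and medial/lateral octants, and quantifies per-region afferent
   length and terminal counts, and
4. estimates how much axial (body-wall) innervation the adducted fin would
   contact, by registering a stereotyped "model fin" onto each fish.

Because raw tracing data of this kind are not publicly deposited, the
package ships a synthetic-data generator that emulates the study design and
carries exact ground truth, so every stage is testable end to end.

# Tree morphometry

## Restriction semantics

All tree metrics operate on a *label restriction*: an edge belongs to the
restriction iff its **child** node carries one of the requested labels. This
convention makes label classes partition the edge set, so restricted total
lengths are exactly additive (`total(all) = total(fin) + total(axial)`), and
it is what lets the octant quantification conserve the fin-restricted total
to machine precision.

The default feature-vector restriction is the fin arbor
(`fin_medial` + `fin_lateral`). The unbranched path from the soma to the
fin — the process leading up to the fin — is included in *total length* and
*maximum path distance* (which is always measured from the soma), but it
does not contribute segments to the contraction, angle, asymmetry or
fractal-dimension averages. A restriction that selects a disconnected node
set (e.g. a single fin surface, whose branches interleave with the other
surface) is rejected with an error listing the orphan components.

## The 13 parameters

| # | name | units | definition |
|---|------|-------|------------|
| 1 | `n_branch_points` | count | nodes with ≥ 2 selected children (a multifurcation counts once) |
| 2 | `max_branch_order` | count | branch points between the soma and the deepest terminal, + 1 |
| 3 | `strahler` | count | terminals = 1; a parent is n + 1 if **all** daughters are n, else the maximum daughter value |
| 4 | `mean_partition_asymmetry` | – | per branch point, `abs(l - r) / (l + r - 2)` on daughter terminal counts, defined when `l + r > 2`; all unordered daughter pairs averaged at a multifurcation; mean over qualifying branch points |
| 5 | `max_path_distance` | µm | largest summed inter-node step length from the soma to any selected terminal |
| 6 | `mean_contraction` | – | per segment, chord length / arc length (1 = straight), averaged |
| 7 | `mean_branch_angle` | deg | amplitude at the branch point between vectors to the two daughter-segment endpoints |
| 8 | `mean_local_angle` | deg | same, with vectors to the node 10 raw trace nodes into each daughter (clamped for short daughters) |
| 9 | `mean_remote_angle` | deg | same, with vectors to each daughter's next critical node |
| 10 | `mean_fractal_dimension` | – | per segment, slope of log cumulative path length on log cumulative chord length (exactly 1 for straight segments); ≥ 5 nodes per segment required |
| 11 | `total_length` | µm | Σ segment arc lengths, plus the soma-to-fin stem |
| 12 | `soma_area` | µm² | supplied metadata (measured on a single-micron z-slice) |
| 13 | `ap_position` | µm | supplied metadata, signed (negative = hindbrain) |

Degenerate inputs carry `NaN` sentinels: an unbranched arbor has no defined
asymmetry or angles (it still has 0 branch points, Strahler 1, order 1).
Zero-arc-length segments are excluded from ratio averages with a warning.

**The branch-angle family.** The legacy description of parameter (7) is
internally inconsistent (it restates a length fraction while naming an
angle). This package resolves the family as three bifurcation *amplitudes*
that differ only in how far into each daughter the direction vectors reach:
the branch angle and the remote angle both use the daughter segments'
endpoints and therefore coincide under the defaults, while the local angle
uses a 10-node offset. The offset is a parameter (`local_offset`), counted
on raw trace nodes — traces are pixel-spaced and the package deliberately
does not resample them — so users whose traces are sampled differently can
adjust it. Keeping both endpoint-based columns preserves the 13-column
layout; they carry identical information unless the offset convention is
changed, which standardization tolerates (they are duplicated, not
constant).

**Angle averaging** is unweighted over branch points (no length weighting);
multifurcations contribute the mean over all unordered daughter pairs.

# Clustering

Features are standardized column-wise to mean 0, standard deviation 1
(n − 1 denominator), with the scaling parameters retained for inversion.
`NaN` cells — produced only by degenerate arbors — are mean-imputed per
column with a warning at this step and nowhere earlier, so the feature CSV
on disk preserves the sentinels. Constant columns are an error, naming the
column.

Clustering is agglomerative with Ward's criterion on the Euclidean distance
matrix. The default variant is `ward.D2` (the textbook Ward criterion on
Euclidean distances); `ward.D` is exposed as an option because legacy
analyses in R sometimes used it on unsquared distances. The cluster count is
selected by the average silhouette width over k = 2 … min(8, n − 1), ties
broken toward the smaller k; singleton clusters contribute silhouette width
0, the standard convention. A leave-one-feature-out stability report
(adjusted Rand index of the k-cut after dropping each feature) is produced
as a report, not a pass/fail test.

# Fin geometry

## Plane fit and projection

The fin plane is the total-least-squares plane through the 14 non-base
landmarks (SVD of the centred coordinates; the four base points are excluded
from the fit but remain projectable). The in-plane basis sets the first axis
along the fin base — the body axis — and orients the normal so the medial
side has positive signed distance (explicitly via `medial_point`, or by a
deterministic sign convention otherwise). Collinear landmark sets are a rank
error. Projection maps points to in-plane (u, v) coordinates with the
centroid at the origin; it is idempotent and an isometry for coplanar
inputs.

## Quadrants and octants

The fin footprint is the polygon through the projected fin-membrane (FM)
ring; the projected fin-body (FB) ring is the blood-vessel boundary
separating base from membrane. The dorsoventral boundary is the line from
the midpoint between (a) the midpoint of the two FB base points and (b) the
FB apex, through the FM apex — the two distinguished proximal/distal FB
landmarks; the exact construction the original study used is not recoverable
from its description, and this reading is the package's documented choice.
Half-plane clipping of the FB polygon and the membrane annulus yields the
four quadrant polygons (DM, DB, VB, VM), which tile the footprint.

Edge assignment splits every fin-labeled edge exactly at its crossings with
the FB ring, the footprint ring and the dorsoventral line, classifies each
sub-edge by its projected midpoint, and accumulates **3D arc length** (the
projected 2D length is reported alongside). 3D length is the headline
because it makes the octant table conserve the fin-restricted morphometry
total exactly, which keeps the whole table auditable; whether the original
octant lengths were 2D or 3D is not stated anywhere, so both are emitted.
Boundary ties go deterministically to the dorsal and membrane sides. Fin
length whose projection falls outside the footprint (possible with noisy
landmarks) is assigned by the same classification rules — effectively the
nearest region — and logged, with a configurable warning threshold. The
medial/lateral surface comes from the node tags, as in a tagged tracing; a
geometric fallback (sign of the signed plane distance) is available and
agrees with the tags whenever arbors do not hop surfaces mid-branch.

## Model fin and adduction overlap

The stereotyped model fin is the cohort mean of the projected FM footprints,
each expressed in its fish's base frame (origin at the FM base midpoint,
first axis along the base, apex on the positive side). Registration onto a
fish is rigid — rotation plus translation, no scaling — matching the base
midpoint and the base angle, the angle the base segment makes with the
in-plane body axis. The construction assumes a consistent anatomical frame
across fish (apex on the positive v side, base labels ordered
anterior→posterior), which the plane-fit conventions guarantee for data
generated or landmarked under this package's conventions. Axial innervation
is projected onto the plane, clipped to the placed polygon, and reported as
clipped 3D arc length and as a percentage of total axial length.

Two separate constructs answer two separate questions: terminal counts "on
the axial surface under the fin" use the fish's **own** footprint, while the
adduction-contact estimate uses the **registered model** fin.

# Statistics

* `correlation_terminals`: two-sided Pearson correlation (t transform,
  n − 2 degrees of freedom) of medial-surface fin terminal counts against
  axial terminal counts under the fin.
* `trend_test`: single-predictor linear regression of total fin afferent
  length on anteroposterior soma position, reported as the regression ANOVA
  F and p plus the slope sign (anterior = more negative position, so
  "anterior neurons have longer afferents" is a negative slope). An
  exclusion argument supports the with/without Rohon-Beard variants. A
  constant response returns F = 0, p = 1 by convention.
* `length_comparison`: the axial-vs-fin comparison is implemented as
  printed in the source analysis — a chi-square goodness-of-fit of the two
  *summed* totals against equal expectation — and is paired with a labelled
  paired Wilcoxon signed-rank alternative. The chi-square form is
  statistically unusual for continuous totals: its statistic scales with
  the measurement unit (summing microns makes it arbitrarily large), so it
  is anticonservative at realistic cohort scales and is emitted for
  fidelity, not inference. The Wilcoxon result is the one to read. For the
  same reason the package makes no null-calibration claim for this test;
  the Pearson and trend tests are calibrated against 10⁴-replicate null
  simulations at the study's n = 21.

# The synthetic cohort

The generator emulates the study conditions, not neurite biophysics: a
cohort of 21 sparsely labeled neurons — 17 hindbrain somata at negative
anteroposterior positions and 4 Rohon-Beard somata at positive positions —
each with an unbranched stem to the fin base, a bifurcating correlated
random walk over the near-planar fin surface (nodes offset ±ε out of plane
and tagged by surface), and a second branching walk over the adjacent body
wall. Soma areas are drawn uniformly within the observed anatomical range
(48.9–178.6 µm²), used only as plausible bounds. The fin is a fan: an FB
half-ring of radius 80 µm inside an FM ring 70 µm further out (≈ 150 µm fin
extent, the scale of a 5-dpf pectoral fin), with configurable radial and
out-of-plane landmark noise (defaults 3 and 2 µm).

Three growth regimes mirror the three observed morphological classes, with
sizes 14/5/1 plus one neuron that does not branch in the fin (always
carried as a Rohon-Beard, mirroring the study's bookkeeping):

| regime | n | branch prob./node | step (µm) | tortuosity (rad/step) | daughter amplitude (deg) | branch-point budget |
|---|---|---|---|---|---|---|
| arborized | 14 | 0.06 | 4 | 0.20 | 70 ± 12 | 22 |
| dense | 5 | 0.14 | 3 | 0.45 | 105 ± 12 | 55 |
| sparse | 1 | 0.025 | 6 | 0.08 | 40 ± 8 | 4 |

The regimes deliberately differ in several feature families at once
(branching density, segment length, meander, amplitude), because the point
of the default cohort is a test-bed with *distinct* classes; separation is
otherwise a free dial (`generate_feature_cohort` draws 13-feature rows
directly from Gaussian regimes whose centroid distance is `separation`
times the within-regime RMS radius, which is how the cluster-recovery
properties are quantified over many replicates).

Further design choices, all fixed before any measurement:

* **Allocation.** Fin vs axial allocation is controlled by branch-point
  budgets (the axial budget is half the fin budget plus a base count), not
  by a length fraction; tying the two sizes together reproduces the
  observed positive coupling between fin and axial innervation.
* **Anteroposterior trend.** Budgets are modulated linearly across the
  soma-position range (±20% by default), so anterior neurons grow larger
  arbors — the study's trend — without destroying regime separation.
* **Medial bias.** The first fin branch and every surface switch draw the
  medial surface with probability `medial_fraction` (default 0.7), making
  the stationary medial share equal the configured fraction.
* **Walls.** A growth tip whose segment would exit the fin footprint turns
  back toward the footprint centroid instead of dying, so branch budgets
  are actually consumed; realized branch points can fall below budget only
  through the global node cap or turn limit.
* **Ground truth.** Octant truth is computed in the generator's canonical
  frame (plane z = 0) by densely sub-sampling every emitted edge and
  classifying samples against the canonical rings — no plane fit, no
  projection, no edge splitting — so it is an independent oracle for the
  measurement path. The cross-module agreement test runs at zero
  out-of-plane landmark noise, where the fitted plane provably coincides
  with the canonical frame and any disagreement isolates the
  boundary-splitting code.

What the generator does **not** emulate: image noise, tracing errors,
z-anisotropy, overlap between neighbouring neurons (every synthetic axial
arbor is fully reconstructable, whereas the real study could reconstruct
only 12 of 21 axial arbors), curved fin surfaces, or any developmental
growth mechanism. Passing tests therefore demonstrate that the
*measurement* pipeline is correct and calibrated on data of this geometry —
not that it is robust to tracing artefacts.

# Numerical conventions and test scales

* Conservation (octant sum = fin-restricted total; axial = under-fin +
  outside) is checked at 1e-6 relative tolerance on a 50-neuron cohort; the
  construction makes it exact to floating-point rounding.
* Boundary splitting is validated against 10⁴-point sampling oracles to
  0.1% of the segment length on constructed crossing segments.
* Strahler, partition asymmetry and segment-count identities are validated
  against independent brute-force recursions on 100 random trees of up to
  50 tips (exact integers / 1e-12).
* Rigid-motion invariance of all tree metrics and region lengths is checked
  under 20 random rotations + translations at 1e-6 relative tolerance.
* Cluster recovery is quantified on 200 seeded feature-space replicates
  (three regimes, separation 4, n = 20): the silhouette must select k = 3
  with perfect adjusted Rand agreement in at least 95% of replicates, and
  unseparated cohorts must score mean silhouette below 0.3.
* Type-I error of the Pearson and trend tests is checked within ±0.01 of
  the nominal 0.05 over 10⁴ null simulations at n = 21.
* Determinism: a fixed seed makes the full pipeline byte-identical across
  runs; every stage writes plain CSV/JSON/Newick/SWC so partial re-runs are
  possible, and a manifest records the config, seed and input hashes.

These problem sizes are the package's design points: large enough that the
identities and calibrations are meaningful, small enough that the whole
suite runs in a couple of minutes on one core.

# Known limitations

* The interbranch segmentation tolerates multifurcations but the
  segment-count identity `segments = terminals + branch points` is stated
  (and tested) for binary arbors.
* A stem that branches *before* the fin with both branches entering the fin
  makes the fin restriction disconnected; the package raises an error
  rather than guessing which component is "the" fin arbor. (The generator
  never produces this; real data would need manual re-tagging.)
* The model-fin registration is rigid and assumes a consistent anatomical
  base frame across fish; fins of very different sizes are deliberately not
  rescaled.
* The chi-square length comparison is reproduced for fidelity but is not a
  calibrated test (see above).

```{r example}
library(finmorph)
res <- run_pipeline(generator_config(seed = 1), out_dir = "run")
res$cluster$assignment$k
res$regions$conservation$relative_error
```
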