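---
title: "Evaluating connectome segmentations: methods and design"
author: "conneval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating connectome segmentations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conneval)
```

## The evaluation model

`conneval` scores a test segmentation `S` of an EM volume against a
reference `G` at three granularities — whole-volume summary, per body,
and per grid subvolume — over two comparison domains: all labeled voxels,
and the set of synapse endpoints (each annotated connection contributes
its presynaptic and its postsynaptic site as one comparison point each,
weighted equally). Every supervised metric is a function of one sufficient
statistic, the sparse contingency table `n(s, g)` counting comparison
points per (test label, reference label) pair.

Conventions, fixed once and used everywhere: coordinates are 0-based
`(z, y, x)` in a global voxel frame; boxes are half-open; label 0 is the
single ignore value (background, untraced voxels, voxels erased by
boundary dilation) and never enters any metric; entropies are reported in
bits (base-2 logarithms).

**Variation of information.** `VI = H(S|G) + H(G|S)`, with probabilities
taken as comparison-point fractions. The over-segmentation component
decomposes exactly into per-reference-body terms `P(g) H(S | G = g)`
(conditional entropies are non-negative, so each term is non-negative and
the terms sum to the component); transposing the table yields the
per-test-segment under-segmentation decomposition. A second per-body view
reports, for one body `g`, its over term together with an under term
`Σ_s P(s) H_b(g | s)` — `H_b` the binary entropy of membership in `g`
within segment `s` — which exposes how far the segments containing `g`
leak into other bodies.

**Rand indices.** Plain and Hubert–Arabie adjusted, by pair counting from
the table and its marginals. In the degenerate case where chance leaves no
room (both labelings a single segment) the adjusted index is defined as 1.

**Connectivity correctness.** Connections resolve to ordered
(pre-label, post-label) edges; a connection is *preserved* when its
test-side edge is exactly `(A(g_pre), A(g_post))` under a one-to-one
partial assignment `A` of reference bodies to test segments. Matching is
by connection identity — the same physical synapse on both sides — never
by edge-weight arithmetic, and edges are direction-sensitive. CC is the
preserved fraction of resolvable reference connections. The thresholded
recall variant restricts the denominator to reference pairs with edge
weight above `k` (strictly, by default; an `inclusive` flag gives `>= k`),
and the precision variant divides by test pairs above threshold; an empty
denominator is reported as `NA`, never as 0.

**Assignment.** The default `greedy` method sorts candidate `(s, g)` pairs
by overlap weight descending, breaking ties by smaller test label then
smaller reference label — determinism is a contract, reports must be
reproducible — and accepts pairs whose labels are both unused. The
`optimal` method maximizes total overlap by maximum-weight bipartite
matching (via `igraph`). In the usual over-segmentation regime every test
fragment overlaps a single body and the two coincide; the test suite
checks `greedy <= optimal` always and equality on split-only corruptions.
Matching weights come from the endpoint-domain table when connections are
supplied (the objects the connectivity metrics score), else from voxels.

**Fragmentation and completeness.** `Frag` is the difference in distinct
segment counts over the comparison domain. The thresholded form sorts
segment sizes descending and reports the minimal prefix reaching X% of
total size; it is also exposed reference-free, as are orphan counts
(size strictly below K) and the autapse report (connections with equal
nonzero pre and post labels, ranked per segment — an outlier list rather
than a hard error, since genuine autapses exist).

## Blockwise architecture

Contingency tables are mergeable: entrywise addition with an empty-table
identity, associative and commutative. The table of a volume equals the
merged tables of any blockwise partition — the property that makes the
evaluator scale: blocks can be processed independently (in principle
concurrently) and combined, and the test suite asserts summary metrics
are identical to 1e-10 across block shapes.

Connected components run in two stages. *Local* components split each
block's labels into maximal 6-connected pieces (6-connectivity is the
conservative choice for anisotropic EM label data); *global* components
then union-find across pairs of face-adjacent boundary voxels of
neighboring ROI blocks whose original labels agree. A segment whose only
connecting pathway runs outside the region of interest is therefore
scored as two objects. Final labels are canonical — components are
numbered by the smallest global voxel index they contain — so the output
is bit-identical regardless of the partition, which in turn makes whole
evaluation reports byte-reproducible.

## Filters and their scope

**Boundary dilation** sets to 0 every reference voxel within Euclidean
distance `r` (voxel units; anisotropy deliberately ignored, since the
radius is specified in pixels) of a differently labeled voxel. Two design
decisions matter here:

* Dilation is a *comparison-domain filter*, not a topology change.
  Component structure is computed before dilation, and the endpoint
  domain — synapse resolution, connection graphs, connectivity metrics —
  always uses the undilated reference. Synapses concentrate on thin
  processes near boundaries; eroding the reference before resolving them
  would discard precisely the points the connectivity metrics exist to
  score.
* Only the reference is masked; comparison skips points where the
  reference is 0, so the test volume needs no modification.

The erased set grows monotonically with the radius (tested), and a
boundary perturbation confined to distance `r` of a boundary is removed
entirely from the voxel metrics by dilation at radius `r` — the rationale
for the default radius of 2 voxels, which absorbs annotator-level
boundary placement noise without touching topology.

**Sparse filtering** masks the test volume wherever the reference is
unlabeled, restricting all metrics to the traced subset.
**Orphan filtering** drops reference segments below a voxel-count
threshold before scoring, for references known to contain untrustworthy
fragments. Neither filter ever introduces a nonzero label.

**Downsampling** maps each `f^3` block to its modal nonzero label,
breaking ties toward the smaller label (deterministic and
partition-independent); synapse coordinates are integer-divided. Offset
and resolution rescale accordingly.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `block_shape` | 64×64×64 | voxels | balances per-block overhead against table merge cost |
| `dilation_radius` | 2 | voxels | absorbs boundary placement noise; see above |
| `orphan_k` | 10 | synapse endpoints | below ~5 synapses a fragment cannot be a plausible complete neuron |
| `completeness` | 50, 75, 90 | % | spread of practically interesting connectome completeness levels |
| `cc_thresholds` | k = 0 strict; k = 9 inclusive | connections | all pathways, and pathways of at least 10 synapses (strong, biologically robust edges) |
| `match_method` | greedy | — | coincides with optimal in the over-segmentation regime at a fraction of the cost |
| `top_n` | 50 | bodies | keeps report JSON small; full tables available programmatically |

## The synthetic scene generator

Test fixtures are generated, never stored. A scene is a densely packed
labeling built from nearest-seed-point regions (space-filling,
face-connected — rare lattice-tie pinch-offs are reattached to an
adjacent segment deterministically), with synaptic connections placed as
point pairs straddling segment-adjacency faces. Faces are sampled with
probability inverse to the smaller partner's volume, concentrating
connections on thin processes, where real synapses sit and where
segmentation errors do the most connectivity damage. Ground truth
contains no autapses by construction, and a single integer seed
reproduces a scene bit-exactly (the caller's RNG state is saved and
restored; no hidden global randomness).

Three corruption operators produce known answers:

* `corrupt_split(m)` applies `m` axis-aligned plane cuts. The cut
  coordinate is drawn from the central half of the segment's extent and a
  cut is redrawn unless both parts stay connected, so each cut raises the
  segment count by exactly one (`frag` recovers `m` exactly) and produces
  substantive fragments, as real split errors do, rather than shaving
  single-voxel faces.
* `corrupt_merge(pairs)` relabels adjacent pairs to one label; former
  between-pair connections become autapses, with count equal to the
  pair's edge weight.
* `corrupt_boundary_shift(r)` reassigns voxels within the radius-`r`
  dilation band to adjacent segments over `r` sweeps, preserving the
  segment count. Voxels hosting synapse endpoints are left in place:
  boundary placement noise is thereby isolated from connectivity error,
  which the split/merge operators model explicitly. Consequently a
  shift-only corruption has `frag = 0` and `CC = 1` but positive voxel
  VI — and dilation at the shift radius restores voxel VI to zero.

Every corruption is logged (operation, segment, cut axis and coordinate,
merged labels), and the log supports an independent oracle: endpoint
labels after corruption are predictable from coordinates and the log
alone, so connectivity correctness and autapse counts can be verified
without touching any volume.

What the generator does **not** emulate: realistic neuron morphology
(regions are convex-ish cells, not tubular arbors spanning the volume),
grayscale imaging artifacts, spatially correlated error hotspots, synapse
annotation noise, or biological autapses. Passing tests therefore
demonstrate metric correctness and pipeline exactness — not that any
particular real segmentation will score well; on real data the metrics
inherit the error characteristics of the synapse annotations they are
given.

## Numerical choices and degenerate inputs

* Entropies in bits; all VI values are documented as base-2.
* Empty contingency tables are an error ("no comparison points"), as is
  Rand on fewer than two points; thresholded connectivity with an empty
  denominator yields `NA`.
* Per-body conservation (`Σ_g` terms = component) holds to 1e-10 and is
  asserted on random tables.
* Ties everywhere break toward smaller labels (matching, mode pooling,
  best-body ranking) — determinism over aesthetics.
* Tables are sparse throughout; label ids may be large and
  non-contiguous, and dense matrices are never materialized.
* Reports embed no timestamps, so identical configurations yield
  byte-identical JSON.

## Problem sizes

The test and acceptance suites run at desk scale by choice: oracle
comparisons on volumes up to 16^3 (where brute-force pair enumeration is
exact and fast), blockwise-exactness checks up to 64^3, and known-answer
corruption recovery on ten seeded scenes of 128^3 voxels, 100 segments
and 1000 connections. The blockwise merge contract is what carries these
guarantees to volumes of arbitrary size; nothing in the pipeline holds
more than one block's table plus the accumulating merged table at once,
apart from the in-memory volumes themselves.

## Known limitations

* Volumes are held in memory as R integer arrays; the blockwise contract
  is the seam for out-of-core or distributed execution, but no such
  backend is included.
* Skeleton-based metrics (expected run length, warping/edit distances)
  are out of scope.
* The zarr reader supports uncompressed v2 stores only; compressed
  stores must be rewritten (e.g. via the Python zarr tooling) first.
* `orphan_count` bins orphans by voxel-centroid block for the heatmap;
  for non-convex fragments the centroid block may not contain the
  fragment.
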