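# conneval

Connectivity-aware evaluation of electron-microscopy (EM) connectomics
segmentations.

Automatic neuron segmentation is scored, almost universally, with
voxel-overlap statistics. Those statistics under-weight exactly the places
where segmentation failures destroy the science: thin neurites carrying
synapses, whose mislabeling silently rewires the reconstructed connectome.
`conneval` evaluates a test segmentation `S` against a reference `G` (or
against nothing at all) with metrics that ask the downstream question —
*how much of the connectome survives?* — and decomposes every score per
body and per subvolume so errors can be localized and debugged, not just
summarized. It is aimed at people running and comparing segmentation
pipelines on EM volumes: label arrays of arbitrary size, an optional list
of synaptic pre/post point annotations, and an optional block-grid region
of interest.

## Metrics

**Variation of information.** With probabilities taken over comparison
points (voxels, or synapse endpoints),

    VI(S, G) = H(S | G) + H(G | S)

in bits; `H(S|G)` is the over-segmentation component and `H(G|S)` the
under-segmentation component. Both decompose exactly into per-body terms
`P(g) H(S | G = g)`, so the worst-fragmented and worst-merged bodies fall
out of the same computation. The plain and Hubert–Arabie adjusted Rand
indices are computed from the same sparse contingency table.

**Connectivity correctness (CC).** Each synaptic connection resolves to an
ordered (pre-segment, post-segment) edge under each labeling. Given a
one-to-one assignment `A` of reference bodies to test segments (greedy by
overlap, or optimal Hungarian-style matching),

    CC(S | G) = Σ_(gi,gj) |x(A(gi), A(gj)) ∩ x(gi, gj)|  /  Σ_(gi,gj) |x(gi, gj)|

where `x(a, b)` is the set of connections between two segments. A false
split strands connections on unassigned fragments; a false merge of two
bodies leaves at most one of them assigned, so both error modes are
punished. Thresholded recall/precision variants (`recCC_k`, `preCC_k`)
restrict to pathways stronger than `k` synapses.

**Fragmentation.** `Frag = |S| − |G|`, a lower bound on merge edits, plus
a thresholded form: the number of segments needed for an X%-complete
volume or connectome.

**Ground-truth-free statistics.** Orphan counts (segments with fewer than
K synapse endpoints, default K = 10), autapse (self-loop) outlier ranking
— a false-merge detector — and segments-to-volume-threshold counts, with a
per-block orphan-density heatmap.

Everything supervised is computed from sparse, *mergeable* blockwise
contingency tables: per-block tables combine associatively into the
whole-volume table, so arbitrarily large volumes can be processed in
pieces and the result provably does not depend on the partition.
Preprocessing implements grid partitioning, local plus global connected
components (so segments joined only outside the ROI stay distinct),
reference boundary dilation, sparse-tracing masks, small-orphan filtering
and mode-pooling downsampling.

## Worked example

```r
library(conneval)

# a synthetic 64^3 scene: 40 densely packed segments, 400 synaptic
# connections biased onto thin processes, then 8 random plane splits
scene  <- generate_scene(c(64, 64, 64), 40, 400, seed = 1)
scene  <- corrupt_split(scene, 8, seed = 2)
report <- run_evaluation(scene$test, scene$ground_truth,
                         synapses = scene$connections,
                         block_shape = c(32, 32, 32))
report
#> <evaluation_report>
#>   voxels: VI 0.1676 (over 0.1676 / under 0.0000), Rand 0.9967, frag 8
#>   endpoints: VI 0.1443, frag 8
#>   connectivity correctness: 0.9000 over 400 connection(s)
#>   unsupervised: 48 segment(s), 13 orphan(s), 0 autapse(s)
```

The eight plane splits are recovered exactly as `frag = 8`; all the VI is
over-segmentation, as it must be for split-only corruption; and 10% of
ground-truth connections are lost because their fragments were not the
assigned match of their body (`cc = 0.90`). Per-body tables name the worst
offenders, carrying both the canonical component label and the original
label it traces to:

```r
head(report$bodies$worst_oversegmented, 3)
#>   label vi_over_bits orig_label
#> 1    36   0.06073995         40
#> 2    34   0.04443281         33
#> 3    23   0.02317671         34
```

`report$subvolumes` localizes the damage per grid block, and
`compare_reports(a, b)` puts two evaluations side by side with
better/worse orientation per metric. A thin command-line driver wraps the
same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "conneval", package = "conneval"))')
Rscript $CLI synthesize --shape 64,64,64 --segments 40 --connections 400 \
        --corrupt split:8 --seed 1 --out-prefix /tmp/scene
Rscript $CLI evaluate --test /tmp/scene_test.zarr --groundtruth /tmp/scene_gt.zarr \
        --synapses /tmp/scene_synapses.json --out /tmp/report.json --heatmap /tmp/orphans.csv
Rscript $CLI compare /tmp/report.json /tmp/other.json
```

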