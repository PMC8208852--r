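# avsep — pulmonary artery–vein separation from centerline geometry

Radiologists assessing COPD, pulmonary nodules or vascular disease need
the pulmonary arteries and veins told apart, but in CT the two trees
interdigitate so densely that a binary vessel segmentation comes out as
one connected structure whose centerline skeleton fuses them at many
*adhesion points*. `avsep` separates the two trees automatically from
that skeleton alone — no contrast priors, no manual seed points.

The method is purely geometric:

1. the skeleton becomes a **graph** of junction/leaf nodes and voxel-path
   links under 26-connectivity;
2. **adhesion points** (nodes of degree ≥ 4) are split by branch-angle
   pairing — with `a1 = |PA|²`, `b1 = |PB|²`, `c1 = |AB|²` the angle of
   branches A, B at node P is
   `θ = arccos((a1 + b1 − c1) / (2·√a1·√b1)) · 180/π`,
   and the pairing of the four branches maximizing the summed angles
   wins, so each vessel continues straight through the crossing;
3. links group into **subtrees**; nearby leaf tips of different subtrees
   (arteries and veins meet at the alveolar sacs without connecting)
   accumulate an **inter-subtree matching strength (IMS)**, and IMS ≥
   `ims_min` relations two-colour the subtrees into two classes;
4. class labels grow from the skeleton through the vessel mask by
   per-slice 2-D **region growing** (geodesic, deterministic ties);
5. the class with the larger **lumen volume per unit centerline length**
   is the venous tree; leftover subtrees are recovered by a majority
   vote along diameter- and angle-consistent paths toward the class
   roots.

A deterministic synthetic phantom generator (paired tubular trees with
planted adhesions, a bulkier venous tree, detached fragments, and
per-voxel ground truth) makes every stage testable end to end; branch
accuracy against gold labels is `100·(total − misjudged)/total`.

## Worked example

```r
library(avsep)

case <- vascular_phantom(seed = 42)
case
#> <synthetic_case> grid 128x128x128 | 4125 mask voxels, 774 skeleton voxels,
#>   4 planted adhesions, seed 42

res <- separate_vessels(case$mask, case$skeleton, gold = case$gt_labels)
res
#> <av_separation> 72 links in 5 subtrees; vein = class1
#>   branch accuracy 97.22% (2/72 misjudged)

res$stats
#> # A tibble: 2 × 5
#>   class  n_voxels volume_mm3 centerline_length_mm volume_per_length
#> 1 class0     1522       1522                 477.              3.19
#> 2 class1     2505       2505                 506.              4.96

res$evaluation
#> # A tibble: 3 × 4
#>   side    total_branches misjudged_branches accuracy_percent
#> 1 left                33                  2             93.9
#> 2 right               39                  0            100
#> 3 overall             72                  2             97.2
```

The phantom's 774-voxel skeleton decomposes into 72 links in 5 subtrees
(the two main trees, a downstream piece isolated by splitting, and two
detached satellites recovered by path vote). `class1` has the higher
volume per unit length (4.96 vs 3.19 mm²) and is therefore called the
venous tree — correctly, since the generator scaled the venous radii by
√1.5. Two of 72 branches are misjudged, giving 97.22% branch accuracy
against the planted labels. `tidy(res)` returns the per-branch table,
`glance(res)` a one-row run summary, and `autoplot(res)` a red/blue
projection of the separated trees.

The same pipeline runs from the shell on real volumes:

```sh
exec/avsep synth --seed 42 --out phantom/
exec/avsep separate --mask phantom/mask.nii.gz \
    --skeleton phantom/skeleton.nii.gz --gold phantom/gt_labels.nii.gz \
    --out run/
```

NIfTI (`.nii`, `.nii.gz`) and uncompressed MetaImage (`.mhd`/`.mha`)
volumes are supported; the graph itself can be exported to a documented
JSON dialect (`graph_to_json()`).

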