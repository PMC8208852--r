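---
title: "Separating pulmonary arteries and veins from centerline geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating pulmonary arteries and veins from centerline geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avsep)
```

## The problem and the model

In thoracic CT the pulmonary arteries and veins form two interdigitated
trees that touch in many places at the resolution of the scan. A binary
vessel segmentation therefore comes out as one connected blob, and its
1-voxel-wide centerline skeleton contains *adhesion points*: voxels where
the two trees pass close enough that the discrete skeleton fuses them.
`avsep` separates the two trees using only the geometry of that skeleton,
with no intensity information and no manually placed seeds.

The procedure has six stages:

1. **Geometric graph.** Under 26-connectivity, skeleton voxels with three
   or more foreground neighbours are junction voxels; 26-adjacent junction
   voxels merge into one node (centroid of the cluster), degree-1 voxels
   become leaf nodes, and the remaining degree-2 chains become links —
   simple voxel paths between two nodes. Every skeleton voxel is owned by
   exactly one node or link, an invariant `validate_graph()` checks.

2. **Adhesion splitting.** A bifurcation has node degree 3, so degree
   $\ge 4$ marks an adhesion of two vessels. For each pair of incident
   branches with representative points $A$ and $B$ seen from the node
   $P$, the branch angle is computed by the law of cosines on squared
   distances, $a_1 = |PA|^2$, $b_1 = |PB|^2$, $c_1 = |AB|^2$,
   $$\mathrm{pos} = \frac{a_1 + b_1 - c_1}{2\sqrt{a_1}\sqrt{b_1}}, \qquad
     \theta = \arccos(\mathrm{pos}) \cdot \frac{180}{\pi},$$
   with `pos` clamped to $[-1, 1]$ for floating-point safety. At a
   degree-4 node the three perfect pairings of the four branches are
   enumerated and the pairing with the largest *sum* of its two angles
   wins: a vessel runs straight through an adhesion, so its two halves
   subtend nearly 180°. Each winning pair is fused into one link passing
   through the node. Degree $\ge 5$ nodes are paired greedily and the odd
   branch stays on a flagged residual node — these complex adhesions are
   genuinely ambiguous and are the main accuracy cost.

3. **Subtrees.** After splitting, the connected components of the link
   graph are the subtrees; each belongs wholly to one vessel class.

4. **Peripheral matching (IMS).** Anatomically, arteries and veins
   approach each other at the alveolar periphery without connecting. For
   every leaf tip of every subtree the nearest leaf of a *different*
   subtree is found; each directed match within `d_max` increments that
   pair's inter-subtree matching strength. Pairs with IMS $\ge$ `ims_min`
   are constrained to opposite classes; the constraint graph is
   two-coloured breadth-first, odd cycles resolved by dropping the
   weakest conflicting edge, and subtrees related only through a chain
   inherit a class by the indirect rule (if A–C and B–C are both strong,
   A and B share the class opposite to C).

5. **Lumen restoration.** Class labels are painted onto the skeleton and
   grown slice by slice through the segmentation mask with 2-D
   8-connected region growing. Level-synchronous growth is exactly
   breadth-first geodesic propagation, so a voxel reachable by both
   classes takes the geodesically nearer seed's label (ties go to
   class0, deterministically).

6. **Anatomical call and leftovers.** The venous tree carries more blood
   volume, so the class with the larger lumen volume per unit centerline
   length is called *vein*. Small subtrees with too few leaves ever to
   match peripherally are then recovered: each of their leaves bridges to
   the nearest assigned skeleton voxel (within `bridge_dist`) and a walk
   toward each class root picks, at every node, the continuation
   maximizing $w_a\,\theta/180 - w_d\,|d_{next}-d_{cur}|/\max(d)$ —
   straightest direction, most similar diameter — and the subtree takes
   the majority class of the links crossed (`path_vote` provenance).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `adhesion_mode` | `"endpoint"` | branch representative: far-node centroid; `k_step` uses the k-th path voxel, more local for long curved branches |
| `adhesion_k` | 5 | step count for `k_step` mode (voxels) |
| `d_max` | 10 mm | peripheral-matching radius; of the order of the alveolar-level artery–vein spacing |
| `ims_min` | 2 | minimum matching strength for a relation — one mutual nearest pair; guards against coincidental single matches |
| `w_a`, `w_d` | 1, 1 | path-vote weights for the angle and diameter terms (both normalized to $[0,1]$) |
| `restore_axis` | 3 | growth plane normal; axis 3 is axial by CT convention |
| `bridge_dist` | `d_max` | leftover-subtree bridging radius |

`d_max` and `ims_min` are the consequential ones. Raising `ims_min`
strictly never assigns more subtrees (a tested monotonicity); lowering
`d_max` below the true tip spacing disconnects the relation graph and
pushes everything to the path vote.

## What the synthetic phantom emulates — and what it does not

Clinical CT with expert per-voxel artery/vein labels is not
redistributable, so the package ships a deterministic phantom generator
(`vascular_phantom()`). It emulates the features the algorithm actually
exploits:

* two bifurcating tubular trees growing along the axial axis (so every
  occupied slice of every tube contains a skeleton seed, as the per-slice
  restoration assumes);
* interleaving: the venous tree replays the arterial branching draws with
  a small angular jitter (±1.5°) and is translated laterally, so every
  arterial leaf tip has a venous counterpart within `d_max` — the
  anatomy peripheral matching relies on;
* venous volume dominance: venous radii are the arterial radii times
  $\sqrt{1.5}$, planting a $\approx 1.5\times$ volume ratio (discrete
  rasterization of the thin distal tubes inflates the realized voxel
  ratio somewhat above the nominal value — the ground-truth volume is
  recorded per case);
* planted adhesions: short twigs anchored on one tree cross exactly one
  centerline voxel of the other tree's partner branch transversally,
  guaranteeing a known number of degree-4 crossings at angles well above
  30°;
* detached satellite fragments placed beside a trunk, farther than
  `d_max` from every leaf — these exercise the unassigned → path-vote
  recovery route;
* rasterization artifacts: slowly diverging sibling branches produce
  occasional small loops and spurious junction clusters, similar to the
  false-positive structures real 3-D thinning leaves behind.

The layout uses two fixed lateral axes: subtrees move into parallel
"lanes" at the second generation, all other generations fan out
orthogonally to the inter-tree offset, and deeper split angles are scaled
down (0.6 at the third generation, 0.45 beyond). This bounds how far a
deep branch can drift toward the other tree while keeping siblings
separating quickly enough to rasterize cleanly; a per-case clearance and
contact audit retries a fresh seeded geometry when a draw violates it.
Planting capacity on the default 128³ grid caps at about 18 crossings.

What the phantom does *not* emulate: CT intensity and noise (the
pipeline never sees intensities), segmentation errors in the input mask,
anatomical lobe structure, curved vessels (branches are straight
segments), and adhesions of three or more vessels at one point beyond
the occasional rasterization accident. Passing the phantom suite
therefore shows the geometric machinery is correct under the stated
anatomy, not that clinical-grade accuracy transfers to real CT.

## Numerical and design choices

* **Pairing score.** "Largest angle" at a quadfurcation is read as the
  largest *sum* of the two pair angles; the sum is symmetric and
  implements the both-vessels-run-straight intent. Ties break toward the
  lexicographically smallest link-id pairs, making runs reproducible.
* **Voxel ownership at a fused crossing.** One voxel cannot belong to
  both fused vessels, so a fully consumed node's cluster voxels go to
  the pair whose attachment segment is nearest; the other fused link
  records a small gap, and the path-adjacency validator allows exactly
  those flagged gaps. Residual (odd-degree) nodes keep their voxels.
* **Counting convention.** Peripheral matching is directional and
  accumulated both ways: a mutual nearest pair contributes 2. The
  default `ims_min = 2` therefore accepts one mutual pair.
* **Degenerate inputs.** Isolated voxels become flagged degree-0 nodes
  (so voxel conservation stays global); pure degree-2 cycles get one
  flagged anchor node and become self-loops; self-loops are excluded
  from angle pairing. A run in which no subtree gets assigned completes
  with an undetermined vein call and an all-zero label volume rather
  than failing.
* **Class canonicalization.** Within each relation component the
  smallest subtree id is class0. Disconnected relation components have
  no information linking their colourings; the phantom family always
  yields one matched component, and on real data the path-vote stage is
  the fallback. This is a known limitation.
* **Root choice.** The class root is the node with the largest mask
  distance-transform radius (local window search), overridable by a
  user coordinate; the anatomical root is the thickest point of a tree.
* **Lung sides.** Branch accuracy is reported per lung by a mid-sagittal
  split of the gold bounding box along a configurable axis when no lung
  mask is available.

## Problem sizes

The test suite runs unit fixtures (lines, Y/X crossings, random stars up
to 41³), 96³ depth-3 phantoms for module tests, and the full acceptance
family of ten 128³ depth-4 phantoms plus ten dense variants; the whole
suite completes in under two minutes on one CPU. The acceptance script
regenerates both families from its `--seed` and asserts nothing — it
reports the measured accuracies, coverage, vein-call count and oracle
deviations. The suite's asserted bounds are: mean branch accuracy
$\ge 90\%$ on the default family, $\ge 75\%$ with tripled adhesion
density, lumen coverage $\ge 0.95$, the vein call correct in 10/10
cases, and branch angles within $10^{-9}$ degrees of an independent
dot-product oracle.

## Known limitations

Adhesions of five or more branches are only greedily resolved and are
flagged rather than fully separated. Per-slice growth cannot label mask
voxels in slices without any skeleton seed (end caps of near-horizontal
tubes). The indirect class rule cannot link disconnected relation
components. Branch curvature between nodes is ignored by the default
`endpoint` representatives — `k_step` mode exists for strongly curved
vessels but is not the default because the far-node convention is the
simplest faithful reading of the geometry.
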