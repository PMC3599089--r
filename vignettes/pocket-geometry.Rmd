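---
title: "Grid geometry of pocket detection: conventions, parameters, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid geometry of pocket detection: conventions, parameters, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxpocket)
```

## The model

`voxpocket` treats a protein as a rigid union of van der Waals spheres
and asks a single geometric question at every point of its surface: *how
much of the surrounding space does the protein fill?* The answer — a
solid angle in steradians — separates convex bumps (< 2π), flat patches
(≈ 2π) and concave depressions (> 2π). Because ligands bind
overwhelmingly in depressions, clustering the most concave surface
elements and scoring each cluster by how deep and how voluminous its
cavity is yields a ranked list of candidate binding regions. Everything
is computed on a discrete voxel lattice; nothing is stochastic, so a
given input and configuration always reproduce the same output
byte-for-byte.

The assumptions are explicit: one rigid conformation (model 1 of NMR
ensembles, first alternate locations), protein `ATOM` records only
(ligands and waters are held out for evaluation), and geometry only — no
conservation, electrostatics or chemistry.

## Grid conventions

A voxel with 1-based index $(i,j,k)$ has its centre at
$\mathrm{origin} + s\,(i-1, j-1, k-1)$ with spacing $s$ (default 1 Å —
small enough that a 6 Å probe sphere holds ~900 voxels, and typical
proteins discretize to $10^4$–$10^5$ occupied voxels). A voxel is
occupied iff its **centre** lies inside some atom sphere; the
sphere-overlap alternative would bias all radii outward by up to half a
voxel diagonal and is not used. Surface/interior classification is by
6-connectivity, with out-of-bounds treated as exterior. The grid origin
is snapped to an integer multiple of the spacing, which makes
integer-Å translations of the input shift voxel indices without
changing any derived quantity.

The bounding box pads every atom sphere by at least the largest probe
radius used downstream (10 Å), so that no virtual sphere or scan ray can
leave the grid at a genuine surface voxel. If a sphere would leave the
grid anyway (a hand-built, under-padded grid), the solid-angle code
raises an error rather than silently clipping, because clipping biases
the denominator of the estimator.

## The solid-angle estimator and its boundary correction

For a surface voxel $v$ and probe radius $r$ (default 6 Å):

$$\mathrm{SA}(v) \;=\; 4\pi\,\frac{V_{\mathrm{in}}}{V_{\mathrm{sphere}}},$$

where $V_{\mathrm{sphere}}$ counts lattice voxels whose centres lie
within $r$ of $v$'s centre and $V_{\mathrm{in}}$ measures the occupied
ones among them: interior voxels with weight 1 and surface voxels with
weight $\tfrac12$ (`surface_weight`, configurable).

The half-weight is the one genuinely non-obvious numerical choice in
the package, so it deserves its arithmetic. A surface voxel's centre
sits on the discrete boundary, about half a voxel below the true
interface. Counting the boundary layer fully (weight 1) makes a flat
face read

$$\frac{(905+113)/2}{905}\cdot 4\pi \approx 2.25\pi$$

at 1 Å spacing (905 lattice points in the 6 Å ball, 113 in its central
plane) — 12.5 % above the 2π a flat surface must give, an error that
decays only linearly in the spacing, and one that breaks the defining
complementarity property of the solid angle (two shapes that fit
together must have solid angles summing to 4π; full counting gives
4.5π). Giving the boundary layer half weight restores, at default
resolution:

```{r flatface}
g <- generate_grid(shape_spec("cube"))
sam <- solid_angle_all(g, radius = 6)
pick <- function(x, y, z) sam$sa[abs(sam$x-x)<1e-9 & abs(sam$y-y)<1e-9 &
                                   abs(sam$z-z)<1e-9]
c(corner = pick(10,10,10)/pi, edge = pick(10,10,0)/pi,
  flat = pick(0,0,10)/pi)   # analytic: 0.5, 1, 2
```

and planar complementarity becomes exact. The raw occupied count
remains available (`surface_weight = 1`) for comparison with
integer-count implementations.

The vectorized `solid_angle_all()` accumulates the same integer counts
as the per-voxel `solid_angle_at()` and applies the same final
expression, so the two are bit-identical regardless of batching — the
package's replacement for a GPU-parallelism contract: results must be
independent of how the map is chunked.

## Candidate selection and clustering

The highest 20 % of surface voxels by solid angle (ties at the cutoff
all included, so the rule is permutation-invariant) are clustered by
single linkage: two candidates link iff their centres are within 20 Å
*and* their solid angles differ by at most `sa_band`. The distance is
Cartesian (20 Å spans many voxels, so grid adjacency cannot be meant).
The similarity band is not prescribed anywhere; the default
$0.1\cdot4\pi$ sr is one depth-bin width (next section), which keeps
the clustering consistent with the depth discretization. Each cluster's
anchor is its maximal-SA voxel, with lexicographic index tie-breaks so
that cluster identity, ordering and anchors are all deterministic and
input-order-independent. Only concave (high-SA) candidates are
clustered; convex groups are not formed.

## Depth and volume indicators

**Depth.** Solid angles map to integer bins: 5 for
$\mathrm{SA} > 0.9\cdot4\pi$, then 4, 3, 2, 1 for each successive
10 %-of-$4\pi$ band down to $0.5\cdot4\pi$ (= 2π), and −1 below — i.e.
flat-or-convex voxels are penalized, not zeroed. Band edges belong to
the lower bin, and exactly 2π is −1. Comparisons carry a $10^{-12}$
relative guard so a boundary value computed by any algebraically
equivalent floating-point route bins identically. A cluster's depth
indicator is the plain mean of its members' bins, −1 values included;
clusters with negative means are retained and rank last.

**Volume.** From the anchor, every empty voxel whose centre is within
10 Å is probed along 7 bi-directional lines — the 3 axes and the 4 body
diagonals $(\pm1,\pm1,\pm1)$, the only four diagonal lines through a
lattice point consistent with a 7-line scan — marched in unit index
steps. A line is *interior* iff both of its rays hit protein before
leaving the (padded) grid; a ray that exits the grid is open to solvent.
Empty voxels with ≥ 4 interior lines count toward the cavity volume.
The indicator is a voxel count, not an Å³ volume.

## Ranking

$$\mathrm{RV}(v) = \frac{\mathrm{CD}_{\mathrm{avg}}(v)}{\mathrm{CD}_{\max}}\,w_1
                 + \frac{\mathrm{CV}(v)}{\mathrm{CV}_{\max}}\,w_2,
  \qquad w_1 + w_2 = 1,$$

with maxima taken over the clusters of the query protein. The original
system trained its weights by cross-validation on a benchmark this
package deliberately does not bundle, and the trained values were never
published; `voxpocket` uses the neutral $w_1 = w_2 = 0.5$ and exposes
both. Ties break by larger volume, then smaller cluster id. If no
cluster has positive average depth, or all volumes are zero, the run
reports `no_rankable_region` — on a convex body that is the correct
answer, not a failure.

## Evaluation

The benchmark literature scores binding-site predictors with
sensitivity, specificity, accuracy, PPV and MCC under a top-1..3
success rule, but leaves the matching unit unstated. This package's
reconstruction — the largest free choice in the artifact — is
residue-level: a region matches the truth if any member voxel centre is
within `match_distance` (4.5 Å, a conventional heavy-atom contact
cutoff) of an annotated residue; a residue is predicted positive iff it
is within that distance of a *matching* top-k region. Zero-denominator
metrics are reported as 0 and flagged. Truth tables are two-column
(chain, resseq) files, or can be derived from a bound ligand's `HETATM`
contacts.

## The synthetic world

`shape_spec()` / `generate_grid()` / `generate_pdb()` build analytic
solids — spheres, slabs, cubes, cylindrical wells, enclosed voids,
complementary box pairs, and a sphere with a carved spherical-cap
pocket — both as exact occupancy grids and as pseudo-atom PDB files
(carbons on a 1.4 Å lattice, below one atom diameter, so the sphere
union has no internal holes; re-voxelization tracks the analytic
boundary to within about one atom radius). Fixtures are byte-exact
deterministic; optional placement jitter is seeded.

The default pocket fixture is a 9 Å host sphere carved by a 6 Å sphere
centred 6.5 Å up the z-axis: mouth radius ≈ 6 Å, depth ≈ 6 Å. Those
proportions were chosen once, for two stated reasons: the concave wall
must hold roughly 20 % of the surface so the fixed candidate rule lands
its cutoff inside the wall population rather than dredging up convex
noise, and at 1 Å spacing the wall must be gently curved enough that
neighbouring voxel layers differ by less than the linkage band.
Narrower or shallower pockets at this resolution fragment into SA
shells or drown among flat-face candidates — the `cylindrical_well`
PDB fixture does exactly that (a narrow well on a wide slab yields
`no_rankable_region` under the 20 % rule) and is kept as an honest
illustration of that resolution limit.

Ground truth for pocket fixtures is defined from geometry alone: the
fixture is re-voxelized, the pocket wall is the set of surface voxels
face-adjacent to carved-void voxels lying at least 1.5 Å below the host
surface (the convex rim, which no concavity detector can claim, is
excluded), and the truth is every residue with an atom within 4.5 Å of
that wall. Under this definition the pipeline's top-1 region recovers
the truth exactly (all five metrics 1.0) across a wide plateau of the
depth margin (1–3.5 Å), so the green test is not balanced on a knife
edge.

What a green synthetic run does **not** establish: performance on real
proteins. Pseudo-atom solids have no chemistry, no sidechain texture,
no multi-pocket competition, and their truth is geometric by
construction. The synthetic suite validates the machinery — estimator
values on known analytic shapes, exact oracle equivalence of the
vectorized paths, end-to-end coherence — not biological accuracy.

## Known limitations

* Van der Waals occupancy only: no probe-rolled (solvent-excluded)
  surface, so very narrow clefts that a water could not enter can still
  register as concave.
* The fixed 20 % candidate rule is scale-free but not size-free: on
  large flat-dominated bodies, small true pockets can fall below the
  cutoff (see the well fixture).
* Single-linkage clustering can chain a pocket wall to its rim through
  intermediate solid angles; on the default fixture this produces a
  separate shallow rim cluster that correctly ranks last.
* The ranking weights are untrained defaults; on real data they are the
  first thing to tune.
* Pairwise clustering is $O(n^2)$ in candidate count — fine up to a few
  thousand candidates (typical single-domain proteins at 1 Å), costly
  beyond.
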