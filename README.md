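# voxpocket

Geometric detection and ranking of candidate protein–ligand binding
pockets from structure alone.

Ligand-binding sites are, overwhelmingly, concave depressions on the
protein surface. `voxpocket` finds them with a purely geometric,
deterministic pipeline aimed at structural bioinformaticians who need
fast, reproducible pocket calls on PDB files — as a first pass before
docking, for binding-site annotation, or as a baseline detector in
method comparisons.

## Method

1. **Voxelization.** Atoms (with van der Waals radii from a Bondi-style
   table) are discretized onto a cubic grid (default 1 Å). A voxel is
   occupied iff its centre falls inside an atom sphere; occupied voxels
   with an empty face-neighbour are *surface*, the rest *interior*.
2. **Solid angle.** Every surface voxel *v* gets the solid angle
   subtended there by the protein body,

   SA(*v*) = 4π · V_in / V_sphere,

   where V_sphere counts the voxels of a virtual sphere (default radius
   6 Å) centred on *v* and V_in the occupied ones among them (surface
   voxels count 1/2 — a boundary correction that makes a flat face read
   exactly 2π; see the vignette). SA < 2π means convex, ≈ 2π flat,
   > 2π concave.
3. **Clustering.** The highest 20 % of surface voxels by solid angle are
   grouped by single linkage (link = within 20 Å **and** solid angles
   within 0.1·4π sr); each cluster's maximal-SA voxel is its *anchor*.
4. **Depth and volume.** Per cluster: the average *depth indicator*
   (solid angles mapped to bins 5,4,3,2,1,−1 over 10 %-of-4π steps down
   to 2π) and the *cavity volume* (empty voxels within 10 Å of the
   anchor having ≥ 4 of 7 bi-directional rays blocked by protein).
5. **Ranking.** RV = (CD_avg/CD_max)·w₁ + (CV/CV_max)·w₂ with
   w₁ = w₂ = 0.5 by default; regions are reported in decreasing RV.

Evaluation against annotated binding residues uses the standard
confusion-matrix metrics (sensitivity, specificity, accuracy, PPV, MCC)
and the top-1..3 success rule: a trial succeeds if any of the top-k
regions touches the true site within 4.5 Å.

## Worked example

The package ships a generator of analytic solids, so the whole pipeline
can be exercised without downloading structures. A 9 Å pseudo-protein
sphere with a carved spherical-cap pocket (mouth ≈ 6 Å, depth ≈ 6 Å),
rendered as ~900 pseudo-atoms:

```r
library(voxpocket)
fix  <- generate_pdb(shape_spec("sphere_with_cap_pocket"))
pred <- pocket_predict(fix)
print(pred)
#> <pocket_prediction> sphere_with_cap_pocket.pdb [ok]
#>   911 atoms | 3836 occupied voxels | 1102 surface voxels | 2 ranked region(s)
#>   rank       rv size anchor_x anchor_y anchor_z  avg_depth volume_voxels
#> 1    1 1.000000   61       -2       -1        1  2.5409836            78
#> 2    2 0.370417  164       -4       -1        4 -0.6585366            78
```

Region 1 — 61 concave voxels whose anchor (−2, −1, 1) sits on the deep
pocket wall, average depth bin 2.5 and 78 enclosed cavity voxels — is
the carved pocket; region 2 is the shallow rim band (negative average
depth, ranked last). Scoring against the fixture's ground-truth
pocket-lining residues:

```r
ev <- pocket_evaluate(pred, fix$truth, k = 1)
r  <- ev$results$top1
#> top-1 success: TRUE | sens 1.00 spec 1.00 acc 1.00 ppv 1.00 mcc 1.00
```

The top-1 region recovers exactly the annotated residues. On a control
convex sphere (no pocket) the pipeline reports a clean
`no_rankable_region` instead of inventing a site.

For real structures: `pocket_predict("1abc.pdb", run_config(chains = "A"))`,
truth from a bound ligand via `pocket_evaluate(pred, "ligand")`.

## Command line

```sh
Rscript inst/cli/voxpocket.R fixtures --kind sphere_with_cap_pocket --out fix
Rscript inst/cli/voxpocket.R predict  --pdb fix.pdb --out pred
Rscript inst/cli/voxpocket.R evaluate --pdb fix.pdb --truth fix.pdb.truth.tsv \
    --out eval.json -k 3
Rscript inst/cli/voxpocket.R summarize --reports eval.json --out summary.tsv
```

## Scope

Rigid single-conformation geometry only: no mmCIF, no probe-rolling
(Connolly) surfaces, no GPU kernels, no physicochemical scoring, no
re-training of the ranking weights. See `vignettes/pocket-geometry.Rmd`
for the numerical conventions, parameter rationale, and limitations.
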