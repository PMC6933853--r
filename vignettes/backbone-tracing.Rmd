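---
title: "Tracing protein backbones in cryo-EM maps by iterative segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing protein backbones in cryo-EM maps by iterative segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catrace)
```

## The problem

A single-particle cryo-EM reconstruction at 2–4.5 Å resolution shows the
path of a protein's main chain as a ribbon of relatively continuous high
density, with side chains branching off at regular intervals. Building an
ab initio Cα model into such a map means answering three questions: which
density belongs to one continuous chain, where does the chain run inside
that density, and where along that run do the Cα atoms sit.

`catrace` answers them the way an experienced structural biologist working
at a graphics display would: find the obvious pieces first at a high
contour level, then lower the contour gradually and watch density extend
and connect — but stop trusting a connection the moment the density starts
to *branch*, because branching usually means side-chain density of two
adjacent chains has fused, and tracing through it would cross between
chains.

## The procedure

A run of `trace_and_build()` has six stages.

**1. Segmentation by iterative contour lowering** (`grow_segments()`).
Connected regions — maximal sets of grid points above a contour level,
adjacent under 26-connectivity — are tracked down a descending schedule of
contour levels. A region grows as the level drops; when two accepted
regions first become connected they are merged into one; and a region that
would become branched is frozen at its last unbranched level and masked
out of the working map, except for the very ends of its trace, which stay
so that later, weaker connections can still attach there. A side arm
counts as branching when it is longer than `branch_cutoff` (10 Å): real
side chains are short, so a longer arm means fused density between chains.

**2. Path tracing** (`region_endpoints()`, `min_weight_path()`). Within a
region, steps between neighbouring voxels are weighted by
$w = \left(\frac{\rho_{max}-\rho}{\rho_{max}-\rho_{min}}\right)^a$
with $a = 2$ by default, so the minimum-weight path between two points is
the route with the highest minimum density — which for proteins is the
main chain, not the side chains. The end points of a region are found by a
double sweep: from the region's density maximum A, find the point B whose
minimum-weight path is longest, then from B the point C likewise; the B–C
path is the region's trace and its unweighted length is the region's
length. Two details matter here:

* *Which length is "furthest".* Along high-density ridges the weights are
  nearly zero, so ranking candidate end points by accumulated *weight* is
  degenerate — fringe voxels reached through a few expensive steps win
  over the geometric chain ends. B and C are therefore selected by the
  unweighted (Ångström) length of the minimum-weight path, the same
  measure that defines the region length. The route itself is still the
  minimum-weight route.
* *Symmetric step costs.* Weighting a step purely by the voxel being
  entered makes path cost direction-dependent; by default each step costs
  the mean of its two endpoint weights times the Euclidean step length in
  voxels (so the cost approximates a line integral and diagonal steps are
  not favoured). The entered-voxel form is available via
  `path_weight_params(symmetric = FALSE)`.

**3. Ridgeline markers and morphing** (`extract_bones()`,
`morph_path()`). Unordered off-grid "bones" markers are placed at the
highest-density points along ridgelines: each region voxel's 3×3×3
neighbourhood is fitted with a quadratic; where the density is a local
maximum in the two directions transverse to the local ridge (both
transverse Hessian eigenvalues negative), the point is kept and refined by
the Newton shift within the transverse plane, clamped to one voxel;
markers closer than half a voxel to a denser marker are thinned away. The
traced path is then morphed onto the bones: each path point receives the
average of the shifts that would move it and its `window_halfwidth = 5`
neighbours on either side onto their nearest bones points, capped at
`max_shift = 2` Å per iteration (so a path cannot jump to a parallel
ridge), for `n_iterations = 3` passes.

**4. Cβ identification** (`side_chain_bones()`, `cbeta_candidates()`).
Bones points within 1.5 Å of the path are discarded as main chain; what
remains marks the side chains. Each path point seeds the centroid of the
remaining bones within 3 Å; the centroids are clustered (single linkage,
cut at 2 Å — Cβ atoms of neighbouring residues are ≥ ~5 Å apart, so 2 Å
separates stubs cleanly) and cluster centres become candidate Cβ
positions. Centres that fall back within 1 Å of the path are discarded as
main-chain contamination: a genuine side-chain take-off centroid sits off
the path by roughly a Cα–Cβ bond length.

**5. Cα placement, optimization, refinement** (`place_initial_ca()`,
`optimize_ca()`, `refine_ca()`). The residue count follows from the
morphed path length divided by the target Cα–Cα distance of 3.8 Å.
Positions are chosen on the path by a small dynamic program over
discretized arc positions: consecutive sites may be 2.8–4.8 Å apart with
a quadratic penalty away from 3.8 Å, and each Cβ candidate projects onto
the path and digs a Gaussian reward well (width 0.6 Å) at its arc
position, anchoring the register where a side chain takes off. The
arrangement is then improved by greedy first-improvement search over
insert/delete/extend moves under a four-term sum-of-squares placement
score (Cα–Cα distance deviation; distance from each Cβ candidate to its
nearest Cα beyond a 1 Å dead zone; normalized density shortfall at Cα–Cα
midpoints; midpoint distance to the path; weights `(1, 1, 1, 1)`, each
term divided by its own count). Finally coordinates are refined by
bounded quasi-Newton minimization of a composite of start-deviation,
distance-deviation and density terms (weights 0.1 / 1 / 1), each Cα
moving at most 2 Å.

**6. Secondary structure, direction, combination** (`find_helices()`,
`splice_ss()`, `choose_direction()`, `combine_models()`). Helices are
located by template search (below) and spliced into the model wherever a
run of fragment Cαs overlaps a run of model Cαs within ¾ of the target
Cα–Cα distance with crossovers at both ends, since template coordinates
are usually more regular than traced ones. Each chain is scored in both
directions (H-bond score plus density-fit score `U`) and the better
direction kept, with ties going to the forward chain. All chains are then
ranked by `U` and length, and residues of lower-ranked chains lying
within 2 Å of a retained Cα are removed; fragments shorter than 3
residues are dropped.

### Scores

* `U = 10 (CC − 0.5) √N` (`density_fit_score()`): `CC` is the Pearson
  correlation between the map and model-based density within 3 Å of the
  model's atoms, and `N` the number of atoms. Above `CC = 0.5` a bigger
  model scores higher; below, it scores lower; at 0.5 size is irrelevant.
* H-bond score (`hbond_score()`): the number of good hydrogen bonds
  (estimated donor–acceptor heavy-atom distance ≤ 3.5 Å) plus half the
  number of poor ones (helical or sheet arrangement, but 3.5–5 Å).
  Secondary structure and partner pairs come from Cα-only geometry
  (`assign_ss_from_ca()`): Cα(i)–Cα(i+3) and Cα(i)–Cα(i+4) distance
  windows for helices, extended stretches plus a 4.0–5.5 Å ladder partner
  for sheets. The recognition windows (4.6–6.4 Å and 5.6–7.8 Å) are
  deliberately wider than ideal-helix values so that a distorted helix is
  still recognized as a helical *arrangement*; whether each bond is good
  or poor is judged from the estimated distance, reconstructed from
  peptide midpoints with fixed offsets (the C=O bond plus the N offset,
  1.8 Å in total for helices; 2.0 Å off the Cα–Cα ladder distance for
  sheets).
* `T = S + CC √N` (`combined_score()`): the combined model score. The
  sequence-likelihood term `S` requires side-chain fitting against an
  empirical rotamer-density library and is out of scope here; `S` is
  accepted as an externally supplied scalar so the formula itself is
  available.

### Helix template search

`find_helices()` works in two stages because the helical phase is
unknowable until the axis is right. For each of the strongest local
density maxima, candidate axis orientations from a Fibonacci hemisphere
are scored by correlating *azimuthally averaged* map rings around the
trial axis against the azimuthal average of an ideal 8-residue helix
template density — averaging makes the score independent of helical
phase and of the bead-like texture of discrete atoms. The best placement
is re-centred (the seeding maximum sits on the backbone spiral, about one
backbone radius off the true axis) and refined by Nelder–Mead over tilt
and position, twice. A placement is accepted when the full and both
axial-half correlations pass the cutoff, the on-axis density is
substantial (at these resolutions a helix images as a solid rod, whereas
a template lying *across* a chain has empty axis ends), and the averaged
signal stands at least two map standard deviations above the map mean
(pure fluctuations never do). Finally the spin about the axis and the
axial shift are fitted by maximizing map density at the template's atom
positions, and overlapping placements are removed by axis-segment
distance. Strand templates are not searched: at 3–4.5 Å a 5 Å-pitch
two-residue repeat is too weak a density motif for reliable rigid
matching, so strands are built by tracing and may be supplied externally
as fragments.

## Synthetic maps and what they do (not) show

`synthesize_map()` produces the ground-truth maps every test runs
against: each atom of a known model contributes an equal-amplitude
isotropic Gaussian of width σ = 0.225 × resolution, plus optional i.i.d.
Gaussian noise scaled to the noise-free peak. Two pseudo-atoms are
inserted along every consecutive Cα–Cα bond before smearing
(`backbone_interp = TRUE`), standing in for the N, C and O atoms that
make main-chain density continuous in experimental maps — without them a
Cα/Cβ point model at 3 Å disintegrates into disconnected beads that no
contour-connectivity method could trace, which would test nothing.
`map_model_cc()` uses the same forward model, including the interpolated
backbone.

The generator emulates the features the method actually exploits:
main-chain density that is continuous and locally strongest, side-chain
density branching off at known take-off points, inter-chain side-chain
contacts (the `two_chain_contact` fixture), and additive noise. It does
**not** emulate resolution anisotropy, B-factor variation along the
chain, map sharpening artefacts, solvent noise structure, or the
scattering differences that distinguish charged side chains in cryo-EM
maps. Passing the recovery tests therefore demonstrates that the
geometric machinery — segmentation, branch rejection, tracing, register
assignment — is correct under controlled conditions; it does not certify
recovery rates on experimental maps.

`make_test_model()` builds the ground-truth geometries: an ideal α-helix
(1.5 Å rise and 100° twist per residue, radius solved so consecutive Cαs
are exactly 3.8 Å apart), a pleated extended strand, a helix–loop–helix
hairpin whose two helix axes end up ≈10 Å apart (typical packing, and
close enough that side-chain density bridges the helices at low contour —
precisely the situation branch rejection exists for), and a two-chain
contact whose facing Cβ stubs approach to a configurable distance.

## Numerical and design choices

* **Grid convention.** 0-based grid indices; Ångström position =
  origin + index × voxel size; all algorithms work in Ångströms. Maps are
  normalized at read time to an x-fastest layout regardless of the MRC
  header's axis permutation.
* **Threshold schedule.** Geometric descent over 40 levels (20 in quick
  mode) from the 99.9th percentile of map values down to the floor,
  mean + 1 SD; geometric because density spans orders of magnitude near
  peaks. A linear schedule is used if the floor is non-positive.
* **Masking.** A frozen region is masked to a finite sentinel
  (floor − 1 SD, never NaN) together with its one-voxel shell, excluding
  end caps and voxels claimed by other regions. Masking only the region's
  own points leaves a thin low-density sleeve around the masked chain
  that respawns as spurious fragment regions at lower contours.
* **Merge bookkeeping.** A merge consumes both parents and re-derives the
  child's branch status on the original (unmasked) density; a branched
  child reverts the merge and freezes the parents. A parent set whose
  merge branched is never retried — density only accretes as the contour
  drops, so a branched merge stays branched. When a region was seeded
  from fragment atoms rather than a contour (all grid points within 3 Å
  of the fragment's atoms), its point set is reconciled with the contour
  at first contact, keeping every region's points contour-consistent.
* **Chain acceptance.** Chains whose map-model correlation is below 0.5 —
  the point where `U` changes sign — are discarded before combination.
  On a pure-noise map this leaves nothing, as it should.
* **Splice gating.** A detected helix fragment is spliced only when the
  mean map density at its Cαs is at least 0.8 of that at the traced
  model's Cαs. A rigid 8-residue template misregisters on curved or
  tightly packed helices; since a misregistered template sits in the
  valleys between backbone density peaks, density support separates good
  placements from bad ones sharply.
* **Determinism.** Every stochastic step (noise, move-order shuffling) is
  seeded; ties in the path search break lexicographically; per-region
  work is independent, and results are merged in region order, so the
  worker count never changes the output.
* **Degenerate inputs.** A flat region gives zero weights everywhere and
  an empty bones set; a single-point region is its own trace with length
  0; a map entirely below the floor yields no regions and an empty model
  list; refinement returns its best-so-far state with a convergence flag
  if the iteration cap (400) is reached.

## Problem sizes

The test-suite and validation runs use helix–loop–helix chains of 20–60
residues on ~30×25×50-voxel maps at 1 Å voxels and 3 Å nominal
resolution, path-search oracles on ≤ 4×4×4 grids (exhaustive
Floyd–Warshall comparison), and segmentation oracles on ≤ 16³ grids
(brute-force flood fill). These sizes were chosen so that ground truth is
unambiguous and exhaustive reference computations are feasible; the
algorithms themselves are resolution- and size-agnostic, with cost
dominated by the per-level connected-component pass and the per-region
Dijkstra sweeps (both linear-ish in voxels, in compiled code).

## Known limitations

* Chain direction is decided by H-bond and density-fit scores computed
  from Cα/Cβ geometry only. A chain and its exact reversal have identical
  scores under both, so exact reversals tie and the forward direction is
  kept; genuine discrimination requires the side-chain fitting stage,
  which is out of scope. The selection machinery is in place and
  discriminates whenever the two candidates differ geometrically.
* The sequence-likelihood score `S`, rotamer fitting, all-atom
  reconstruction and real-space refinement are out of scope; `T` accepts
  `S` as input.
* True branches (disulfides, covalent ligands) are not handled specially:
  the branch cutoff leaves them as separate fragments.
* Strand template search is not implemented (see above); strands are
  traced or supplied.
* The synthetic forward model is a stand-in for experimental maps, not a
  claim of equivalence (see above).
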