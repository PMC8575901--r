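---
title: "Room-temperature vs cryogenic Photosystem I: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Room-temperature vs cryogenic Photosystem I: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psigeom)
```

## The scientific problem

Photosystem I (PS I) is a ~1 MDa trimeric membrane pigment–protein complex
whose two pseudo-symmetric cofactor branches (ending in the phylloquinones
A~1A~/A~1B~ and the [4Fe4S] cluster F~X~) transfer electrons with markedly
different kinetics. Room-temperature (RT) serial femtosecond crystallography
structures of PS I differ from cryogenic ones in two measurable ways that
this package quantifies:

1. **Anisotropic thermal expansion.** The whole complex expands in the
   membrane plane at RT while staying essentially unchanged perpendicular to
   it. The natural readout is the set of ~96 chlorophyll Mg positions,
   expressed in a cylindrical frame around the complex's own electron
   transfer axis.
2. **Phylloquinone-pocket rearrangements.** The aromatic side chains
   π-stacked on the two quinones (PsaA-Phe689, PsaB-Phe669, PsaA-Trp697,
   PsaB-Trp677 and the symmetry-breaking PsaB-Trp673) change their
   ring-plane angles and contacts between cryo and RT models; these angles
   are small numbers with structural error bars that must themselves be
   estimated.

Upstream of any such comparison sit three serial-crystallography
computations that the package also implements: resolution of the merohedral
indexing ambiguity (space group P6~3~ on a hexagonal lattice), the CC~1/2~
resolution cutoff of the merged data, and classification of the crystal
packing polymorph from per-lattice unit-cell distributions.

## Geometric conventions

**The axial frame.** The P700 centre is the midpoint of the two special-pair
Mg atoms; the F~X~ centre is the centroid of the four cluster irons. The
frame origin is the midpoint of these two centres and the axis points from
P700 toward F~X~ (the membrane normal, to a good approximation). Each
chlorophyll Mg is decomposed into a radial coordinate (distance from the
axis, "along the membrane plane") and a signed axial coordinate
("perpendicular to the membrane").

**Per-structure frames, no superposition.** `expansion_profile()` decomposes
each structure in its *own* frame. A global rigid-body superposition would
absorb part of the expansion into the fit and bias deltas toward zero; using
internal frames makes the profile exactly invariant under independent rigid
motions of either model (a property the test suite verifies with random
motions). A superposition-based variant remains available behind
`superpose_first = TRUE` as a sensitivity check.

**Ring planes and stacking angles.** Ring planes are total-least-squares
planes (eigenvector of least variance of the centred ring-atom coordinates);
plane fits use only planar moieties — the 6 phenyl carbons, the 9 indole
atoms, and the naphthoquinone head (10 fused-ring carbons plus the two
carbonyl oxygens; the isoprenoid tail is excluded). Interplanar angles are
folded to [0°, 90°], since stacking angles are reported acute; the fold also
makes the angle invariant to the arbitrary sign of a fitted normal.

**Stacking distances, three ways.** The literature rarely states whether a
printed stacking distance is a closest contact or a centroid separation.
Every `stacking_report()` record therefore carries the minimum atom–atom
contact, the centroid–centroid distance, and the distance from the partner
centroid to the ring plane; the headline comparisons use minimum contact.

**"Rotation out of plane".** A pocket ring's change between two models is
reported as the difference of the two acute interplanar angles (e.g. 73° at
RT − 26° cryo = 47°), not as a 3D rotation decomposition — that is what a
printed "rotates by 47°" means operationally.

**Radius of gyration.** Uniform weights over non-hydrogen, non-water atoms
by default (mass weighting behind a flag). The Rg convention behind any given
published value is rarely explicit; uniform weighting is the simplest
reproducible choice and the flag lets a user match alternatives.

**Altlocs and hydrogens.** `collapse_altlocs()` keeps, per (chain, residue,
atom), the highest-occupancy record, breaking ties toward the
lexicographically smallest altloc, and removes hydrogens; all downstream
geometry is heavy-atom. Whether published analyses collapsed altlocs is
usually unstated; collapsing is assumed because it is deterministic and
conventional.

## Serial-crystallography algorithms

**Coset operators.** In a merohedral space group the crystal point group is
a proper subgroup of the lattice point group, so every indexed shot admits
several equally valid index settings. `coset_operators()` enumerates one
representative per right coset of the crystal group in the lattice group
(proper rotations only; intensities are treated as Friedel-symmetric). For
point group 6 on the hexagonal lattice this yields the identity and the
two-fold `(h,k,l) -> (k,h,-l)`. Representatives are chosen as the simplest
coset member (fewest/smallest entries, then fewest minus signs) so the
printed operator matches the conventional twin law. An exhaustive
enumeration oracle in the tests confirms the coset counts for every
supported pair.

**Canonical indices.** Merging correctness depends on a fixed
asymmetric-unit convention: every index is mapped to the lexicographically
smallest member of its orbit under the point group plus Friedel inversion.

**Tranche-based ambiguity resolution.** All-pairs correlation clustering
costs N²M² correlations (N shots, M operators), which is intractable at
serial scale. `resolve_ambiguity()` splits the data into consecutive
tranches (default 250 shots) sharing a fixed overlap (default 25), resolves
each tranche independently, and reconciles: each new tranche's solution is
relabeled by the global operator that wins a majority vote on the shots
shared with the already-reconciled set (ties resolve to the identity and are
logged). The per-tranche step is an alternating assignment/reference-update
optimisation over the precomputed per-relative-operator correlation
matrices, with seeded multi-starts; the solution is gauge-fixed so the first
shot carries the identity. Within a tranche correlations are computed by
crossproducts of zero-filled and indicator matrices (numerically identical
to pairwise-complete Pearson, verified against `stats::cor`), and the total
workload is recorded: at 1000 shots with tranches of 250 it is 13% of the
full-pairwise bound, and it grows linearly in the number of shots at fixed
tranche size. Ground-truth agreement is always assessed *up to a global
operator*, the gauge freedom inherent to the problem.

**CC~1/2~ and the cutoff.** Shots are split at the shot level (the serial
norm) into two seed-deterministic halves, each half is merged, and the
Pearson correlation of common merged intensities is computed in
equal-population resolution bins. The resolution cutoff scans from low to
high resolution and stops at the last bin before CC~1/2~ first *rises* —
beyond that point no useful signal is being added. Because the per-bin
CC~1/2~ is itself a noisy estimate, a rise smaller than `tol` (default 0.02,
the fluctuation scale at a few hundred reflections per bin) is treated as
sampling noise; `tol = 0` restores the strict rule. Bins with fewer than 3
common reflections are flagged undefined and skipped.

**Isoform classification.** Per-lattice unit-cell samples are fit with 1-
and 2-component Gaussian mixtures (EM via mclust, deterministic model-based
initialisation). The verdict is *bimodal* only when the 2-component model
wins by more than 10 conventional BIC points **and** the component means are
separated by more than twice the pooled component sd — the double condition
avoids declaring a polymorph from a marginally better likelihood. A
zero-variance sample short-circuits to a unimodal verdict with a floored sd.
The pooled a/c parameter exists because a monoclinic polymorph shows its
bimodality in the combined a- and c-axis histogram (maxima near 281 and
286 Å) whereas a hexagonal isoform is unimodal near 285 Å.

## Coordinate-precision estimation

The precision of a pocket angle is estimated by perturbation: observed
amplitudes are moved by `u |F_obs − F_model|` with `u` drawn independently
per reflection, the model's coordinates are kicked (isotropic Gaussian with
prescribed RMS), the model is re-refined against each perturbed set, and the
statistic of interest is read across the ensemble (conventionally 100
trials). The perturbation distribution is not standardised; uniform on
[−1, 1] is the minimal reading of "within ± the residual" and is the
default, with a truncated Gaussian available. Negative perturbed amplitudes
are clamped to zero and counted. Crystallographic re-refinement is **not**
reimplemented here: `refinement_hook()` wraps an external refinement command,
and for self-contained runs `make_model_ensemble()` stands in for
re-refinement by rotating designated ring sets about random in-plane axes
with angles ~ N(0, σ²). When both rings of a stacked pair are jittered
independently and their base angle is away from the 0°/90° folds, each ring
contributes σ²/2 to the interplanar-angle variance, so the ensemble sd of
the angle recovers σ — the property the tests check at σ = 1°, 2°, 5°.

## The synthetic data generators

Every pipeline is exercised without downloads by seeded generators that are
pure functions of (spec, seed):

* `make_toy_complex_pair()` — Mg marker "chlorophylls" on a cylindrical
  lattice about a synthetic P700–F~X~ axis (defaults: 96 chlorophylls, a
  30 Å axis, antenna radii 10–55 Å), four Fe markers, and hexagonal ring
  pairs at prescribed angles/separations (defaults mirror the
  characteristic pocket geometries: 13°/3.9 Å, 73°/3.3 Å, 16°/3 Å,
  13°/3 Å, 50°/3.5 Å, 45°/7 Å). The alternate structure multiplies radial
  coordinates by `radial_scale` (default 1.005, the magnitude of in-plane
  thermal expansion) so the ground-truth deltas are known exactly.
* `simulate_shots()` — a Wilson-like (squared-normal) reference intensity
  table over canonical indices *closed under the twin operator* (a
  measurable reflection set contains both twin mates; twin-invariant
  classes carry no assignment information and are excluded), per-shot
  random subsets (default 30% observed), lognormal multiplicative noise
  (default cv 0.2, optionally growing with resolution), and a known
  fraction of shots (default 50%) reindexed by the twin operator.
* `simulate_cells()` — Gaussian-mixture per-lattice cell samples.
* `make_model_ensemble()` — the angular-jitter ensembles above.

What the generators deliberately do **not** emulate: diffraction physics
(no partiality model, detector geometry or spot-shape effects), cofactor
chemistry beyond the marker atoms the registry needs, and refinement
behaviour. Passing the self-contained tests therefore demonstrates the
correctness of the *computations* under the stated statistical conditions,
not the behaviour of the full experimental pipeline on raw frames.

## The cofactor registry

Chain labels and cofactor numbering differ between depositions, so all
named targets resolve through an editable YAML registry keyed by dialect.
For deposited PS I entries the protein residues use their deposited
numbers; the phylloquinones are selected by residue-name sweep per chain;
F~X~ is the [4Fe4S] cluster outside the F~A~/F~B~-bearing subunit; and P700
is the closest Mg–Mg pair of the chlorophyll sweep (the special pair is
~6.3 Å apart, well below any antenna pair). ET-chain/connecting branch tags
for deposited dialects use axial proximity (the 6 Mg nearest the axis, then
the next 2); the synthetic dialect tags explicitly.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to make every statistical check sharp at desk scale: 1000
shots × 2000 reflections for ambiguity resolution (tranches of 250,
overlap 25), 120 shots × 4000 reflections for the cutoff recovery, 1000
lattices × 20 seeds for isoform verdicts, 100-model ensembles, and 20 000
reflections for the perturbation bound. Tolerances follow from the
constructions: exact-by-construction quantities are asserted to numerical
precision; sampled quantities to 3–4 standard errors of their estimators.

Degenerate inputs are first-class: collinear ring atoms, coincident frame
centres, single-abscissa regressions, all-undefined correlation matrices,
zero-variance cell samples and empty selections all raise (or log) specific
errors rather than propagating NaNs.

## Known limitations

* The desk-scale reproductions on deposited coordinates require the 1JB0
  and 7M75 files, which are not shipped; `analysis/06_deposited_structures.R`
  and the corresponding acceptance checks run only once those files are
  placed under `deposited_dir()`.
* No reciprocal-space refinement, map calculation, spot finding or
  integration; the serial tools start from integrated per-shot intensity
  lists.
* Per-reflection error-model scaling during merging is out of scope;
  `merge_shots()` averages with multiplicities and propagated sigmas.
* The registry's deposited dialects encode selector heuristics (closest
  Mg–Mg pair, residue-name sweeps) that are robust but should be reviewed
  against any new deposition before use.
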