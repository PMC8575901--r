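# psigeom

Geometry and serial-crystallography analysis of room-temperature (RT) vs
cryogenic structures of Photosystem I (PS I), the trimeric membrane
pigment–protein complex that drives light-induced transmembrane electron
transfer.

RT serial femtosecond crystallography structures of PS I differ from
cryogenic ones in subtle, quantifiable ways. This package is for structural
biologists who want to compute those quantities reproducibly:

* **Anisotropic expansion of the chlorophyll lattice.** Each structure is
  decomposed in its own cylindrical frame built from the electron-transfer
  axis: origin midway between the P700 centre (midpoint of the special-pair
  Mg atoms) and the F<sub>X</sub> centre (centroid of the four cluster
  irons). For every chlorophyll Mg with radial coordinate *r* (distance
  from the axis, i.e. in the membrane plane) and axial coordinate *z*, the
  profile reports Δr and Δz between two models, their means and the radial
  gradient dΔr/dr (reported per 10 Å, by OLS with a Theil–Sen cross-check).
* **π-stacking geometry of the phylloquinone pockets.** Total-least-squares
  ring planes, acute interplanar angles θ = arccos|n̂<sub>a</sub>·n̂<sub>b</sub>|
  folded to [0°, 90°], and three distance conventions (minimum contact,
  centroid–centroid, centroid-to-plane) for the Phe/Trp–quinone pairs, plus
  signed angle changes between a cryo and an RT model.
* **Coordinate-precision estimation.** Structure-factor perturbation
  F′ = F<sub>obs</sub> + u·|F<sub>obs</sub> − F<sub>model</sub>|,
  u ~ U(−1, 1) per reflection, coordinate kicking, and geometry statistics
  over a re-refined model ensemble (an external refinement hook; a seeded
  synthetic ensemble generator stands in for self-contained runs).
* **Serial-crystallography utilities.** Coset-decomposition reindexing
  operators for merohedral space groups (for point group 6: identity and
  (h,k,l)→(k,h,−l)), tranche-based resolution of the indexing ambiguity
  (reducing the N²M² all-pairs correlation cost to ~NM² with overlapping
  tranches reconciled by majority vote), merging under an operator
  assignment, half-dataset CC<sub>1/2</sub> per resolution bin with a
  monotonicity-based resolution cutoff, and unit-cell isoform
  classification by 1- vs 2-component Gaussian mixtures (ΔBIC > 10 and
  mean separation > 2× pooled sd).

Seeded synthetic-data generators emulate every input the pipelines need —
toy membrane complexes with a prescribed expansion field and ring
orientations, serial shot sets with known twin assignments, unit-cell
mixtures, and model ensembles with prescribed angular spread — so the whole
package builds and tests without downloads. The methods vignette
(`vignettes/rt-vs-cryo-psi-geometry.Rmd`) documents the conventions and
design choices in detail.

## Worked example

```r
library(psigeom)
reg <- read_registry()

# a cryo/RT-like pair with a known 0.5% in-plane expansion
tc  <- make_toy_complex_pair(toy_complex_spec(radial_scale = 1.005, seed = 1))
prof <- expansion_profile(tc$ref, tc$alt,
                          build_cofactor_map(tc$ref, reg, "synthetic"),
                          build_cofactor_map(tc$alt, reg, "synthetic"))
expansion_summary(prof)
#> expansion over 96 chlorophylls
#>   in-plane:      +0.161 +/- 0.067 A (gradient +0.050 A / 10 A)
#>   perpendicular: +0.000 +/- 0.000 A
```

The gradient of 0.050 Å per 10 Å is exactly the prescribed scale factor
(Δr = 0.005·r), and the perpendicular change is zero — the signature of
in-plane-only thermal expansion. The same pipeline applied to deposited
cryo/RT coordinate files reports the published ~0.2 Å mean in-plane
expansion.

```r
# resolve a 50%-twinned serial data set of 1000 shots
ops <- coset_operators("6")
sim <- simulate_shots(shot_sim_spec(n_shots = 1000, flip_fraction = 0.5,
                                    seed = 1))
sol <- resolve_ambiguity(sim$shots, "6", ops, tranche_size = 250,
                         overlap = 25, seed = 2)
sol
#> assignment over 1000 shots in 5 tranche(s) (size 250, overlap 25)
#>   correlations evaluated: 5.2e+05; mean within-cluster CC 0.947
truth <- vapply(sim$shots, `[[`, integer(1), "true_operator")
assignment_accuracy(sol$assignment, truth, ops, "6")$accuracy
#> [1] 1
```

All 1000 ground-truth twin labels are recovered (up to the global operator
gauge) while evaluating 13% of the correlations an all-pairs approach would
need. The numbered scripts under `analysis/` run each pipeline end to end
and write their tables to `results/`.

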