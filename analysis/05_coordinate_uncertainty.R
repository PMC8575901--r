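#!/usr/bin/env Rscript
# Perturbation-based coordinate precision: perturb amplitudes within the
# model residual, kick coordinates, and read the precision of a stacking
# angle from the spread of a 100-model ensemble (the synthetic ensemble
# generator stands in for re-refinement; a refinement_hook() can replace
# it when a refinement engine is available).

suppressPackageStartupMessages(library(psigeom))
dir.create("results", showWarnings = FALSE)
seed <- 1L

set.seed(seed)
n <- 5000L
refl <- data.frame(h = seq_len(n), k = 0L, l = 0L,
                   f_obs = runif(n, 1, 300), f_model = runif(n, 1, 300))
pert <- perturb_structure_factors(refl, seed = seed + 1L)
cat(sprintf("perturbed %d amplitudes; max |dF|/|Fobs-Fmodel| = %.3f; %d clamped\n",
            n, max(abs(pert$f_obs - refl$f_obs) /
                     pmax(abs(refl$f_obs - refl$f_model), 1e-12)),
            attr(pert, "n_clamped")))

reg <- read_registry()
tc <- make_toy_complex_pair(toy_complex_spec(seed = seed))
kicked <- kick_coordinates(tc$ref, 0.2, seed = seed + 2L)
disp <- sqrt(rowSums((atom_xyz(kicked) - atom_xyz(tc$ref))^2))
cat(sprintf("coordinate kick: RMS displacement %.3f A (target 0.200)\n",
            sqrt(mean(disp^2))))

ens <- make_model_ensemble(tc$ref, c("ring6_a", "ring6_b"), reg,
                           "synthetic", angular_sd = 2, n = 100,
                           seed = seed + 3L)
met <- make_pocket_metric("ring6_a/ring6_b", reg, "synthetic")
st <- ensemble_geometry_stats(ens, met, "ring6 stacking angle")
print(st)
write.csv(data.frame(metric = st$metric_label, mean = st$mean, sd = st$sd,
                     n_models = st$n_models),
          "results/coordinate_uncertainty.csv", row.names = FALSE)
cat("the ensemble spread recovers the prescribed 2 degree angular sd --\n")
cat("the same readout used to attach error bars to pocket angles.\n")
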