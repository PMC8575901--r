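#!/usr/bin/env Rscript
# Anisotropic-expansion and pocket-geometry pipelines on a synthetic
# cryo/RT pair with known ground truth (in-plane scale 1.005, no axial
# change). Writes the per-chlorophyll profile and the stacking report.

suppressPackageStartupMessages(library(psigeom))
dir.create("results", showWarnings = FALSE)
seed <- 1L

reg <- read_registry()
tc <- make_toy_complex_pair(toy_complex_spec(radial_scale = 1.005,
                                             axial_scale = 1, seed = seed))
map_ref <- build_cofactor_map(tc$ref, reg, "synthetic")
map_alt <- build_cofactor_map(tc$alt, reg, "synthetic")

prof <- expansion_profile(tc$ref, tc$alt, map_ref, map_alt)
s <- expansion_summary(prof)
print(s)
cat(sprintf("Theil-Sen gradient: %+.4f A / 10 A\n",
            s$gradient_per_10A_theil_sen))
write.csv(prof, "results/expansion_profile.csv", row.names = FALSE)

pairs <- data.frame(ring_a = paste0("ring", 1:6, "_a"),
                    ring_b = paste0("ring", 1:6, "_b"))
rep <- stacking_report(tc$ref, map_ref, pairs)
cat("\nStacking geometry of the synthetic ring pairs:\n")
print(rep[, c("pair_label", "angle", "min_contact", "centroid_to_plane")],
      digits = 4)
write.csv(rep, "results/stacking_report_synthetic.csv", row.names = FALSE)

cat("\nA 0.5% in-plane expansion reproduces a gradient of",
    sprintf("%.3f", s$gradient_per_10A),
    "A per 10 A with no perpendicular change -- the signature the",
    "chlorophyll-lattice comparison is designed to detect.\n")
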