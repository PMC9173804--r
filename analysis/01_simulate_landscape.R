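#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system -- a 50 x 50 landscape with
# 10 time slices of drifting environmental fields, camps placed by the true
# suitability surface (with wedge-shaped population sizes), a dated
# archaeological site register, and a DEM with a water barrier. Everything
# downstream consumes these files, so the whole workflow is reproducible
# from this seed alone.

suppressPackageStartupMessages(library(paleoniche))
dir.create("results", showWarnings = FALSE)

seed <- 20260929L
cfg <- sim_config(seed = seed)
truth <- gen_landscape_stack(cfg)

camps <- gen_camps(truth, n_camps = 300)
density_camps <- gen_camps(truth, n_camps = 2000)
sites <- gen_archaeo_sites(truth, n_sites = 100, mode = "signal",
                           seed = seed + 1)
dem <- gen_dem(truth$grid, relief_amplitude = 150, corr_length = 6,
               river = list(orientation = "vertical", at = 25, width = 1),
               seed = seed + 2)

write_stack_csv(truth$stack, "results/stack.csv")
write.csv(camps, "results/camps.csv", row.names = FALSE)
write.csv(density_camps, "results/density_camps.csv", row.names = FALSE)
write.csv(sites, "results/sites.csv", row.names = FALSE)
write.csv(data.frame(row = as.vector(row(dem$dem)),
                     col = as.vector(col(dem$dem)),
                     elevation_m = as.vector(dem$dem),
                     water = as.vector(dem$water)),
          "results/dem.csv", row.names = FALSE)

land <- truth$grid$land_mask
cat(sprintf("landscape: %d x %d cells, %d slices, true suitability mean %.3f\n",
            cfg$n_rows, cfg$n_cols, cfg$n_slices,
            mean(truth$true_suit[[1]][land])))
cat(sprintf("camps: %d (mean size %.1f persons); sites: %d; seed %d\n",
            nrow(camps), mean(camps$population_size), nrow(sites), seed))
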