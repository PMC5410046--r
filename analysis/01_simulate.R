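#!/usr/bin/env Rscript
# Step 1: generate the synthetic partial-diallel breeding population used by
# the rest of the analysis: 27 parents, 34 full-sib families trimmed to 734
# progeny on 2 sites, 4993 gene SNPs on 12 linkage groups (1850 cM), four
# traits with individual heritabilities between 0.41 and 0.74, 1.8% missing
# genotype calls. Writes the plain-text population files under
# results/population/.

library(sprucegs)

seed <- 2026
cfg <- sim_config()

message("Simulating ", cfg$n_families, " families / ",
        cfg$n_progeny_total, " trees / ", cfg$n_markers, " SNPs ...")
pop <- simulate_population(cfg, seed = seed)

write_population(pop, "results/population")

st <- marker_stats(pop$genotypes)
message(sprintf("Marker density: %.1f per cM; mean MAF %.2f; %.1f%% missing",
                cfg$n_markers / cfg$total_map_length,
                mean(st$maf, na.rm = TRUE),
                100 * mean(is.na(pop$genotypes))))
message("Population written to results/population/")
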