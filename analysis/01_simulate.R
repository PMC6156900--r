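#!/usr/bin/env Rscript
# Step 1: generate the family-structured marker dataset used by the rest of
# the analysis. 200 sibship families of mixed sizes (2-8 members, n = 1000
# individuals), 1000 markers of which 10 carry a mean shift of 0.2, family
# random effect and residual variance both 1. Everything is reproducible
# from the seed written into the manifest.

suppressMessages(library(famlmm))

out_dir <- "results/dataset"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 1101)
write_manifest(file.path(out_dir, "manifest.txt"), config = cfg,
               seeds = list(dataset = cfg$seed),
               files = list(out = out_dir))

ds <- simulate_dataset(cfg)
write_dataset(ds, out_dir)

message("simulated ", ncol(ds$responses), " markers for ", length(ds$ids),
        " individuals in ", length(unique(ds$family)), " families")
message("causal markers (known truth): ", paste(ds$causal, collapse = ", "))
message("family sizes: ", paste(sort(unique(table(ds$family))), collapse = ", "),
        " (mean ", mean(table(ds$family)), ")")
message("wrote ", out_dir, "/{phenotypes,covariates,truth}.tsv + config.txt")
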