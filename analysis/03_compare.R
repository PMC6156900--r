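#!/usr/bin/env Rscript
# Step 3: the replicate comparison study. Three independently simulated
# datasets, five representative draws each (15 runs), top-20 sets per
# option, three-way Venn regions and truth recovery aggregated as
# mean +/- SD — plus the hybrid strategy (markers found by BOTH the
# independence and the representative scan). Pass --reps/--draws/--k to
# change the protocol.

suppressMessages({
  library(optparse)
  library(famlmm)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--reps", type = "integer", default = 3),
  make_option("--draws", type = "integer", default = 5),
  make_option("--k", type = "integer", default = 20),
  make_option("--seed", type = "integer", default = 1101)
)))

out_dir <- "results/study"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = opts$seed)
write_manifest(file.path(out_dir, "manifest.txt"), config = cfg,
               seeds = list(study = cfg$seed),
               files = list(out = out_dir))

study <- run_study(cfg, n_replicates = opts$reps,
                   n_representative_draws = opts$draws, k = opts$k)
write_study_report(study, out_dir)

print(study)

rs <- study$recovery_summary
tp <- setNames(rs$mean_true_positives, rs$option)
fdr <- setNames(rs$mean_fdr, rs$option)
ov <- setNames(study$pairwise$mean_overlap, study$pairwise$pair)
message("")
message("findings:")
message(sprintf(
  "  - the kinship option recovers the most true signals (%.2f vs %.2f independence, %.2f representative)",
  tp[["kinship"]], tp[["independence"]], tp[["representative"]]))
message(sprintf(
  "  - independence tracks kinship closely (mean top-%d overlap %.1f) while representative does not (%.1f)",
  opts$k, ov[["kinship_independence"]], ov[["kinship_representative"]]))
message(sprintf(
  "  - the hybrid intersection has lower FDR than independence alone (%.2f vs %.2f) at mean size %.1f",
  fdr[["hybrid"]], fdr[["independence"]], rs$mean_size[rs$option == "hybrid"]))
message("report written under ", out_dir)
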