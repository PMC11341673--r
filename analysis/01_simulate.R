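#!/usr/bin/env Rscript
# Stage 1: generate the study-shaped synthetic dataset.
#
# Two species (pepper-like, broccoli-like) x two light treatments (HL,
# LL) x three leaf-age classes x nine replicate plants, with per-compound
# wax delta13C laid down from a known drawdown model so that every later
# stage can be checked against ground truth. Writes the leaves table, the
# long compounds table and the truth table under results/analysis/.

suppressPackageStartupMessages(library(amphistomy))

out_dir <- "results/analysis"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

config <- synthetic_config(seed = 20260925 %% 100000L)
study <- generate_study(config)

write.csv(study$leaves, file.path(out_dir, "leaves.csv"),
          row.names = FALSE)
write.csv(study$compounds, file.path(out_dir, "compounds.csv"),
          row.names = FALSE)
write.csv(study$truth$leaves, file.path(out_dir, "truth.csv"),
          row.names = FALSE)
jsonlite::write_json(
  list(drawdown = study$truth$drawdown,
       coupling = study$truth$coupling,
       seed = study$truth$seed,
       n_truncated = study$truth$n_truncated),
  file.path(out_dir, "truth_params.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("Generated %d leaves (%d compound rows) with seed %d.\n",
            nrow(study$leaves), nrow(study$compounds), config$seed))
cat(sprintf("Truncated draws: %d.\n", study$truth$n_truncated))
cat("Wrote leaves.csv, compounds.csv, truth.csv, truth_params.json\n")
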