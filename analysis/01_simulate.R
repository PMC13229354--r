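#!/usr/bin/env Rscript

# Step 1 -- simulate a decade of the multi-gear coastal fleet.
#
# Generates the environmental grids (bathymetry, sediment) and the fleet's
# electronic logbooks, sales notes and truth table under the default
# planted-metier configuration (12 metiers across six gears, ~50,000 hauls
# over 2014-2023, ~1.8% injected record errors), then writes everything in
# the package's plain-text formats. Bulky intermediates go to
# scratch/analysis/; downstream steps read them back through the package
# readers, so the whole file dialect is exercised.

library(metierid)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
dir <- "scratch/analysis"
dir.create(dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
env <- generate_env(cfg)
rec <- generate_records(cfg, env)

write_env_grid(env$depth, file.path(dir, "depth.grid"))
write_env_grid(env$sediment, file.path(dir, "sediment.grid"))
write_logbook(rec$hauls, rec$catches, file.path(dir, "logbook.csv"))
write_sales(rec$sales$notes, rec$sales$lines, file.path(dir, "sales.csv"))
readr::write_csv(rec$truth$hauls, file.path(dir, "truth_hauls.csv"))
readr::write_csv(rec$truth$violations, file.path(dir, "truth_violations.csv"))

cat(sprintf("simulated %d hauls on %d trips by %d vessels (seed %d)\n",
            nrow(rec$hauls), nrow(rec$sales$notes),
            length(unique(rec$hauls$vessel_id)), seed))
cat(sprintf("injected violations: %d hauls\n",
            length(unique(rec$truth$violations$haul_id))))
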