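#!/usr/bin/env Rscript

# Step 3 -- target-species attribution and environmental annotation.
#
# Values every valid haul at its trip's average prices, picks the target
# species (highest sale value), keys the potential metier (gear x target),
# and annotates each haul with midpoint, year, season, fishing area, depth
# stratum and sediment class.

library(metierid)

dir <- "scratch/analysis"
log <- read_logbook(file.path(dir, "logbook_valid.csv"))
sal <- read_sales(file.path(dir, "sales.csv"))
env <- list(depth = read_env_grid(file.path(dir, "depth.grid")),
            sediment = read_env_grid(file.path(dir, "sediment.grid")))

assigned <- assign_metiers(log$hauls, log$catches, sal)
annotated <- annotate_hauls(assigned, env$depth, env$sediment)
readr::write_csv(annotated, file.path(dir, "annotated.csv"))

cat(sprintf("%d valid hauls assigned to %d potential metiers\n",
            nrow(annotated), length(unique(annotated$metier))))

truth <- readr::read_csv(file.path(dir, "truth_hauls.csv"),
                         show_col_types = FALSE)
j <- merge(annotated[, c("haul_id", "target_species")], truth, by = "haul_id")
j <- j[!j$is_tail, ]
cat(sprintf("target species matches the planted truth on %.1f%% of planted hauls\n",
            100 * mean(j$target_species == j$target)))
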