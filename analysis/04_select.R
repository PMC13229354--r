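#!/usr/bin/env Rscript

# Step 4 -- rank potential metiers and select the important ones.
#
# Ranks metiers within each gear by haul count and applies the
# max-distance-to-chord knee rule to each gear's rank-frequency curve.
# Writes the full ranked table and the selection summary.

library(metierid)

dir <- "scratch/analysis"
annotated <- readr::read_csv(file.path(dir, "annotated.csv"),
                             show_col_types = FALSE)

ranked <- rank_metiers(annotated)
sel <- select_metiers(ranked, n_years = 10)
print(sel)

readr::write_csv(sel$table, "results/metier_ranking.csv")
s <- sel$summary
readr::write_csv(tibble::tibble(
  quantity = c("selected_metiers", "excluded_metiers", "excluded_hauls",
               "excluded_share_pct", "mean_excluded_per_metier_year"),
  value = c(s$n_selected, s$n_excluded, s$excluded_hauls,
            s$excluded_share_pct, round(s$mean_excluded_per_metier_year, 2))),
  "results/selection_summary.csv")

cat("selected metiers:\n")
print(as.data.frame(sel$table[sel$table$selected,
                              c("gear_code", "metier", "n_hauls", "rank")]))
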