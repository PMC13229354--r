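#!/usr/bin/env Rscript

# Step 5 -- statistical characterization of the selected metiers.
#
# Guarded chi-square goodness-of-fit tests (area, season, depth), the
# area x season independence test, Bonferroni correction within each
# variable, OLS yearly trends, the Table-2-style summary and per-metier
# effort grids.

library(metierid)

dir <- "scratch/analysis"
annotated <- readr::read_csv(file.path(dir, "annotated.csv"),
                             show_col_types = FALSE)
ranking <- readr::read_csv("results/metier_ranking.csv",
                           show_col_types = FALSE)
selected <- ranking$metier[ranking$selected]

res <- characterize_metiers(annotated, metiers = selected,
                            years = 2014:2023, alpha = 0.01)
readr::write_csv(res$tests, "results/chisq_tests.csv")
readr::write_csv(res$trends, "results/yearly_trends.csv")

sel <- select_metiers(rank_metiers(annotated), n_years = 10)
report <- summary_report(annotated, sel, years = 2014:2023)
readr::write_csv(report, "results/metier_summary.csv")

cat(sprintf("%d of %d applied uniformity tests rejected at alpha = 0.01\n",
            sum(res$tests$reject, na.rm = TRUE), sum(res$tests$applied)))
cat(sprintf("%d metiers with a significant yearly trend\n",
            sum(res$trends$significant)))
cat("\nper-metier summary (head):\n")
print(as.data.frame(report[1:8, c("metier", "n_hauls", "detail_range",
                                  "season", "area", "depth")]))

# effort grid for the most active metier, in the plain-text matrix format
top <- report$metier[1]
g <- effort_grid(annotated, metier = top, cell_size = 0.05)
write.table(g$counts, file.path(dir, paste0("effort_", top, ".txt")),
            row.names = FALSE, col.names = FALSE)
cat(sprintf("\neffort grid for %s: %d hauls across %d occupied cells\n",
            top, sum(g$counts), sum(g$counts > 0)))
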