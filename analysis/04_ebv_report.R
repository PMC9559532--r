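#!/usr/bin/env Rscript

# Stage 4: breeding-value report. Standardized EBVs (80-120 scale, mean
# 100) from both models, top-20% selection, and the cross-model coincidence
# of selected animals by coat group.

suppressPackageStartupMessages(library(etrgen))

out <- "results/report"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tab_mgg <- select_top_fraction(
  utils::read.csv("results/models/ebv_mgg.csv"), 0.20)
tab_mhrv <- select_top_fraction(
  utils::read.csv("results/models/ebv_mhrv.csv"), 0.20)

cat("animals evaluated:", nrow(tab_mgg), "; selected per model:",
    sum(tab_mgg$selected), "\n")
cat("mean standardized EBV (MGG):", round(mean(tab_mgg$ebv_std), 6), "\n")

sm <- ebv_selection_summary(tab_mgg, tab_mhrv)
utils::write.csv(rbind(tab_mgg, tab_mhrv),
                 file.path(out, "ebv_tables.csv"), row.names = FALSE)
utils::write.csv(sm$by_group, file.path(out, "selected_by_group.csv"),
                 row.names = FALSE)
utils::write.csv(sm$coincidence, file.path(out, "coincidence.csv"),
                 row.names = FALSE)

cat("\nselected animals by coat and model (mean standardized EBV):\n")
print(sm$by_group, digits = 4)
cat("\ncross-model coincidence of the selected top 20%:\n")
print(sm$coincidence, digits = 3)
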