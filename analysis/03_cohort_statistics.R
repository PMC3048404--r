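#!/usr/bin/env Rscript

# Stage 3 — longitudinal percent changes and between-arm statistics.
#
# Reads the cohort table from stage 2, computes each animal's day-2 vs
# day-0 change per biomarker (tumor volume as percent of baseline, all
# other biomarkers as signed percent change) and compares arms by one-way
# ANOVA, printing a study-style summary.

suppressMessages(library(gliomark))

records <- read.csv("results/cohort.csv", stringsAsFactors = FALSE)

changes <- summarize_changes(records)
write.csv(changes, "results/changes.csv", row.names = FALSE)

cat("Arm-level longitudinal changes (mean +/- SEM):\n")
for (bm in unique(changes$biomarker)) {
  sub <- changes[changes$biomarker == bm, ]
  lab <- vapply(seq_len(nrow(sub)), function(i)
    sprintf("%s %+.1f+/-%.1f%%", sub$arm[i], sub$mean_change[i], sub$sem[i]),
    "")
  cmp <- tryCatch(compare_groups(records, bm), error = function(e) NULL)
  ptxt <- if (is.null(cmp)) "" else
    sprintf("  [F = %.2f, p = %.3g%s]", cmp$f_statistic, cmp$p_value,
            if (cmp$significant) " *" else "")
  cat(sprintf("  %-13s %s%s\n", bm, paste(lab, collapse = ", "), ptxt))
}

stats <- lapply(unique(changes$biomarker), function(bm) {
  cmp <- tryCatch(compare_groups(records, bm), error = function(e) NULL)
  if (is.null(cmp)) return(NULL)
  list(biomarker = bm, f = cmp$f_statistic, p = cmp$p_value,
       significant = cmp$significant)
})
jsonlite::write_json(Filter(Negate(is.null), stats), "results/stats.json",
                     auto_unbox = TRUE, digits = NA)
cat("Stats -> results/changes.csv, results/stats.json\n")
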