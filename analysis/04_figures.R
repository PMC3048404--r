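#!/usr/bin/env Rscript

# Stage 4 — figure panels: per-arm biomarker changes with SEM bars.
#
# Reproduces the study-style four-panel layout from the stage-3 tables:
# (1) tumor volume and rVCI, (2) rCBV and rMBV, (3) ADC and T2,
# (4) Ktrans and ve.

suppressMessages({library(gliomark); library(ggplot2)})

changes <- read.csv("results/changes.csv", stringsAsFactors = FALSE)
dir.create("results/figures", showWarnings = FALSE)

panels <- list(
  growth_and_caliber = c("volume_mm3", "rvci"),
  blood_volumes = c("rcbv", "rmbv"),
  edema = c("adc", "t2_ms"),
  permeability_dce = c("ktrans", "ve"))

for (nm in names(panels)) {
  sub <- changes[changes$biomarker %in% panels[[nm]], ]
  if (!nrow(sub)) next
  p <- ggplot(sub, aes(biomarker, mean_change, fill = arm)) +
    geom_col(position = position_dodge(0.8), width = 0.7) +
    geom_errorbar(aes(ymin = mean_change - sem, ymax = mean_change + sem),
                  position = position_dodge(0.8), width = 0.25) +
    geom_hline(yintercept = if (all(sub$mode == "of_baseline")) 100 else 0,
               linetype = 2) +
    labs(y = ifelse(all(sub$mode == "of_baseline"),
                    "day-2 volume, % of baseline",
                    "change day 0 -> day 2, %"),
         x = NULL, fill = NULL,
         title = gsub("_", " ", nm)) +
    theme_minimal(base_size = 11)
  ggsave(file.path("results/figures", paste0(nm, ".pdf")), p,
         width = 4.5, height = 3.2)
}
cat("Figures -> results/figures/*.pdf\n")
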