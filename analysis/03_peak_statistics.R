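#!/usr/bin/env Rscript
# Peak-intensity statistics on the preprocessed cohort: per-band
# Mann-Whitney U comparison of healthy vs pooled NPC, per-band
# Kruskal-Wallis comparison across stages I-IV, the NPC-minus-normal
# difference spectrum, and box-plot summaries.
#
#   Rscript analysis/03_peak_statistics.R

suppressPackageStartupMessages(library(sersnpc))
dir.create("results", showWarnings = FALSE)

prep <- read_spectra("scratch/preprocessed.csv")
pim <- extract_peak_intensities(prep)

mw <- peak_stats_table(pim, comparison = "npc-vs-normal")
kw <- peak_stats_table(pim, comparison = "stages")
utils::write.table(mw, "results/peak_stats_mw.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(kw, "results/peak_stats_kw.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(box_summary(pim), "results/box_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

diff <- difference_spectrum(subset_spectra(prep, prep$labels != "normal"),
                            subset_spectra(prep, prep$labels == "normal"))
write_spectra(diff, "results/difference_npc_minus_normal.csv")

up <- mw$shift[mw$direction > 0 & mw$p_value < 0.01]
down <- mw$shift[mw$direction < 0 & mw$p_value < 0.01]
cat("NPC vs normal (Mann-Whitney, p < 0.01):\n")
cat("  higher in NPC:", paste(up, collapse = " "), "\n")
cat("  lower in NPC: ", paste(down, collapse = " "), "\n")
cat("stage trend at 1003 cm-1 (Kruskal-Wallis):",
    "p =", format(kw$p_value[kw$shift == 1003], digits = 3),
    kw$stars[kw$shift == 1003], "\n")
cat("medians I-IV at 1003:",
    paste(signif(unlist(kw[kw$shift == 1003,
                           c("median_I", "median_II", "median_III",
                             "median_IV")]), 4), collapse = " "), "\n")
cat("wrote results/peak_stats_{mw,kw}.tsv, box_summary.tsv,",
    "difference_npc_minus_normal.csv\n")
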