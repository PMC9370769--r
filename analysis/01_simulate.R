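#!/usr/bin/env Rscript
# Simulate the default five-class protein SERS cohort (225 healthy plus
# 120/249/291/279 NPC stage I-IV subjects; 1164 spectra on the 400-1800
# cm-1 grid at 2 cm-1) and write it to scratch/cohort.csv.
#
#   Rscript analysis/01_simulate.R [seed]

suppressPackageStartupMessages(library(sersnpc))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("scratch", showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
cohort <- simulate_cohort(cfg)
write_spectra(cohort, "scratch/cohort.csv")

cat("simulated cohort (seed", seed, "):\n")
print(cohort)
cat("raw intensity range:", signif(range(cohort$intensity), 4), "\n")
cat("wrote scratch/cohort.csv\n")
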