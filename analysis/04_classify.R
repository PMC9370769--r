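#!/usr/bin/env Rscript
# Five-class screening/staging classifiers on the preprocessed cohort:
# the 1D CNN (stride-3 pooling variant, 100 epochs) and the PCA-LDA
# comparator, both on the 936/228 stratified split.
#
#   Rscript analysis/04_classify.R [seed] [epochs]

suppressPackageStartupMessages(library(sersnpc))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(args[1]); if (is.na(seed)) seed <- 1L
epochs <- as.integer(args[2]); if (is.na(epochs)) epochs <- 100L
dir.create("results", showWarnings = FALSE)

prep <- read_spectra("scratch/preprocessed.csv")
split <- stratified_split(prep, split_plan(seed = seed + 100003L))
cat("split:", n_spectra(split$train), "training /",
    n_spectra(split$test), "test spectra\n")

spec <- cnn_spec(pool_stride = 3, epochs = epochs, seed = seed + 200003L)
fit <- train_cnn(split$train, spec)
utils::write.table(fit$curves, "results/cnn_curves.csv", sep = ",",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("CNN training: final loss %.4g, final accuracy %.1f%%\n",
            fit$curves$loss[epochs], 100 * fit$curves$accuracy[epochs]))

cnn_rep <- evaluate(fit, split$test)
cat("\nCNN test performance:\n"); print(cnn_rep)

pl <- fit_pca_lda(split$train, n_components = 20)
pl_rep <- evaluate(pl, split$test)
cat("\nPCA-LDA test performance (20 components):\n"); print(pl_rep)

to_json <- function(rep) list(
  overall_accuracy = rep$overall_accuracy,
  per_class_accuracy = as.list(rep$per_class_accuracy),
  confusion = unclass(unname(as.matrix(rep$confusion))))
jsonlite::write_json(list(cnn = to_json(cnn_rep), pcalda = to_json(pl_rep),
                          seed = seed, epochs = epochs),
                     "results/classification_report.json",
                     auto_unbox = TRUE, digits = NA)
cat("\nwrote results/cnn_curves.csv and results/classification_report.json\n")
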