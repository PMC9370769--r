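#' Train/test split plan
#'
#' Per-class training and test counts. The defaults reproduce the study's
#' 80/20 split of the 1164-spectrum cohort: 936 training spectra
#' (180/96/201/234/225) and 228 reserved test spectra (45/24/48/57/54)
#' for normal and stages I--IV.
#'
#' @param train,test named integer vectors over the five classes.
#' @param seed seed for the per-class sampling.
#' @export
split_plan <- function(train = c(normal = 180, I = 96, II = 201, III = 234,
                                 IV = 225),
                       test = c(normal = 45, I = 24, II = 48, III = 57,
                                IV = 54),
                       seed = 1L) {
  stopifnot(identical(sort(names(train)), sort(names(test))),
            all(train >= 0), all(test >= 0))
  structure(list(train = train, test = test, seed = as.integer(seed)),
            class = "split_plan")
}

#' Stratified train/test split of a labeled cohort
#'
#' Seeded sampling without replacement within each class. Under the
#' default plan the split is exhaustive (train + test = cohort) and the
#' two sets are disjoint by sample id.
#'
#' @param set labeled \code{spectrum_set}.
#' @param plan a \code{\link{split_plan}}.
#' @return list with \code{train} and \code{test} \code{spectrum_set}s.
#' @export
stratified_split <- function(set, plan = split_plan()) {
  if (is.null(set$labels)) stop("split requires labeled spectra")
  cc <- table(set$labels)
  for (cl in names(plan$train)) {
    need <- plan$train[[cl]] + plan$test[[cl]]
    if (need > cc[[cl]])
      stop("class ", cl, ": plan needs ", need, " but only ", cc[[cl]],
           " spectra available")
  }
  set.seed(plan$seed)
  test_idx <- integer(0)
  train_idx <- integer(0)
  for (cl in names(plan$train)) {
    idx <- which(set$labels == cl)
    te <- if (plan$test[[cl]] > 0) sample(idx, plan$test[[cl]]) else integer(0)
    rest <- setdiff(idx, te)
    tr <- if (plan$train[[cl]] < length(rest))
      sample(rest, plan$train[[cl]]) else rest
    test_idx <- c(test_idx, te)
    train_idx <- c(train_idx, tr)
  }
  list(train = subset_spectra(set, sort(train_idx)),
       test = subset_spectra(set, sort(test_idx)))
}

report_json <- function(report) {
  list(overall_accuracy = report$overall_accuracy,
       per_class_accuracy = as.list(report$per_class_accuracy),
       confusion = unclass(unname(as.matrix(report$confusion))))
}

#' Run the full analysis chain
#'
#' simulate -> preprocess -> split -> peak statistics -> CNN -> PCA-LDA,
#' driven by one master seed, writing all artifacts under \code{out_dir}:
#' \code{cohort.csv}, \code{preprocessed.csv}, \code{split.json},
#' \code{peak_stats.tsv}, \code{curves.csv}, \code{cnn_report.json},
#' \code{pcalda_report.json} and \code{run_report.json}.
#'
#' @param out_dir output directory (created if needed).
#' @param sim_config a \code{\link{simulation_config}}.
#' @param effects a \code{\link{class_effect_model}}.
#' @param peaks a peak table.
#' @param plan a \code{\link{split_plan}}.
#' @param cnn a \code{\link{cnn_spec}}; the default uses stride-3 pooling,
#'   the package's tractable training variant.
#' @param pca_components retained principal components for PCA-LDA.
#' @param seed master seed; overrides the seeds inside the sub-configs.
#' @return the run report, invisibly (also written as JSON).
#' @export
run_all <- function(out_dir,
                    sim_config = simulation_config(),
                    effects = class_effect_model(),
                    peaks = default_peak_table(),
                    plan = split_plan(),
                    cnn = cnn_spec(pool_stride = 3, epochs = 30),
                    pca_components = 20,
                    seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  sim_config$seed <- seed
  plan$seed <- seed + 100003L
  cnn$seed <- seed + 200003L

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  cohort <- stage("simulate", simulate_cohort(sim_config, peaks, effects))
  write_spectra(cohort, file.path(out_dir, "cohort.csv"))

  prep <- stage("preprocess", preprocess_set(cohort))
  write_spectra(prep, file.path(out_dir, "preprocessed.csv"))

  split <- stage("split", stratified_split(prep, plan))
  jsonlite::write_json(
    list(train = split$train$sample_ids, test = split$test$sample_ids),
    file.path(out_dir, "split.json"))

  pim <- stage("stats", extract_peak_intensities(prep, peaks))
  stats_tab <- stage("stats", peak_stats_table(pim, peaks))
  utils::write.table(stats_tab, file.path(out_dir, "peak_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cnn_fit <- stage("train-cnn", train_cnn(split$train, cnn))
  utils::write.table(cnn_fit$curves, file.path(out_dir, "curves.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  cnn_report <- stage("evaluate-cnn", evaluate(cnn_fit, split$test))
  jsonlite::write_json(report_json(cnn_report),
                       file.path(out_dir, "cnn_report.json"),
                       auto_unbox = TRUE, digits = NA)

  pl_fit <- stage("train-pcalda", fit_pca_lda(split$train, pca_components))
  pl_report <- stage("evaluate-pcalda", evaluate(pl_fit, split$test))
  jsonlite::write_json(report_json(pl_report),
                       file.path(out_dir, "pcalda_report.json"),
                       auto_unbox = TRUE, digits = NA)

  report <- list(
    seed = seed,
    config = list(cohort_sizes = as.list(sim_config$cohort_sizes),
                  grid = range(sim_config$grid),
                  spacing = diff(sim_config$grid)[1],
                  effect_size = effects$effect_size,
                  stage_step = effects$stage_step,
                  subject_sd = effects$subject_sd,
                  noise_sd = sim_config$noise_sd,
                  scale_sd = sim_config$scale_sd,
                  cnn = unclass(cnn), pca_components = pca_components,
                  plan = list(train = as.list(plan$train),
                              test = as.list(plan$test))),
    split_counts = list(train = as.list(table(split$train$labels)),
                        test = as.list(table(split$test$labels))),
    peak_stats = stats_tab,
    cnn = c(report_json(cnn_report),
            list(final_training_loss = utils::tail(cnn_fit$curves$loss, 1),
                 final_training_accuracy =
                   utils::tail(cnn_fit$curves$accuracy, 1))),
    pcalda = report_json(pl_report),
    files = list.files(out_dir))
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
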