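# a coarse grid keeps these trainings to seconds
cnn_tiny <- function(...) cnn_spec(pool_stride = 3, batch_size = 10, ...)

test_that("the instantiated architecture matches the printed layer sequence", {
  spec <- cnn_spec()
  arch <- cnn_architecture(spec, input_len = 701)
  conv <- arch[arch$layer == "conv", ]
  expect_equal(conv$kernels, c(16, 16, 32, 32, 64, 64, 128, 128, 256, 256))
  expect_true(all(conv$kernel_size == 3))
  expect_true(all(conv$stride == 1))
  expect_true(all(conv$activation == "tanh"))
  pools <- arch[arch$layer == "maxpool", ]
  expect_equal(nrow(pools), 5)
  expect_true(all(pools$kernel_size == 3))
  expect_true(all(pools$stride == 1))
  expect_equal(arch$layer[nrow(arch) - 1:0], c("dense", "softmax"))
  expect_identical(spec$optimizer, "adam")
  expect_identical(spec$loss, "cross-entropy")
  expect_equal(spec$learning_rate, 0.001)
  expect_equal(spec$batch_size, 20)
  expect_equal(spec$epochs, 100)
  # a short spectrum cannot survive five pooling stages
  expect_error(cnn_architecture(cnn_spec(pool_stride = 3), input_len = 100),
               "too short")
})

test_that("softmax outputs are normalized probabilities", {
  cfg <- tiny_config(n_per_class = 4, by = 4, seed = 17)
  prep <- preprocess_set(simulate_cohort(cfg))
  m <- train_cnn(prep, cnn_tiny(epochs = 2, seed = 5))
  p <- predict(m, prep)
  expect_equal(rowSums(p), setNames(rep(1, 20), prep$sample_ids),
               tolerance = 1e-6)
  expect_true(all(p >= 0))
})

test_that("perfectly separated classes are fit to 100% training accuracy", {
  cfg <- simulation_config(cohort_sizes = c(normal = 20, I = 0, II = 0,
                                            III = 0, IV = 20),
                           grid = raman_grid(by = 4), noise_sd = 0,
                           scale_sd = 0, baseline_range = c(0, 0), seed = 23)
  eff <- class_effect_model(effect_size = 0.5, subject_sd = 0.02)
  prep <- preprocess_set(simulate_cohort(cfg, effects = eff))
  m <- train_cnn(prep, cnn_tiny(epochs = 40, seed = 2))
  rep <- evaluate(m, prep)
  expect_equal(rep$overall_accuracy, 1)
  # loss curve dropped
  expect_lt(m$curves$loss[nrow(m$curves)], m$curves$loss[1])
  expect_equal(nrow(m$curves), 40)
})

test_that("training is deterministic given the seed", {
  cfg <- tiny_config(n_per_class = 4, by = 4, seed = 29)
  prep <- preprocess_set(simulate_cohort(cfg))
  m1 <- train_cnn(prep, cnn_tiny(epochs = 3, seed = 8))
  m2 <- train_cnn(prep, cnn_tiny(epochs = 3, seed = 8))
  expect_identical(m1$curves, m2$curves)
  expect_identical(evaluate(m1, prep)$confusion, evaluate(m2, prep)$confusion)
  m3 <- train_cnn(prep, cnn_tiny(epochs = 3, seed = 9))
  expect_false(identical(m1$curves$loss, m3$curves$loss))
})

test_that("evaluation bookkeeping: confusion rows equal class counts", {
  cfg <- tiny_config(n_per_class = 5, by = 4, seed = 37)
  prep <- preprocess_set(simulate_cohort(cfg))
  m <- train_cnn(prep, cnn_tiny(epochs = 2, seed = 4))
  rep <- evaluate(m, prep)
  expect_equal(unname(rowSums(rep$confusion)), rep(5, 5))
  expect_equal(rep$per_class_accuracy,
               diag(rep$confusion) / rowSums(rep$confusion))
  # grid mismatch is refused
  other <- resample(prep, raman_grid(by = 16))
  expect_error(evaluate(m, other), "grid mismatch")
  expect_error(train_cnn(spectrum_set(prep$shifts, prep$intensity),
                         cnn_tiny()), "label")
})

test_that("stratified cross-validation assigns balanced folds", {
  cfg <- tiny_config(n_per_class = 20, by = 4, seed = 41)
  prep <- preprocess_set(simulate_cohort(cfg))
  spec <- cnn_tiny(epochs = 1, seed = 6)
  set.seed(spec$seed)
  folds <- integer(n_spectra(prep))
  for (cl in levels(prep$labels)) {
    idx <- which(prep$labels == cl)
    folds[idx] <- sample(rep_len(1:5, length(idx)))
  }
  tab <- table(folds, prep$labels)
  expect_true(all(abs(tab - 4) <= 1))
  expect_true(all(rowSums(tab) == 20))
  # class with too few members
  small <- subset_spectra(prep, c(which(prep$labels == "normal"),
                                  which(prep$labels == "I")[1:3]))
  expect_error(kfold_cv(small, spec, k = 5), "at least k")
})

test_that("cross-validation recovers separable classes", {
  cfg <- simulation_config(cohort_sizes = c(normal = 25, I = 0, II = 0,
                                            III = 0, IV = 25),
                           grid = raman_grid(by = 4), noise_sd = 0.005,
                           scale_sd = 0.05, baseline_range = c(0.2, 0.5),
                           seed = 47)
  eff <- class_effect_model(effect_size = 0.5, subject_sd = 0.03)
  prep <- preprocess_set(simulate_cohort(cfg, effects = eff))
  cv <- kfold_cv(prep, cnn_tiny(epochs = 25, seed = 10), k = 5)
  expect_length(cv$fold_accuracy, 5)
  expect_gte(cv$mean_accuracy, 0.95)
  # same seed reproduces the fold assignment
  cv2 <- kfold_cv(prep, cnn_tiny(epochs = 1, seed = 10), k = 5)
  expect_identical(cv$folds, cv2$folds)
})

test_that("permuted training labels drive test accuracy to chance", {
  cfg <- tiny_config(n_per_class = 25, by = 4, seed = 59)
  prep <- preprocess_set(simulate_cohort(cfg))
  sp <- stratified_split(prep, split_plan(
    train = c(normal = 20, I = 20, II = 20, III = 20, IV = 20),
    test = c(normal = 5, I = 5, II = 5, III = 5, IV = 5), seed = 60))
  shuffled <- sp$train
  set.seed(61)
  shuffled$labels <- sample(shuffled$labels)
  m <- train_cnn(shuffled, cnn_tiny(epochs = 15, seed = 62))
  acc <- evaluate(m, sp$test)$overall_accuracy
  expect_gte(acc, 0.12)
  expect_lte(acc, 0.28)
})
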