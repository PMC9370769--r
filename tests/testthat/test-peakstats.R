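test_that("peak extraction follows the local-max convention", {
  g <- raman_grid(by = 1)                  # 1003 lies on this grid
  s <- spectrum_set(g, matrix(lorentz_ref(g, 1003, 10), ncol = 1))
  tab <- default_peak_table()
  pim <- extract_peak_intensities(s, tab, window = 4)
  expect_equal(unname(pim$values[1, "1003"]), 1)
  # window 0 reads the nearest grid point
  g2 <- raman_grid(by = 2)                 # nearest grid point is 1002
  s2 <- spectrum_set(g2, matrix(lorentz_ref(g2, 1003, 10), ncol = 1))
  pim0 <- extract_peak_intensities(s2, tab, window = 0)
  expect_equal(unname(pim0$values[1, "1003"]), lorentz_ref(1002, 1003, 10))
  # a +3 cm-1 calibration shift within the window barely changes the read
  s3 <- spectrum_set(g, matrix(lorentz_ref(g, 1006, 10), ncol = 1))
  pim3 <- extract_peak_intensities(s3, tab, window = 4)
  expect_lt(abs(pim3$values[1, "1003"] - pim$values[1, "1003"]) /
              pim$values[1, "1003"], 0.02)
  expect_error(extract_peak_intensities(s, tab, window = 1e5), "span")
})

test_that("Mann-Whitney matches the brute-force pair count on small samples", {
  set.seed(11)
  for (rep in 1:20) {
    n1 <- sample(2:10, 1)
    n2 <- sample(2:10, 1)
    a <- sample(1:8, n1, replace = TRUE)   # ties occur
    b <- sample(1:8, n2, replace = TRUE)
    res <- suppressWarnings(mann_whitney(a, b))
    expect_equal(unname(res$statistic), u_stat_ref(a, b))
  }
  # identical samples
  expect_warning(res <- mann_whitney(c(1, 2, 3), c(1, 2, 3) * 0 + c(1, 2, 3)),
                 regexp = NA)
  expect_gt(res$p_value, 0.99)
  # complete separation at n = 20/20: exact tail at U = 0
  a <- 1:20
  b <- 21:40
  res <- mann_whitney(a, b)
  expect_equal(unname(res$statistic), 0)
  expect_lt(res$p_value, 1e-4)
  expect_equal(res$direction, 1)
  # degenerate: all values identical
  expect_warning(res0 <- mann_whitney(rep(2, 5), rep(2, 6)), "identical")
  expect_equal(res0$p_value, 1)
})

test_that("Kruskal-Wallis matches the rank-formula oracle", {
  groups <- list(c(1, 2), c(11, 12), c(21, 22), c(31, 32))
  res <- kruskal_wallis(groups)
  expect_equal(unname(res$statistic), h_stat_ref(groups))
  set.seed(21)
  for (rep in 1:10) {
    gr <- lapply(1:4, function(i) sample(1:12, sample(2:6, 1), replace = TRUE))
    res <- kruskal_wallis(gr)
    expect_equal(unname(res$statistic), h_stat_ref(gr), tolerance = 1e-12)
  }
  # four identical groups
  same <- replicate(4, 1:10, simplify = FALSE)
  res <- kruskal_wallis(same)
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 1)
  expect_error(kruskal_wallis(list(1:3, 1:3)), "at least 3")
  expect_error(kruskal_wallis(list(1:3, 1:3, numeric(0))), "at least 2")
})

test_that("significance stars follow the strict caption thresholds", {
  expect_equal(significance_stars(0.03), "*")
  expect_equal(significance_stars(0.05), "ns")
  expect_equal(significance_stars(5e-5), "****")
  expect_equal(significance_stars(0.0001), "***")
  expect_equal(significance_stars(0.009), "**")
  expect_error(significance_stars(1.2), "\\[0, 1\\]")
})

test_that("difference spectra are antisymmetric and catch grid mismatch", {
  g <- raman_grid(by = 4)
  a <- spectrum_set(g, matrix(runif(351 * 3), ncol = 3))
  b <- spectrum_set(g, matrix(runif(351 * 3), ncol = 3))
  d1 <- difference_spectrum(a, b)
  d2 <- difference_spectrum(b, a)
  expect_equal(d1$intensity[, 1], -d2$intensity[, 1])
  expect_equal(difference_spectrum(a, a)$intensity[, 1],
               rep(0, length(g)))
  expect_error(difference_spectrum(a, spectrum_set(raman_grid(by = 8),
                                                   matrix(1, 176, 1))),
               "match")
})

test_that("NPC-minus-normal difference has the configured signs at key bands", {
  cfg <- tiny_config(n_per_class = 25, seed = 61)
  prep <- preprocess_set(simulate_cohort(cfg))
  npc <- subset_spectra(prep, prep$labels != "normal")
  nor <- subset_spectra(prep, prep$labels == "normal")
  d <- difference_spectrum(npc, nor)
  g <- prep$shifts
  expect_gt(d$intensity[which.min(abs(g - 1003)), 1], 0)
  expect_lt(d$intensity[which.min(abs(g - 1449)), 1], 0)
})

test_that("RSD is 100 sd/mean with guard rails", {
  expect_equal(rsd(c(9, 10, 11)), 10)
  expect_equal(rsd(rep(4.2, 30)), 0)
  expect_error(rsd(c(-1, 1)), "non-positive")
  # 30 replicate simulations of one subject: repeatability under low noise
  cfg <- simulation_config(grid = raman_grid(by = 4), noise_sd = 0.01,
                           scale_sd = 0, baseline_range = c(0.5, 0.5),
                           seed = 1)
  eff <- class_effect_model(subject_sd = 0)
  reps <- lapply(1:30, function(i)
    simulate_spectrum("normal", cfg, effects = eff, subject_seed = 1000 + i))
  set_ <- do.call(bind_spectra, reps)
  set_$sample_ids <- paste0("r", 1:30)
  colnames(set_$intensity) <- set_$sample_ids
  prep <- preprocess_set(set_)
  pim <- extract_peak_intensities(prep)
  expect_lt(rsd(pim$values[, "1003"]), 5)
})

test_that("the per-peak statistics table covers all bands and both tests", {
  cfg <- tiny_config(n_per_class = 8, seed = 71)
  prep <- preprocess_set(simulate_cohort(cfg))
  pim <- extract_peak_intensities(prep)
  tab <- peak_stats_table(pim)
  expect_equal(nrow(tab), 24)
  expect_true(all(tab$test == "mann-whitney-u"))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  kw <- peak_stats_table(pim, comparison = "stages")
  expect_true(all(kw$test == "kruskal-wallis"))
  bon <- peak_stats_table(pim, bonferroni = TRUE)
  expect_true(all(bon$p_adjusted >= bon$p_value))
  bs <- box_summary(pim)
  expect_equal(nrow(bs), 24 * 5)
  expect_true(all(bs$q1 <= bs$median & bs$median <= bs$q3))
})

test_that("rejection rate at 1003 cm-1 grows with the effect size", {
  rate_at <- function(effect, n_seeds = 25) {
    hits <- 0L
    for (s in seq_len(n_seeds)) {
      g <- sim_group_intensities(1003, 20, 20, "IV", 900000 + s * 100,
                                 effects = class_effect_model(
                                   effect_size = effect, stage_step = 0,
                                   subject_sd = 0.10), by = 8)
      res <- suppressWarnings(mann_whitney(g$a, g$b))
      hits <- hits + (res$p_value < 0.05)
    }
    hits / n_seeds
  }
  rates <- vapply(c(0, 0.05, 0.1, 0.2), rate_at, numeric(1))
  expect_true(all(diff(rates) >= -0.01))
  expect_gt(rates[4], rates[1])
})
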