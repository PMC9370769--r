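test_that("default peak table has the 24 bands with configured structure", {
  tab <- default_peak_table()
  expect_equal(nrow(tab), 24)
  top4 <- tab$shift[order(tab$base_amplitude, decreasing = TRUE)[1:4]]
  expect_setequal(top4, c(1003, 1266, 1449, 1679))
  expect_equal(sum(tab$direction == "up"), 9)
  expect_equal(sum(tab$direction == "down"), 13)
  expect_setequal(tab$shift[tab$direction == "none"], c(679, 1616))
  expect_setequal(tab$shift[tab$stage_trend == "linear"], c(1003, 1033))
})

test_that("expected spectra peak at the phenylalanine band and follow the amplitude rule", {
  for (lab in c("normal", "NPC", "I", "IV")) {
    es <- expected_spectrum(lab)
    peak <- es$shifts[which.max(es$intensity[, 1])]
    expect_lt(abs(peak - 1003), 2.01)   # 1003 is off the even 2 cm-1 grid
  }
  # null effects collapse all classes onto one spectrum
  null <- class_effect_model(effect_size = 0, stage_step = 0)
  base <- expected_spectrum("normal", effects = null)$intensity
  for (lab in c("NPC", "I", "II", "III", "IV"))
    expect_equal(expected_spectrum(lab, effects = null)$intensity[, 1],
                 base[, 1])
  # closed-form stage ratio at an isolated grid point near 1003
  eff <- class_effect_model()
  g <- raman_grid(by = 2)
  i1003 <- which.min(abs(g - 1003))
  # ratio holds exactly for the single-band contribution; compare spectra
  # built from the 1003 band alone
  tab <- default_peak_table()[default_peak_table()$shift == 1003, ]
  s1 <- expected_spectrum("I", peaks = tab, effects = eff)$intensity[i1003, 1]
  s4 <- expected_spectrum("IV", peaks = tab, effects = eff)$intensity[i1003, 1]
  expect_equal(unname(s4 / s1),
               (1 + 4 * eff$stage_step) / (1 + 1 * eff$stage_step))
  expect_error(expected_spectrum("V"), "unknown class label")
})

test_that("degenerate noise settings reproduce the expected spectrum exactly", {
  cfg <- simulation_config(grid = raman_grid(by = 4), noise_sd = 0,
                           scale_sd = 0, baseline_range = c(0, 0), seed = 5)
  eff <- class_effect_model(subject_sd = 0)
  s <- simulate_spectrum("II", cfg, effects = eff, subject_seed = 99)
  e <- expected_spectrum("II", effects = eff, grid = cfg$grid)
  expect_equal(s$intensity[, 1], e$intensity[, 1], tolerance = 1e-12)
})

test_that("simulation is seed-deterministic and non-negative", {
  cfg <- tiny_config(n_per_class = 4, seed = 31)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$intensity, b$intensity)
  expect_true(all(a$intensity >= 0))
  expect_equal(as.integer(class_counts(a)), rep(4L, 5))
  # different seed, different draws
  cfg2 <- tiny_config(n_per_class = 4, seed = 32)
  expect_false(identical(simulate_cohort(cfg2)$intensity, a$intensity))
})

test_that("cohort sizes drive membership", {
  cfg <- simulation_config(cohort_sizes = c(normal = 5, I = 0, II = 0,
                                            III = 0, IV = 0),
                           grid = raman_grid(by = 8), seed = 2)
  coh <- simulate_cohort(cfg)
  expect_equal(n_spectra(coh), 5)
  expect_true(all(coh$labels == "normal"))
})

test_that("Monte-Carlo mean converges toward the noise-free class mean", {
  # with baseline off and modest noise, the deviation of the empirical mean
  # from the expected spectrum shrinks roughly as 1/sqrt(n)
  eff <- class_effect_model(subject_sd = 0.05)
  base <- function(n, seed) {
    cfg <- simulation_config(cohort_sizes = c(normal = n, I = 0, II = 0,
                                              III = 0, IV = 0),
                             grid = raman_grid(by = 8),
                             baseline_range = c(0, 0), scale_sd = 0.05,
                             noise_sd = 0.02, seed = seed)
    coh <- simulate_cohort(cfg, effects = eff)
    exp_s <- expected_spectrum("normal", effects = eff, grid = cfg$grid)
    max(abs(rowMeans(coh$intensity) - exp_s$intensity[, 1]))
  }
  dev_small <- mean(vapply(1:5, function(s) base(8, 100 + s), numeric(1)))
  dev_large <- mean(vapply(1:5, function(s) base(128, 200 + s), numeric(1)))
  # sqrt(128/8) = 4; require a clear (>2x) reduction, the lognormal mean
  # bias exp(sd^2/2) bounds it away from the full factor
  expect_lt(dev_large, dev_small / 2)
})
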