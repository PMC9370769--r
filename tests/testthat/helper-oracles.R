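# Independent reference implementations used as oracles.  These are coded
# naively (explicit loops, closed forms) and never call the package's own
# computational path.

# closed-form Lorentzian with unit peak height
lorentz_ref <- function(x, center, fwhm) {
  g2 <- (fwhm / 2)^2
  g2 / ((x - center)^2 + g2)
}

# literal step-by-step iterative modified polynomial loop, refitting with
# lm() on a raw polynomial basis each round
imodpoly_ref <- function(shifts, y, order = 5, tol = 0.01, max_iter = 100) {
  x <- 2 * (shifts - min(shifts)) / (max(shifts) - min(shifts)) - 1
  polyfit <- function(xx, yy) {
    df <- data.frame(yy = yy)
    for (d in 0:order) df[[paste0("x", d)]] <- xx^d
    co <- stats::lm(yy ~ . - 1, data = df)$coefficients
    function(x2) {
      s <- 0
      for (d in 0:order) s <- s + co[d + 1] * x2^d
      s
    }
  }
  P <- polyfit(x, y)
  fit <- P(x)
  dev <- stats::sd(y - fit)
  history <- dev
  if (dev == 0)
    return(list(dev = dev, iterations = 0L, dev_history = history,
                baseline = fit))
  keep <- which(y <= fit + dev)
  if (length(keep) <= order + 1) keep <- seq_along(y)
  w <- y[keep]
  iter <- 0L
  repeat {
    iter <- iter + 1L
    P <- polyfit(x[keep], w)
    fitk <- P(x[keep])
    devn <- stats::sd(w - fitk)
    history <- c(history, devn)
    if (devn == 0 || abs(devn - dev) / devn < tol) {
      dev <- devn
      break
    }
    dev <- devn
    if (iter >= max_iter) break
    w <- pmin(w, fitk + dev)
  }
  list(dev = dev, iterations = iter, dev_history = history,
       baseline = P(x))
}

# brute-force Mann-Whitney U for group a (pair counting, half for ties)
u_stat_ref <- function(a, b) {
  u <- 0
  for (ai in a) for (bj in b)
    u <- u + (ai > bj) + 0.5 * (ai == bj)
  u
}

# brute-force tie-corrected Kruskal-Wallis H from mid-ranks
h_stat_ref <- function(groups) {
  vals <- unlist(groups)
  N <- length(vals)
  r <- rank(vals)
  sizes <- vapply(groups, length, integer(1))
  idx <- split(seq_len(N), rep(seq_along(groups), sizes))
  h <- 0
  for (g in seq_along(groups)) {
    rbar <- mean(r[idx[[g]]])
    h <- h + sizes[g] * (rbar - (N + 1) / 2)^2
  }
  h <- 12 * h / (N * (N + 1))
  ties <- table(vals)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# small cohorts on a coarse grid keep the test run fast
tiny_config <- function(n_per_class = 10, by = 4, seed = 1, ...) {
  simulation_config(
    cohort_sizes = c(normal = n_per_class, I = n_per_class, II = n_per_class,
                     III = n_per_class, IV = n_per_class),
    grid = raman_grid(by = by), seed = seed, ...)
}

trapz_ref <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# simulate intensities at one shift for two groups, through the real
# preprocessing path
sim_group_intensities <- function(shift, n_a, n_b, label_b, seed,
                                  effects = class_effect_model(), by = 4) {
  cfg <- simulation_config(
    cohort_sizes = c(normal = n_a, I = 0, II = 0, III = 0, IV = 0),
    grid = raman_grid(by = by), seed = seed)
  cfg$cohort_sizes[label_b] <- n_b
  set_ <- preprocess_set(simulate_cohort(cfg, effects = effects))
  pim <- extract_peak_intensities(set_)
  j <- match(as.character(shift), colnames(pim$values))
  list(a = pim$values[pim$labels == "normal", j],
       b = pim$values[pim$labels == label_b, j])
}
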