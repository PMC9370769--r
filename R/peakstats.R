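#' Extract per-sample peak intensities
#'
#' For each band in the peak table, reads the sample's intensity as the
#' local maximum within +/- \code{window} cm^-1 of the nominal shift
#' (robust to small calibration offsets); \code{window = 0} reads the
#' value at the nearest grid point.
#'
#' @param set a preprocessed (unit-area) \code{spectrum_set}.
#' @param peaks peak table with a \code{shift} column.
#' @param window half-width of the search window in cm^-1.
#' @return object of class \code{peak_intensity_matrix}: list with
#'   \code{values} (samples x peaks matrix, columns named by shift),
#'   \code{shifts}, \code{labels}, \code{sample_ids}.
#' @export
extract_peak_intensities <- function(set, peaks = default_peak_table(),
                                     window = 4) {
  stopifnot(window >= 0)
  span <- max(set$shifts) - min(set$shifts)
  if (window > span) stop("window exceeds the grid span")
  m <- matrix(0, nrow = n_spectra(set), ncol = nrow(peaks),
              dimnames = list(set$sample_ids, as.character(peaks$shift)))
  for (j in seq_len(nrow(peaks))) {
    if (window == 0) {
      idx <- which.min(abs(set$shifts - peaks$shift[j]))
    } else {
      idx <- which(abs(set$shifts - peaks$shift[j]) <= window)
      if (length(idx) == 0L)
        idx <- which.min(abs(set$shifts - peaks$shift[j]))
    }
    m[, j] <- apply(set$intensity[idx, , drop = FALSE], 2L, max)
  }
  structure(list(values = m, shifts = peaks$shift, labels = set$labels,
                 sample_ids = set$sample_ids),
            class = "peak_intensity_matrix")
}

#' Two-sided Mann-Whitney U test
#'
#' Wraps \code{stats::wilcox.test} with the conventions used throughout:
#' exact distribution when both groups have n <= 20 and no ties, otherwise
#' the tie-corrected normal approximation; the reported direction is the
#' sign of median(B) - median(A).
#'
#' @param a,b numeric samples (each n >= 2).
#' @return list with \code{test}, \code{statistic} (U for group \code{a}),
#'   \code{p_value}, \code{stars}, \code{direction}.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (length(unique(c(a, b))) == 1L) {
    warning("all values identical in both groups; p = 1")
    return(list(test = "mann-whitney-u", statistic = length(a) * length(b) / 2,
                p_value = 1, stars = "ns", direction = 0))
  }
  exact <- length(a) <= 20 && length(b) <= 20 && !anyDuplicated(c(a, b))
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  p <- min(ht$p.value, 1)
  list(test = "mann-whitney-u", statistic = unname(ht$statistic),
       p_value = p, stars = significance_stars(p),
       direction = sign(stats::median(b) - stats::median(a)))
}

#' Kruskal-Wallis rank test across three or more groups
#'
#' @param groups list of >= 3 numeric samples, each n >= 2.
#' @return list with \code{test}, \code{statistic} (tie-corrected H),
#'   \code{p_value} (chi-square, k-1 df), \code{stars}.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 3) stop("need at least 3 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs at least 2 values")
  vals <- unlist(groups)
  if (length(unique(vals)) == 1L) {
    warning("all values identical in all groups; p = 1")
    return(list(test = "kruskal-wallis", statistic = 0, p_value = 1,
                stars = "ns"))
  }
  ht <- stats::kruskal.test(groups)
  p <- min(ht$p.value, 1)
  list(test = "kruskal-wallis", statistic = unname(ht$statistic),
       p_value = p, stars = significance_stars(p))
}

#' Significance stars for a p-value
#'
#' \code{ns} for p >= 0.05, then \code{*} (< 0.05), \code{**} (< 0.01),
#' \code{***} (< 0.001), \code{****} (< 0.0001); boundaries are strict.
#'
#' @param p p-value in [0, 1].
#' @export
significance_stars <- function(p) {
  if (!is.finite(p) || p < 0 || p > 1) stop("p must be in [0, 1]")
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 1e-2) "**"
  else if (p < 0.05) "*"
  else "ns"
}

#' Difference of two mean spectra
#'
#' Pointwise mean(A) - mean(B); may be negative (it is a difference, not a
#' spectrum of counts).
#'
#' @param setA,setB \code{spectrum_set}s on identical grids.
#' @return single-column \code{spectrum_set} holding the difference.
#' @export
difference_spectrum <- function(setA, setB) {
  if (!isTRUE(all.equal(setA$shifts, setB$shifts, tolerance = 0)))
    stop("grids do not match")
  d <- rowMeans(setA$intensity) - rowMeans(setB$intensity)
  spectrum_set(setA$shifts, matrix(d, ncol = 1), sample_ids = "difference")
}

#' Relative standard deviation (repeatability), in percent
#'
#' @param x replicate measurements, n >= 2, positive mean.
#' @return 100 * sample-sd / mean.
#' @export
rsd <- function(x) {
  stopifnot(length(x) >= 2)
  m <- mean(x)
  if (m <= 0) stop("RSD undefined for non-positive mean")
  100 * stats::sd(x) / m
}

#' Per-peak group-comparison table
#'
#' One row per band: shift, assignment, per-class median intensities, the
#' test used, its statistic, p-value, stars, and (for the two-group
#' comparison) the direction of the NPC shift. \code{"npc-vs-normal"}
#' pools all four stages against the healthy group (Mann-Whitney U);
#' \code{"stages"} compares stages I--IV (Kruskal-Wallis).
#'
#' @param pim a \code{peak_intensity_matrix} with labels.
#' @param peaks the peak table the intensities were extracted with.
#' @param comparison \code{"npc-vs-normal"} or \code{"stages"}.
#' @param bonferroni if TRUE, adds a Bonferroni-adjusted p column (off by
#'   default; the per-band stars are reported unadjusted).
#' @return data.frame, one row per band.
#' @export
peak_stats_table <- function(pim, peaks = default_peak_table(),
                             comparison = c("npc-vs-normal", "stages"),
                             bonferroni = FALSE) {
  comparison <- match.arg(comparison)
  if (is.null(pim$labels)) stop("peak intensities carry no labels")
  lab <- as.character(pim$labels)
  rows <- lapply(seq_along(pim$shifts), function(j) {
    v <- pim$values[, j]
    med <- vapply(sers_classes(), function(cl)
      if (any(lab == cl)) stats::median(v[lab == cl]) else NA_real_,
      numeric(1))
    if (comparison == "npc-vs-normal") {
      res <- mann_whitney(v[lab == "normal"], v[lab != "normal"])
      dir <- res$direction
    } else {
      res <- kruskal_wallis(split(v[lab != "normal"], lab[lab != "normal"]))
      dir <- NA_real_
    }
    data.frame(shift = pim$shifts[j],
               assignment = peaks$assignment[match(pim$shifts[j], peaks$shift)],
               median_normal = med[["normal"]], median_I = med[["I"]],
               median_II = med[["II"]], median_III = med[["III"]],
               median_IV = med[["IV"]], test = res$test,
               statistic = res$statistic, p_value = res$p_value,
               stars = res$stars, direction = dir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bonferroni) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "bonferroni")
    out$stars_adjusted <- vapply(out$p_adjusted, significance_stars,
                                 character(1))
  }
  out
}

#' Box-plot summary statistics per band and class
#'
#' Median, quartiles and Tukey whiskers (1.5 IQR) for each band within
#' each class, suitable for TSV export.
#'
#' @param pim a labeled \code{peak_intensity_matrix}.
#' @return data.frame with one row per (band, class).
#' @export
box_summary <- function(pim) {
  if (is.null(pim$labels)) stop("peak intensities carry no labels")
  lab <- as.character(pim$labels)
  out <- list()
  for (j in seq_along(pim$shifts)) {
    for (cl in unique(lab)) {
      v <- pim$values[lab == cl, j]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3] - q[1]
      out[[length(out) + 1L]] <- data.frame(
        shift = pim$shifts[j], class = cl, n = length(v),
        q1 = q[1], median = q[2], q3 = q[3],
        whisker_low = min(v[v >= q[1] - 1.5 * iqr]),
        whisker_high = max(v[v <= q[3] + 1.5 * iqr]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
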