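#' Raman shift grid
#'
#' Constructs a uniformly spaced, strictly increasing Raman shift axis in
#' cm^-1. The default covers the fingerprint window 400--1800 cm^-1 at
#' 2 cm^-1 spacing (701 points), which oversamples the nominal 8 cm^-1
#' instrument resolution while keeping downstream classifiers tractable.
#'
#' @param from,to span of the axis in cm^-1.
#' @param by grid spacing in cm^-1.
#' @return Numeric vector of shifts with class \code{raman_grid}.
#' @export
raman_grid <- function(from = 400, to = 1800, by = 2) {
  shifts <- seq(from, to, by = by)
  validate_grid(shifts)
  structure(shifts, class = c("raman_grid", "numeric"))
}

validate_grid <- function(shifts) {
  if (length(shifts) < 2L) stop("grid needs at least two points")
  d <- diff(shifts)
  if (any(d <= 0)) stop("Raman shift axis must be strictly increasing")
  if (max(d) - min(d) > 1e-9) stop("Raman shift axis must be uniformly spaced")
  invisible(shifts)
}

#' Class labels used throughout the package
#'
#' Healthy controls plus the four TNM stages of nasopharyngeal carcinoma.
#' @export
sers_classes <- function() c("normal", "I", "II", "III", "IV")

as_sers_label <- function(x) {
  lv <- sers_classes()
  f <- factor(as.character(x), levels = lv)
  if (anyNA(f) && !anyNA(x)) {
    bad <- setdiff(unique(as.character(x)), lv)
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  }
  f
}

#' Set of SERS spectra on a common Raman grid
#'
#' The central container: an intensity matrix with one column per sample
#' (spectrum) and one row per grid point, plus optional class labels.
#'
#' @param shifts Raman shift axis (cm^-1), strictly increasing, uniform.
#' @param intensity numeric matrix, \code{length(shifts)} rows, one column
#'   per sample. All values must be finite.
#' @param labels optional vector of class labels (\code{"normal"},
#'   \code{"I"}..\code{"IV"}), one per sample.
#' @param sample_ids optional character vector of sample identifiers;
#'   defaults to the column names or \code{s1, s2, ...}.
#' @return An object of class \code{spectrum_set}.
#' @export
spectrum_set <- function(shifts, intensity, labels = NULL, sample_ids = NULL) {
  validate_grid(shifts)
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(shifts))
    stop("intensity must have one row per grid point")
  if (!all(is.finite(intensity))) stop("all intensities must be finite")
  n <- ncol(intensity)
  if (is.null(sample_ids)) {
    sample_ids <- colnames(intensity)
    if (is.null(sample_ids))
      sample_ids <- paste0("s", seq_len(n), recycle0 = TRUE)
  }
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (length(sample_ids) != n) stop("one sample_id per spectrum required")
  colnames(intensity) <- sample_ids
  if (!is.null(labels)) {
    if (length(labels) != n) stop("one label per spectrum required")
    labels <- as_sers_label(labels)
  }
  structure(
    list(shifts = as.numeric(shifts), intensity = intensity,
         labels = labels, sample_ids = sample_ids),
    class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra, grid %g..%g cm-1 (%d points)\n",
              n_spectra(x), min(x$shifts), max(x$shifts), length(x$shifts)))
  if (!is.null(x$labels)) {
    cc <- class_counts(x)
    cat("  classes:", paste(sprintf("%s=%d", names(cc), cc), collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of spectra in a set
#' @param set a \code{spectrum_set}.
#' @export
n_spectra <- function(set) ncol(set$intensity)

#' Per-class spectrum counts
#' @param set a labeled \code{spectrum_set}.
#' @return Named integer vector over the five class levels.
#' @export
class_counts <- function(set) {
  if (is.null(set$labels)) stop("set is unlabeled")
  table(set$labels)
}

#' Subset a spectrum set by sample index
#' @param set a \code{spectrum_set}.
#' @param idx integer or logical index over samples.
#' @export
subset_spectra <- function(set, idx) {
  spectrum_set(set$shifts, set$intensity[, idx, drop = FALSE],
               labels = if (!is.null(set$labels)) set$labels[idx],
               sample_ids = set$sample_ids[idx])
}

#' Combine spectrum sets sharing one grid
#' @param ... \code{spectrum_set} objects on identical grids.
#' @export
bind_spectra <- function(...) {
  sets <- list(...)
  g <- sets[[1]]$shifts
  for (s in sets) {
    if (!isTRUE(all.equal(s$shifts, g, tolerance = 0)))
      stop("all sets must share an identical grid")
  }
  labs <- lapply(sets, function(s) s$labels)
  has_lab <- !vapply(labs, is.null, logical(1))
  labels <- if (all(has_lab)) unlist(lapply(labs, as.character)) else NULL
  spectrum_set(g, do.call(cbind, lapply(sets, function(s) s$intensity)),
               labels = labels,
               sample_ids = unlist(lapply(sets, function(s) s$sample_ids)))
}

# fixed float formatting so write/read round trips are bit-stable
fmt_num <- function(x) formatC(x, format = "g", digits = 9)

#' Write a spectrum set to CSV
#'
#' Column 1 is the shift axis (header \code{raman_shift_cm-1}); remaining
#' columns are samples named by \code{sample_id}. When labels are present
#' they are carried in a first data row whose shift cell is \code{# label}.
#' Numbers are written with 9 significant digits, so a write/read round
#' trip preserves intensities to better than 1e-9 relative.
#'
#' @param set non-empty \code{spectrum_set}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_spectra <- function(set, path) {
  if (!inherits(set, "spectrum_set")) stop("set must be a spectrum_set")
  if (n_spectra(set) == 0L) stop("cannot write an empty spectrum set")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("raman_shift_cm-1", set$sample_ids), collapse = ","), con)
  if (!is.null(set$labels))
    writeLines(paste(c("# label", as.character(set$labels)), collapse = ","), con)
  body <- cbind(fmt_num(set$shifts),
                matrix(fmt_num(set$intensity), nrow = length(set$shifts)))
  writeLines(apply(body, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Read a spectrum set from CSV
#'
#' Accepts the dialect written by \code{\link{write_spectra}}, and, for
#' convenience, a plain two-column \code{shift,intensity} file (one
#' spectrum, no header required beyond the shift column name).
#'
#' @param path CSV file path.
#' @return A \code{spectrum_set}; labels attached when the file carries a
#'   \code{# label} row.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "character", comment.char = "")
  if (ncol(raw) < 2L) stop("malformed spectra CSV: need shift + >=1 sample column")
  labels <- NULL
  if (nrow(raw) > 0L && grepl("^#\\s*label", raw[[1]][1])) {
    labels <- as.character(raw[1, -1])
    raw <- raw[-1, , drop = FALSE]
  }
  shifts <- suppressWarnings(as.numeric(raw[[1]]))
  if (anyNA(shifts)) stop("malformed spectra CSV: non-numeric shift values")
  if (any(diff(shifts) <= 0))
    stop("malformed spectra CSV: shift column must be strictly increasing")
  intensity <- vapply(raw[-1], function(col) {
    v <- suppressWarnings(as.numeric(col))
    if (anyNA(v)) stop("malformed spectra CSV: non-numeric or ragged intensity column")
    v
  }, numeric(nrow(raw)))
  intensity <- matrix(intensity, nrow = length(shifts),
                      dimnames = list(NULL, names(raw)[-1]))
  spectrum_set(shifts, intensity, labels = labels)
}

#' Resample spectra onto a new grid by linear interpolation
#'
#' @param set a \code{spectrum_set}.
#' @param target target shift axis; its span must lie within the source span.
#' @return The set interpolated onto \code{target}; endpoints are exact.
#' @export
resample <- function(set, target) {
  validate_grid(target)
  if (min(target) < min(set$shifts) || max(target) > max(set$shifts))
    stop("target grid extends beyond the source span")
  out <- apply(set$intensity, 2L, function(y)
    stats::approx(set$shifts, y, xout = target, method = "linear")$y)
  out <- matrix(out, nrow = length(target))
  spectrum_set(as.numeric(target), out, labels = set$labels,
               sample_ids = set$sample_ids)
}
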