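# trapezoidal integral on a (possibly non-uniform) axis
trapz_area <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Iterative improved modified polynomial (I-ModPoly) baseline fit
#'
#' Estimates the fluorescence background of a Raman spectrum by iterative
#' polynomial fitting that accounts for the noise level and excludes peak
#' contributions:
#' \enumerate{
#'   \item least-squares polynomial fit P0 of the given order on the full
#'     grid; DEV0 = standard deviation of the residual (spectrum - P0);
#'   \item first iteration: points with intensity > P0 + DEV0 (peaks) are
#'     removed from the working data for all subsequent fits;
#'   \item subsequent iterations replace the working data by
#'     \code{min(w, P + DEV)} of the previous round, refit, and recompute
#'     DEV;
#'   \item stop when the relative DEV change falls below \code{tol} or at
#'     \code{max_iter}.
#' }
#' The fitted polynomial, evaluated on the full grid, is the baseline; the
#' corrected spectrum is \code{max(input - baseline, 0)}.
#'
#' @param shifts Raman shift axis.
#' @param y intensity vector (finite).
#' @param order polynomial order (default 5, the order used for protein
#'   SERS fluorescence backgrounds).
#' @param tol relative DEV convergence tolerance.
#' @param max_iter iteration cap; hitting it is recorded, not an error.
#' @return list with \code{baseline}, \code{corrected}, \code{iterations},
#'   \code{dev_history}, \code{converged}, \code{n_clipped}.
#' @export
imodpoly_baseline <- function(shifts, y, order = 5, tol = 0.01,
                              max_iter = 100) {
  stopifnot(order >= 1, length(y) == length(shifts),
            length(y) > order + 1, all(is.finite(y)))
  # fit on an axis rescaled to [-1, 1]: raw cm^-1 powers are ill-conditioned
  x <- 2 * (shifts - min(shifts)) / (max(shifts) - min(shifts)) - 1
  X <- outer(x, 0:order, `^`)
  qr_full <- qr(X)
  beta <- qr.coef(qr_full, y)
  fit <- drop(X %*% beta)
  dev <- stats::sd(y - fit)
  dev_history <- dev
  if (dev == 0) {                      # already an exact polynomial
    return(list(baseline = fit, corrected = pmax(y - fit, 0),
                iterations = 0L, dev_history = dev_history,
                converged = TRUE, n_clipped = sum(y - fit < 0)))
  }
  keep <- y <= fit + dev
  if (sum(keep) <= order + 1) keep <- rep(TRUE, length(y))
  Xk <- X[keep, , drop = FALSE]
  qr_keep <- qr(Xk)
  w <- y[keep]
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    beta <- qr.coef(qr_keep, w)
    fit_k <- drop(Xk %*% beta)
    dev_new <- stats::sd(w - fit_k)
    dev_history <- c(dev_history, dev_new)
    if (dev_new == 0 || abs(dev_new - dev) / dev_new < tol) {
      converged <- TRUE
      dev <- dev_new
      break
    }
    dev <- dev_new
    if (iter >= max_iter) break
    w <- pmin(w, fit_k + dev)
  }
  baseline <- drop(X %*% beta)
  corrected <- pmax(y - baseline, 0)
  list(baseline = baseline, corrected = corrected, iterations = iter,
       dev_history = dev_history, converged = converged,
       n_clipped = sum(y - baseline < 0))
}

#' Area-normalize a spectrum to unit integrated intensity
#'
#' Divides by the trapezoidal integral over the full axis so the area under
#' the spectrum equals 1, converting absolute to relative intensity and
#' removing laser-power / concentration scale.
#'
#' @param shifts Raman shift axis.
#' @param y intensity vector with positive integral.
#' @return rescaled intensity vector.
#' @export
area_normalize <- function(shifts, y) {
  a <- trapz_area(shifts, y)
  if (!is.finite(a) || a <= 0)
    stop("cannot area-normalize: integrated intensity is not positive")
  y / a
}

#' Preprocess a spectrum set: baseline subtraction + area normalization
#'
#' Applies \code{\link{imodpoly_baseline}} followed by
#' \code{\link{area_normalize}} to every spectrum, preserving labels and
#' order. A per-spectrum processing log (iteration count, convergence,
#' number of clipped points) is attached as attribute \code{"log"}.
#'
#' @param set a \code{spectrum_set}.
#' @inheritParams imodpoly_baseline
#' @return preprocessed \code{spectrum_set} (each spectrum has unit
#'   trapezoidal area) with a \code{"log"} attribute.
#' @export
preprocess_set <- function(set, order = 5, tol = 0.01, max_iter = 100) {
  n <- n_spectra(set)
  out <- set$intensity
  log <- data.frame(sample_id = set$sample_ids,
                    iterations = integer(n), converged = logical(n),
                    n_clipped = integer(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    res <- tryCatch(
      imodpoly_baseline(set$shifts, set$intensity[, i], order, tol, max_iter),
      error = function(e) stop("sample '", set$sample_ids[i], "': ",
                               conditionMessage(e), call. = FALSE))
    y <- tryCatch(area_normalize(set$shifts, res$corrected),
                  error = function(e) stop("sample '", set$sample_ids[i],
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
    out[, i] <- y
    log$iterations[i] <- res$iterations
    log$converged[i] <- res$converged
    log$n_clipped[i] <- res$n_clipped
  }
  res <- spectrum_set(set$shifts, out, labels = set$labels,
                      sample_ids = set$sample_ids)
  attr(res, "log") <- log
  res
}

#' Processing log of a preprocessed set
#' @param set the result of \code{\link{preprocess_set}}.
#' @export
preprocess_log <- function(set) attr(set, "log")
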