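#' PCA-LDA chemometric classifier
#'
#' Mean-centered principal component analysis reduced to
#' \code{n_components} scores, followed by multi-class linear discriminant
#' analysis on the scores. The PCA rotation is fitted on the training set
#' only and applied to any later data. If the within-class scatter is
#' singular, a small ridge (1e-6 on the score covariance diagonal) is
#' added and the fallback is noted in the returned object.
#'
#' @param train labeled \code{spectrum_set} (preprocessed).
#' @param n_components number of retained principal components; must be
#'   smaller than both the sample count and the grid length.
#' @return object of class \code{pcalda_model} with the PCA basis, the
#'   fitted LDA, and \code{scores}: per-sample coordinates on the first
#'   two discriminant axes of the training set.
#' @export
fit_pca_lda <- function(train, n_components = 20) {
  if (is.null(train$labels)) stop("PCA-LDA requires labeled spectra")
  X <- t(train$intensity)                       # samples x features
  if (n_components >= min(nrow(X), ncol(X)))
    stop("n_components must be < min(n_samples, n_features)")
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE,
                       rank. = n_components)
  scores <- pca$x[, seq_len(n_components), drop = FALSE]
  labels <- droplevels(train$labels)
  ridge_used <- FALSE
  lda_fit <- tryCatch(
    MASS::lda(scores, grouping = labels),
    error = function(e) {
      ridge_used <<- TRUE
      ridge_lda(scores, labels, ridge = 1e-6)
    })
  ld <- lda_project(lda_fit, scores)$x
  structure(list(pca = pca, lda = lda_fit, n_components = n_components,
                 classes = sers_classes(), shifts = train$shifts,
                 ridge_used = ridge_used,
                 scores = ld[, seq_len(min(2L, ncol(ld))), drop = FALSE]),
            class = "pcalda_model")
}

#' Class posteriors from a fitted PCA-LDA model
#'
#' @param object a \code{pcalda_model}.
#' @param newdata \code{spectrum_set} on the training grid.
#' @param ... unused.
#' @return matrix (samples x classes) of posterior probabilities; classes
#'   absent from training get probability 0.
#' @export
predict.pcalda_model <- function(object, newdata, ...) {
  if (!isTRUE(all.equal(newdata$shifts, object$shifts, tolerance = 0)))
    stop("grid mismatch: resample spectra onto the training grid first")
  sc <- stats::predict(object$pca,
                       t(newdata$intensity))[, seq_len(object$n_components),
                                             drop = FALSE]
  post <- lda_project(object$lda, sc)$posterior
  out <- matrix(0, nrow(post), length(object$classes),
                dimnames = list(newdata$sample_ids, object$classes))
  out[, colnames(post)] <- post
  out
}

#' Project spectra onto the fitted discriminant axes
#'
#' @param model a \code{pcalda_model}.
#' @param set \code{spectrum_set} on the training grid.
#' @return matrix of coordinates on the LDA axes (up to the first two).
#' @export
lda_scores <- function(model, set) {
  sc <- stats::predict(model$pca,
                       t(set$intensity))[, seq_len(model$n_components),
                                         drop = FALSE]
  ld <- lda_project(model$lda, sc)$x
  ld[, seq_len(min(2L, ncol(ld))), drop = FALSE]
}

# uniform projection interface over MASS::lda and the ridge fallback
lda_project <- function(fit, scores) {
  if (inherits(fit, "ridge_lda")) {
    # linear discriminant functions of the equal-covariance Gaussian model
    d <- scores %*% fit$coef
    d <- sweep(d, 2L, fit$const, `+`)        # log-posterior up to a constant
    d <- d - apply(d, 1L, max)
    post <- exp(d) / rowSums(exp(d))
    colnames(post) <- fit$classes
    x <- scale(scores, center = fit$grand_mean, scale = FALSE) %*% fit$axes
    colnames(x) <- paste0("LD", seq_len(ncol(x)))
    list(x = x, posterior = post)
  } else {
    p <- stats::predict(fit, scores)
    list(x = p$x, posterior = p$posterior)
  }
}

# LDA with a diagonal ridge on the pooled within-class covariance, used
# when the scatter is singular (e.g. constant score dimensions)
ridge_lda <- function(scores, labels, ridge = 1e-6) {
  classes <- levels(labels)
  p <- ncol(scores)
  means <- t(vapply(classes, function(cl)
    colMeans(scores[labels == cl, , drop = FALSE]), numeric(p)))
  Sw <- matrix(0, p, p)
  for (cl in classes) {
    Xc <- scale(scores[labels == cl, , drop = FALSE],
                center = means[cl, ], scale = FALSE)
    Sw <- Sw + crossprod(Xc)
  }
  Sw <- Sw / (nrow(scores) - length(classes)) + ridge * diag(p)
  prior <- as.numeric(table(labels)) / length(labels)
  Swi <- solve(Sw)
  coef <- Swi %*% t(means)                       # p x k discriminant coefs
  const <- -0.5 * colSums(t(means) * coef) + log(prior)
  # discriminant axes: eigenvectors of solve(Sw) %*% Sb
  gm <- colMeans(scores)
  Sb <- matrix(0, p, p)
  for (i in seq_along(classes)) {
    d <- means[i, ] - gm
    Sb <- Sb + prior[i] * tcrossprod(d)
  }
  ev <- eigen(Swi %*% Sb)
  k <- min(length(classes) - 1L, p)
  axes <- Re(ev$vectors[, seq_len(k), drop = FALSE])
  structure(list(coef = coef, const = const, axes = axes, grand_mean = gm,
                 classes = classes, prior = prior),
            class = "ridge_lda")
}
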