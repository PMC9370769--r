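#' 1D CNN specification
#'
#' The five-block convolutional architecture used for five-class spectral
#' classification: each block is two stacked convolution layers (kernel
#' length 3, stride 1, tanh activation) followed by max-pooling (window 3,
#' stride 1), with kernel counts 16, 32, 64, 128, 256 across the blocks;
#' the head is flatten, a tanh fully connected layer, and a softmax output
#' over the five classes. Training uses Adam on the cross-entropy loss for
#' 100 epochs with batch size 20 and learning rate 0.001.
#'
#' Stride-1 pooling barely downsamples, which makes the flattened layer
#' very wide; \code{pool_stride = 3} selects the conventional
#' non-overlapping variant used for the package's own training
#' experiments.
#'
#' @param channels kernel counts of the five blocks.
#' @param kernel_size convolution kernel length.
#' @param pool_size,pool_stride max-pooling window and stride.
#' @param fc_width width of the fully connected hidden layer.
#' @param n_class number of output classes.
#' @param epochs,batch_size,learning_rate Adam training hyperparameters.
#' @param seed seed for weight initialization and batch shuffling.
#' @export
cnn_spec <- function(channels = c(16, 32, 64, 128, 256), kernel_size = 3,
                     pool_size = 3, pool_stride = 1, fc_width = 64,
                     n_class = 5, epochs = 100, batch_size = 20,
                     learning_rate = 0.001, seed = 1L) {
  stopifnot(length(channels) >= 1, all(channels >= 1), kernel_size == 3,
            pool_size >= 2, pool_stride >= 1, fc_width >= 1, n_class >= 2,
            epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(channels = as.integer(channels),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 pool_stride = as.integer(pool_stride),
                 fc_width = as.integer(fc_width),
                 n_class = as.integer(n_class),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 optimizer = "adam", loss = "cross-entropy",
                 seed = as.integer(seed)),
            class = "cnn_spec")
}

# per-stage spatial lengths; errors if pooling exhausts the signal
cnn_lengths <- function(spec, input_len) {
  len <- integer(length(spec$channels) + 1L)
  len[1] <- input_len
  for (k in seq_along(spec$channels)) {
    len[k + 1] <- (len[k] - spec$pool_size) %/% spec$pool_stride + 1L
    if (len[k] < spec$pool_size || len[k + 1] < 1L)
      stop("input length ", input_len, " too short for ",
           length(spec$channels), " pooling stages")
  }
  len
}

#' Layer-by-layer architecture table
#'
#' Introspection view of the instantiated network: one row per layer with
#' type, kernel count, kernel size, stride, activation, and the output
#' length/channels at the given input length.
#'
#' @param spec a \code{\link{cnn_spec}}.
#' @param input_len spectrum length the network is applied to.
#' @return data.frame, one row per layer.
#' @export
cnn_architecture <- function(spec, input_len = 701) {
  len <- cnn_lengths(spec, input_len)
  rows <- list(data.frame(layer = "input", kernels = NA_integer_,
                          kernel_size = NA_integer_, stride = NA_integer_,
                          activation = NA_character_, out_len = input_len,
                          out_channels = 1L, stringsAsFactors = FALSE))
  for (k in seq_along(spec$channels)) {
    for (j in 1:2)
      rows[[length(rows) + 1L]] <- data.frame(
        layer = "conv", kernels = spec$channels[k],
        kernel_size = spec$kernel_size, stride = 1L, activation = "tanh",
        out_len = len[k], out_channels = spec$channels[k],
        stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = "maxpool", kernels = NA_integer_, kernel_size = spec$pool_size,
      stride = spec$pool_stride, activation = NA_character_,
      out_len = len[k + 1], out_channels = spec$channels[k],
      stringsAsFactors = FALSE)
  }
  flat <- len[length(len)] * spec$channels[length(spec$channels)]
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "flatten", kernels = NA_integer_, kernel_size = NA_integer_,
    stride = NA_integer_, activation = NA_character_, out_len = flat,
    out_channels = 1L, stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "dense", kernels = spec$fc_width, kernel_size = NA_integer_,
    stride = NA_integer_, activation = "tanh", out_len = spec$fc_width,
    out_channels = 1L, stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "softmax", kernels = spec$n_class, kernel_size = NA_integer_,
    stride = NA_integer_, activation = "softmax", out_len = spec$n_class,
    out_channels = 1L, stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

cnn_init_weights <- function(spec, input_len) {
  convW <- list(); convB <- list()
  cin <- 1L
  l <- 0L
  for (k in seq_along(spec$channels)) {
    cout <- spec$channels[k]
    for (j in 1:2) {
      l <- l + 1L
      convW[[l]] <- glorot(cout, 3L * cin, 3L * cin, 3L * cout)
      convB[[l]] <- numeric(cout)
      cin <- cout
    }
  }
  len <- cnn_lengths(spec, input_len)
  flat <- len[length(len)] * cin
  fcW <- glorot(spec$fc_width, flat, flat, spec$fc_width)
  outW <- glorot(spec$n_class, spec$fc_width, spec$fc_width, spec$n_class)
  list(convW = convW, convB = convB, fcW = fcW,
       fcB = numeric(spec$fc_width), outW = outW,
       outB = numeric(spec$n_class))
}

cnn_labels_int <- function(set) {
  if (is.null(set$labels)) stop("training requires labeled spectra")
  as.integer(set$labels) - 1L
}

#' Train the 1D CNN
#'
#' Mini-batch backpropagation with Adam on the cross-entropy loss, for
#' exactly \code{spec$epochs} epochs with seeded shuffling. Weight
#' initialization (Glorot uniform) and batch order are the only sources of
#' randomness and are driven by \code{spec$seed}, so training is
#' deterministic given the seed.
#'
#' @param train labeled, preprocessed \code{spectrum_set} with at least
#'   \code{spec$batch_size} spectra.
#' @param spec a \code{\link{cnn_spec}}.
#' @return object of class \code{cnn_model}: weights, the spec, the
#'   training grid, and per-epoch \code{curves} (loss and accuracy on the
#'   training batches).
#' @export
train_cnn <- function(train, spec = cnn_spec()) {
  y <- cnn_labels_int(train)
  n <- n_spectra(train)
  if (n < spec$batch_size)
    stop("need at least batch_size (", spec$batch_size, ") training spectra")
  input_len <- length(train$shifts)
  cnn_lengths(spec, input_len)   # architecture feasibility check
  # standardize intensities with training-set statistics: unit-area spectra
  # have O(1e-3) values, which starves a deep tanh stack of signal
  center <- mean(train$intensity)
  scale <- stats::sd(as.numeric(train$intensity))
  if (scale == 0) scale <- 1
  X <- (train$intensity - center) / scale
  set.seed(spec$seed)
  w0 <- cnn_init_weights(spec, input_len)
  order <- t(vapply(seq_len(spec$epochs), function(e) sample.int(n) - 1L,
                    integer(n)))
  fit <- cnn_train_cpp(X, y, w0,
                       rep(spec$channels, each = 2L), spec$pool_size,
                       spec$pool_stride, order, spec$batch_size,
                       spec$learning_rate)
  structure(list(spec = spec, weights = fit$weights, shifts = train$shifts,
                 classes = sers_classes(),
                 scaling = c(center = center, scale = scale),
                 curves = data.frame(epoch = seq_len(spec$epochs),
                                     loss = as.numeric(fit$loss),
                                     accuracy = as.numeric(fit$accuracy))),
            class = "cnn_model")
}

#' Class-membership probabilities from a trained CNN
#'
#' @param object a \code{cnn_model}.
#' @param newdata \code{spectrum_set} on the training grid.
#' @param ... unused.
#' @return matrix (samples x classes) of softmax probabilities.
#' @export
predict.cnn_model <- function(object, newdata, ...) {
  if (!isTRUE(all.equal(newdata$shifts, object$shifts, tolerance = 0)))
    stop("grid mismatch: resample spectra onto the training grid first")
  X <- (newdata$intensity - object$scaling[["center"]]) /
    object$scaling[["scale"]]
  p <- cnn_predict_cpp(X, object$weights,
                       rep(object$spec$channels, each = 2L),
                       object$spec$pool_size, object$spec$pool_stride, 64L)
  colnames(p) <- object$classes
  rownames(p) <- newdata$sample_ids
  p
}

#' Evaluate a classifier on a labeled test set
#'
#' @param model a \code{cnn_model} or \code{pcalda_model}.
#' @param test labeled \code{spectrum_set} on the training grid.
#' @return object of class \code{class_report}: 5x5 \code{confusion}
#'   (rows = true class), \code{per_class_accuracy} (class-wise recall),
#'   \code{overall_accuracy}.
#' @export
evaluate <- function(model, test) {
  if (is.null(test$labels)) stop("evaluation requires labeled spectra")
  probs <- stats::predict(model, test)
  pred <- factor(colnames(probs)[max.col(probs, ties.method = "first")],
                 levels = sers_classes())
  confusion <- table(true = test$labels, predicted = pred)
  per_class <- diag(confusion) / pmax(rowSums(confusion), 1L)
  structure(list(confusion = confusion,
                 per_class_accuracy = per_class,
                 overall_accuracy = sum(diag(confusion)) / sum(confusion)),
            class = "class_report")
}

#' @export
print.class_report <- function(x, ...) {
  cat(sprintf("overall accuracy: %.1f%%\n", 100 * x$overall_accuracy))
  cat("per-class accuracy (recall):\n")
  print(round(100 * x$per_class_accuracy, 1))
  cat("confusion matrix (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

#' Stratified k-fold cross-validation of the CNN
#'
#' Seeded stratified fold assignment (each class spread across folds as
#' evenly as possible), one model per fold; reports held-out-fold overall
#' accuracies and their mean.
#'
#' @param train labeled \code{spectrum_set}.
#' @param spec a \code{\link{cnn_spec}}.
#' @param k number of folds.
#' @return list with \code{fold_accuracy} (length k), \code{mean_accuracy},
#'   and the fold assignment.
#' @export
kfold_cv <- function(train, spec = cnn_spec(), k = 5) {
  if (k < 2) stop("k must be at least 2")
  if (is.null(train$labels)) stop("cross-validation requires labels")
  cc <- table(train$labels)
  cc <- cc[cc > 0]
  if (any(cc < k))
    stop("every represented class needs at least k = ", k, " members")
  set.seed(spec$seed)
  folds <- integer(n_spectra(train))
  for (cl in names(cc)) {
    idx <- which(train$labels == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  acc <- vapply(seq_len(k), function(f) {
    fit <- train_cnn(subset_spectra(train, folds != f), spec)
    evaluate(fit, subset_spectra(train, folds == f))$overall_accuracy
  }, numeric(1))
  list(fold_accuracy = acc, mean_accuracy = mean(acc), folds = folds)
}
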