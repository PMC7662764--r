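#' Training control parameters
#'
#' Optimizer and stopping settings for [stgcn()].  Training uses stochastic
#' gradient descent with classical momentum on the cross-entropy loss and
#' stops early once the epoch training loss has improved by less than `tol`
#' for `patience` consecutive epochs.
#'
#' @param lr Positive initial learning rate.
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum number of epochs.
#' @param tol Minimum loss improvement counted as progress.
#' @param patience Consecutive non-improving epochs before stopping.
#' @param min_epochs Epochs before early stopping may trigger.
#' @param decay_epochs Epochs after which the learning rate is multiplied
#'   by `decay_factor` (step schedule).
#' @param decay_factor Multiplicative learning-rate decay.
#' @param warmup Linear learning-rate warmup epochs (stabilizes the first
#'   batch-norm statistics).
#' @param clip_norm Global gradient-norm clipping threshold (`Inf`
#'   disables); available for heavy-tailed inputs.
#' @param shuffle Reshuffle sample order every epoch.
#' @return A list of class `stgcn_control`.
#' @export
stgcn_control <- function(lr = 0.05, momentum = 0.9, batch_size = 128L,
                          max_epochs = 20L, tol = 1e-3, patience = 3L,
                          min_epochs = 14L, decay_epochs = c(14L, 18L),
                          decay_factor = 0.3, warmup = 2L, clip_norm = Inf,
                          shuffle = TRUE) {
  if (lr < 0) stop("learning rate must be nonnegative")
  if (patience < 1L) stop("patience must be at least 1")
  structure(list(lr = lr, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), tol = tol,
                 patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs),
                 decay_epochs = as.integer(decay_epochs),
                 decay_factor = decay_factor, warmup = as.integer(warmup),
                 clip_norm = clip_norm, shuffle = isTRUE(shuffle)),
            class = "stgcn_control")
}

#' Fit a spatial-temporal graph convolutional stroke classifier
#'
#' Trains the three-layer ST-GCN of this package on labeled motion samples:
#' three units of spatial graph convolution (degree-normalized adjacency
#' aggregation plus channel map), depthwise temporal convolution, batch
#' normalization and ReLU, with 32/64/64 feature maps; global average
#' pooling over joints and time; a 1x1 convolution; concatenation with the
#' standardized active-feature vector; and a fully connected softmax layer
#' over the three classes (forehand, backhand, no-shot).
#'
#' With `fuzzy = TRUE` the two coordinate channels are expanded into six
#' trapezoidal membership channels (low/mid/high per coordinate) before
#' entering the network; the fuzzy bank is fitted on the training data
#' unless one is supplied.  The active features are always computed from
#' the raw coordinates and are z-scored with training-set statistics.
#'
#' @param x Training data: a `motion_dataset`, a list of `motion_sample`s,
#'   or a numeric `C x V x T x N` array.
#' @param y Class labels (factor or character); taken from the dataset when
#'   `x` is a `motion_dataset`.
#' @param graph A `skeleton_graph`; defaults to the canonical 19-node
#'   tennis skeleton.
#' @param fuzzy Expand coordinate channels into trapezoidal memberships.
#' @param bank Optional pre-fitted [fit_fuzzy_bank()] bank (fuzzy variant).
#' @param anchors Quantile anchors for bank fitting when `bank` is `NULL`.
#' @param use_features Fuse the active-feature vector (default `TRUE`).
#' @param feats Optional precomputed feature matrix (samples in rows) as
#'   returned by [active_features_matrix()]; computed when `NULL`.
#' @param channels Feature-map widths of the three units.
#' @param temporal_kernel Odd temporal kernel extent (default 3 frames).
#' @param control A [stgcn_control()] list.
#' @param seed Integer seed; fits are bit-reproducible given the seed.
#' @return An object of class `stgcn` with [predict()], [print()],
#'   [summary()], [coef()], [plot()], [fitted()] and [residuals()] methods.
#' @export
#' @examples
#' set.seed(1)
#' ds <- generate_dataset(generator_config(n_forehand = 10, n_backhand = 10,
#'                                         n_noshot = 10, noise_sd = 0))
#' fit <- stgcn(ds, control = stgcn_control(max_epochs = 5), seed = 1)
#' predict(fit, ds)[1:5]
stgcn <- function(x, y = NULL, graph = skeleton_graph(tennis_skeleton()),
                  fuzzy = FALSE, bank = NULL,
                  anchors = c(0.10, 0.35, 0.65, 0.90),
                  use_features = TRUE, feats = NULL,
                  channels = c(32L, 64L, 64L), temporal_kernel = 3L,
                  control = stgcn_control(), seed = 1L) {
  cl <- match.call()
  d <- .coerce_training_data(x, y)
  arr <- d$arr
  y <- d$y
  if (nlevels(y) < 2L) stop("need at least two classes")
  if (any(table(y) < 1L)) stop("every class needs at least one training sample")
  N <- dim(arr)[4L]

  fmat <- NULL
  feat_center <- feat_scale <- NULL
  if (use_features) {
    if (is.null(feats)) feats <- active_features_matrix(.split_samples(arr, y))
    if (nrow(feats) != N) stop("feature matrix rows must match sample count")
    feat_center <- colMeans(feats)
    feat_scale <- apply(feats, 2L, stats::sd)
    feat_scale[!is.finite(feat_scale) | feat_scale < 1e-12] <- 1
    fmat <- t((feats - rep(feat_center, each = N)) /
                rep(feat_scale, each = N))     # F x N
  }

  if (fuzzy) {
    if (is.null(bank)) bank <- fit_fuzzy_bank(arr, anchors = anchors)
    Xin <- fuzzify(arr, bank)
  } else {
    bank <- NULL
    Xin <- arr
  }

  cfg <- .nn_cfg(c_in = dim(Xin)[1L], n_feats = if (use_features) ncol(feats) else 0L,
                 channels = channels, temporal_kernel = temporal_kernel,
                 V = dim(Xin)[2L], T = dim(Xin)[3L],
                 use_features = use_features)
  A_norm <- graph$A_norm
  if (nrow(A_norm) != cfg$V) stop("graph size does not match sample node count")

  Xi <- aperm(Xin, c(1L, 3L, 4L, 2L))      # internal (C, T, N, V) layout
  res <- .with_seed(seed, {
    params <- .nn_init(cfg)
    state <- .nn_state_init(cfg)
    .nn_train(Xi, as.integer(y), fmat, params, state, A_norm, cfg, control)
  })

  obj <- structure(list(
    params = res$params, state = res$state, cfg = cfg, graph = graph,
    fuzzy = fuzzy, bank = bank, use_features = use_features,
    feat_center = feat_center, feat_scale = feat_scale,
    levels = levels(y), control = control, seed = seed,
    history = res$history, epochs = res$epochs, n_train = N, call = cl),
    class = "stgcn")
  probs <- .stgcn_probs(obj, arr, fmat)
  obj$fitted <- probs
  obj$y <- y
  obj
}

# Forward pass in evaluation mode, chunked to bound memory.
.stgcn_probs <- function(object, arr, fmat, chunk = 512L) {
  if (object$fuzzy) arr <- fuzzify(arr, object$bank)
  N <- dim(arr)[4L]
  out <- matrix(NA_real_, object$cfg$n_classes, N)
  for (s in seq(1L, N, by = chunk)) {
    i <- s:min(N, s + chunk - 1L)
    fwd <- .nn_forward(aperm(arr[, , , i, drop = FALSE], c(1L, 3L, 4L, 2L)),
                       if (object$use_features) fmat[, i, drop = FALSE] else NULL,
                       object$params, object$state, object$graph$A_norm,
                       object$cfg, train = FALSE)
    out[, i] <- fwd$probs
  }
  rownames(out) <- object$levels
  out
}

.newdata_parts <- function(object, newdata, y = NULL, feats = NULL) {
  d <- .coerce_training_data(newdata, y, levels = object$levels,
                             require_labels = FALSE)
  fmat <- NULL
  if (object$use_features) {
    if (is.null(feats))
      feats <- active_features_matrix(.split_samples(d$arr, d$y))
    N <- dim(d$arr)[4L]
    fmat <- t((feats - rep(object$feat_center, each = N)) /
                rep(object$feat_scale, each = N))
  }
  list(arr = d$arr, y = d$y, fmat = fmat)
}

#' Predict classes or class probabilities
#'
#' @param object A fitted `stgcn` model.
#' @param newdata New samples (`motion_dataset`, sample list or array).
#' @param type `"class"` (default) or `"prob"`.
#' @param feats Optional precomputed raw feature matrix (samples in rows).
#' @param ... Unused.
#' @return A factor of class labels, or an `N x 3` probability matrix.
#'   Probabilities are nonnegative and sum to one; argmax ties resolve to
#'   the lowest class index.
#' @export
predict.stgcn <- function(object, newdata, type = c("class", "prob"),
                          feats = NULL, ...) {
  type <- match.arg(type)
  parts <- .newdata_parts(object, newdata, feats = feats)
  probs <- .stgcn_probs(object, parts$arr, parts$fmat)
  if (type == "prob") return(t(probs))
  factor(object$levels[apply(probs, 2L, which.max)], levels = object$levels)
}

#' Evaluate a classifier on labeled data
#'
#' Computes the confusion matrix (rows are true classes), per-class
#' true-positive rates (diagonal over row sum) and overall accuracy
#' (trace over total).
#'
#' @param object A fitted `stgcn` model.
#' @param newdata Labeled data to evaluate on.
#' @param y Labels when `newdata` carries none.
#' @param feats Optional precomputed raw feature matrix.
#' @param ... Unused.
#' @return An object of class `stgcn_eval`.
#' @export
evaluate <- function(object, ...) UseMethod("evaluate")

#' @rdname evaluate
#' @export
evaluate.stgcn <- function(object, newdata, y = NULL, feats = NULL, ...) {
  parts <- .newdata_parts(object, newdata, y = y, feats = feats)
  if (is.null(parts$y)) stop("evaluation requires labels")
  probs <- .stgcn_probs(object, parts$arr, parts$fmat)
  pred <- factor(object$levels[apply(probs, 2L, which.max)],
                 levels = object$levels)
  classification_metrics(parts$y, pred)
}

#' Confusion matrix, per-class true-positive rates and accuracy
#'
#' @param truth True labels (factor or character).
#' @param pred Predicted labels on the same levels.
#' @return An `stgcn_eval` list with `confusion` (rows = truth),
#'   `tp_rate` and `accuracy`.
#' @export
classification_metrics <- function(truth, pred) {
  if (!is.factor(truth)) truth <- factor(truth)
  pred <- factor(pred, levels = levels(truth))
  if (anyNA(pred)) stop("prediction outside the label set: ",
                        paste(unique(setdiff(pred, levels(truth))), collapse = ", "))
  cm <- table(truth = truth, predicted = pred)
  structure(list(confusion = unclass(cm),
                 tp_rate = diag(cm) / pmax(rowSums(cm), 1L),
                 accuracy = sum(diag(cm)) / sum(cm)),
            class = "stgcn_eval")
}

#' @export
print.stgcn_eval <- function(x, ...) {
  cat("Overall accuracy:", sprintf("%.1f%%", 100 * x$accuracy), "\n")
  cat("Per-class true-positive rates:\n")
  print(round(x$tp_rate, 3))
  cat("Confusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' @export
print.stgcn <- function(x, ...) {
  cat("ST-GCN stroke classifier",
      if (x$fuzzy) "(fuzzy input)" else "(raw input)", "\n")
  cat("  input channels:", x$cfg$c_in,
      "| feature maps:", paste(x$cfg$channels, collapse = "/"),
      "| classes:", x$cfg$n_classes, "\n")
  cat("  trained on", x$n_train, "samples for", x$epochs, "epochs",
      sprintf("(final loss %.4f)", x$history[x$epochs]), "\n")
  invisible(x)
}

#' @export
summary.stgcn <- function(object, ...) {
  npar <- sum(vapply(object$params, length, 1L))
  train_acc <- mean(object$levels[apply(object$fitted, 2L, which.max)] ==
                      as.character(object$y))
  structure(list(model = object, n_params = npar, train_accuracy = train_acc),
            class = "summary.stgcn")
}

#' @export
print.summary.stgcn <- function(x, ...) {
  print(x$model)
  cat("  parameters:", x$n_params,
      "| training accuracy:", sprintf("%.1f%%", 100 * x$train_accuracy), "\n")
  if (x$model$use_features)
    cat("  active-feature fusion: ", length(x$model$feat_center),
        " descriptors\n", sep = "")
  invisible(x)
}

#' @export
coef.stgcn <- function(object, ...) object$params

#' @export
fitted.stgcn <- function(object, ...) t(object$fitted)

#' @export
residuals.stgcn <- function(object, ...) {
  onehot <- outer(object$levels, as.character(object$y), "==") * 1
  t(onehot - object$fitted)
}

#' @export
plot.stgcn <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "b", pch = 20,
                 xlab = "epoch", ylab = "training cross-entropy",
                 main = "ST-GCN training loss", ...)
  invisible(x)
}

# ---- data coercion helpers ----

.coerce_training_data <- function(x, y, levels = NULL, require_labels = TRUE) {
  if (inherits(x, "motion_dataset")) {
    arr <- x$x
    if (is.null(y)) y <- x$y
  } else if (inherits(x, "motion_sample")) {
    arr <- array(x$x, c(dim(x$x), 1L), dimnames = c(dimnames(x$x), list(NULL)))
    if (is.null(y)) y <- x$label
  } else if (is.list(x) && length(x) && inherits(x[[1L]], "motion_sample")) {
    arr <- .as_sample_array(x)
    if (is.null(y)) y <- vapply(x, `[[`, "", "label")
  } else if (is.array(x) && length(dim(x)) == 4L) {
    arr <- x
  } else if (is.array(x) && length(dim(x)) == 3L) {
    arr <- array(x, c(dim(x), 1L), dimnames = c(dimnames(x), list(NULL)))
  } else stop("cannot interpret 'x' as motion sample data")
  if (!is.null(y)) {
    y <- if (is.null(levels)) factor(y) else factor(y, levels = levels)
    if (length(y) != dim(arr)[4L]) stop("labels do not match sample count")
  } else if (require_labels) stop("labels 'y' are required")
  list(arr = arr, y = y)
}

# Rebuild a list of motion samples from an array (for feature extraction).
.split_samples <- function(arr, y = NULL) {
  N <- dim(arr)[4L]
  lapply(seq_len(N), function(n) {
    structure(list(x = arr[, , , n],
                   label = if (is.null(y)) NA_character_ else as.character(y[n]),
                   nodes = dimnames(arr)[[2L]],
                   channels = dimnames(arr)[[1L]],
                   phase_ids = NULL),
              class = "motion_sample")
  })
}

.dataset_samples <- function(ds) .split_samples(ds$x, ds$y)

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
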