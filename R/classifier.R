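#' Texture features of a detection-window patch
#'
#' Summary statistics separating colony texture from background/fibroblast
#' texture: intensity level and spread, gradient energy, short- and
#' medium-range spatial autocorrelation along both axes, and coarse-scale
#' heterogeneity (standard deviation of 12x12 block means). These are the
#' inputs of the reference patch classifier.
#'
#' @param patch numeric matrix, exactly `window` x `window`.
#' @param window expected side length (default 96).
#' @return named numeric vector of 10 features.
#' @export
patch_features <- function(patch, window = 96L) {
  if (!is.matrix(patch) || nrow(patch) != window || ncol(patch) != window)
    stop("patch must be a ", window, "x", window, " matrix")
  p <- patch
  nr <- nrow(p); nc <- ncol(p)
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }
  lag_h <- function(k) safe_cor(as.vector(p[, seq_len(nc - k)]),
                                as.vector(p[, k + seq_len(nc - k)]))
  lag_v <- function(k) safe_cor(as.vector(p[seq_len(nr - k), ]),
                                as.vector(p[k + seq_len(nr - k), ]))
  block <- 12L
  bm <- window_sums(p, block, block)[seq(1, nr - block + 1, by = block),
                                     seq(1, nc - block + 1, by = block)] / block^2
  c(mean      = mean(p),
    sd        = stats::sd(as.vector(p)),
    mad       = stats::mad(as.vector(p)),
    grad_h    = mean(abs(p[, -1] - p[, -nc])),
    grad_v    = mean(abs(p[-1, ] - p[-nr, ])),
    ac1_h     = lag_h(1L),
    ac1_v     = lag_v(1L),
    ac4_h     = lag_h(4L),
    ac4_v     = lag_v(4L),
    coarse_sd = stats::sd(as.vector(bm)))
}

feature_matrix <- function(patches, window = 96L) {
  t(vapply(patches, patch_features, numeric(10), window = window))
}

as_patch_list <- function(patches) {
  if (is.matrix(patches)) return(list(patches))
  if (is.data.frame(patches)) return(patches$patch)
  if (is.list(patches)) return(patches)
  stop("patches must be a matrix, a list of matrices, or a patch tibble")
}

nnet_forward <- function(wts, n_in, size, x) {
  sig <- function(z) 1 / (1 + exp(-z))
  W1 <- matrix(wts[seq_len((n_in + 1) * size)], n_in + 1, size)
  w2 <- wts[(n_in + 1) * size + seq_len(size + 1)]
  h <- sig(cbind(1, x) %*% W1)
  as.vector(sig(cbind(1, h) %*% w2))
}

#' Train the patch texture classifier
#'
#' Reference implementation of the pluggable patch-to-probability contract: a
#' single-hidden-layer feed-forward network (logistic output, weight decay)
#' over the [patch_features()] of each 96x96 window, fitted on standardized
#' features. Input labels follow the dataset convention 0 = iPSC texture,
#' 1 = non-iPSC; predictions are always reported as P(iPSC) to avoid double
#' negation. A stratified holdout split is scored and stored in the model
#' metadata. Training is deterministic given `seed`.
#'
#' @param patches tibble with list-column `patch` and column `label`
#'   (0 = iPSC, 1 = non-iPSC), as from [generate_patch_dataset()].
#' @param hidden hidden units (default 8).
#' @param decay L2 weight decay (default 1e-3).
#' @param maxit optimizer iterations (default 300).
#' @param holdout fraction held out for the accuracy estimate (default 0.2).
#' @param threshold decision threshold on P(iPSC) (default 0.5).
#' @param seed RNG seed for the split and the initial weights.
#' @return object of class `patch_classifier`.
#' @export
train_patch_classifier <- function(patches, hidden = 8L, decay = 1e-3,
                                   maxit = 300L, holdout = 0.2,
                                   threshold = 0.5, seed = 1L) {
  if (!is.data.frame(patches) || nrow(patches) == 0)
    stop("empty patch set")
  lab <- patches$label
  if (length(unique(lab)) < 2)
    stop("training requires both classes (labels 0 and 1) present")
  x <- feature_matrix(patches$patch)
  y <- as.numeric(lab == 0)  # P(iPSC) target
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")

  set.seed(seed)
  idx0 <- which(y == 1); idx1 <- which(y == 0)
  hold <- c(sample(idx0, max(1, round(holdout * length(idx0)))),
            sample(idx1, max(1, round(holdout * length(idx1)))))
  tr <- setdiff(seq_along(y), hold)

  fit <- nnet::nnet(xs[tr, , drop = FALSE], y[tr], size = hidden,
                    entropy = TRUE, decay = decay, maxit = maxit,
                    trace = FALSE)
  p_hold <- nnet_forward(fit$wts, ncol(xs), hidden, xs[hold, , drop = FALSE])
  acc <- mean((p_hold >= threshold) == (y[hold] == 1))

  structure(list(
    wts = fit$wts, n_in = ncol(xs), size = as.integer(hidden),
    center = center, scale = scale, threshold = threshold,
    patch_size = 96L,
    train_x = x, train_y = y,
    meta = list(seed = as.integer(seed), decay = decay,
                maxit = as.integer(maxit),
                n_class0 = sum(lab == 0), n_class1 = sum(lab == 1),
                holdout_accuracy = acc, n_holdout = length(hold),
                rounds = 0L)),
    class = "patch_classifier")
}

predict_features <- function(model, x) {
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  nnet_forward(model$wts, model$n_in, model$size, xs)
}

#' Predict P(iPSC) for patches
#'
#' @param object a `patch_classifier`.
#' @param patches a single patch matrix, a list of patch matrices, or a patch
#'   tibble with a `patch` list-column.
#' @param ... unused.
#' @return numeric vector of probabilities that each patch shows iPSC texture.
#' @export
predict.patch_classifier <- function(object, patches, ...) {
  pl <- as_patch_list(patches)
  x <- feature_matrix(pl, window = object$patch_size)
  predict_features(object, x)
}

#' Corrective fine-tuning of a trained classifier
#'
#' Implements the iterative correction loop: misclassified windows, relabelled
#' by the operator, are appended to the training set and the network is
#' refitted (warm-started from the current weights). The returned model never
#' does worse than the input model on the correction set: if refitting did not
#' help there, the input model is kept.
#'
#' @param model a `patch_classifier`.
#' @param corrections non-empty patch tibble with corrected `label`s.
#' @param maxit refit iterations (default 200).
#' @return updated `patch_classifier`.
#' @export
fine_tune <- function(model, corrections, maxit = 200L) {
  stopifnot(inherits(model, "patch_classifier"))
  if (!is.data.frame(corrections) || nrow(corrections) == 0)
    stop("corrections must be a non-empty patch set")
  cx <- feature_matrix(corrections$patch, window = model$patch_size)
  cy <- as.numeric(corrections$label == 0)

  err_rate <- function(m) {
    p <- predict_features(m, cx)
    mean((p >= m$threshold) != (cy == 1))
  }
  old_err <- err_rate(model)

  x <- rbind(model$train_x, cx)
  y <- c(model$train_y, cy)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd); scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  set.seed(model$meta$seed + model$meta$rounds + 1L)
  fit <- nnet::nnet(xs, y, size = model$size, entropy = TRUE,
                    decay = model$meta$decay, maxit = maxit,
                    Wts = model$wts, trace = FALSE)
  new_model <- model
  new_model$wts <- fit$wts
  new_model$center <- center
  new_model$scale <- scale
  new_model$train_x <- x
  new_model$train_y <- y
  new_model$meta$rounds <- model$meta$rounds + 1L
  new_err <- err_rate(new_model)
  if (new_err <= old_err) new_model else {
    model$meta$rounds <- model$meta$rounds + 1L
    model
  }
}

#' Serialize / restore a patch classifier
#'
#' The model file is a single JSON artifact with a metadata header (format
#' tag, version, patch size, threshold, seed) followed by the weights,
#' feature scaling and retained training features. Doubles are written at
#' full precision, so a restored model reproduces predictions bit-identically.
#'
#' @param model a `patch_classifier`.
#' @param path file path.
#' @return `write_classifier` returns `path` invisibly; `read_classifier`
#'   returns the restored `patch_classifier`.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "patch_classifier"))
  obj <- list(
    format = "colonyscope-texture-model", version = 1L,
    patch_size = model$patch_size, threshold = model$threshold,
    n_in = model$n_in, size = model$size,
    wts = model$wts, center = as.list(model$center),
    scale = as.list(model$scale),
    train_x = model$train_x, train_y = model$train_y,
    feature_names = colnames(model$train_x),
    meta = model$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "colonyscope-texture-model"))
    stop("not a colonyscope texture model file")
  tx <- as.matrix(obj$train_x)
  colnames(tx) <- obj$feature_names
  structure(list(
    wts = as.numeric(obj$wts), n_in = as.integer(obj$n_in),
    size = as.integer(obj$size),
    center = unlist(obj$center), scale = unlist(obj$scale),
    threshold = obj$threshold, patch_size = as.integer(obj$patch_size),
    train_x = tx, train_y = as.numeric(obj$train_y),
    meta = obj$meta), class = "patch_classifier")
}

#' @export
print.patch_classifier <- function(x, ...) {
  cat("<patch_classifier> ", x$n_in, " features -> ", x$size,
      " hidden units; threshold ", x$threshold, "\n", sep = "")
  cat("  trained on ", x$meta$n_class0, "+", x$meta$n_class1,
      " patches; holdout accuracy ", round(x$meta$holdout_accuracy, 3),
      "; fine-tune rounds ", x$meta$rounds, "\n", sep = "")
  invisible(x)
}
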