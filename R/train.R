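# Optimization: SGD with momentum, per-batch cosine annealing, weighted
# oversampling, patient-grouped cross-validation folds.

#' Training configuration
#'
#' Defaults follow the published training protocol: batch size 16, 30
#' epochs, SGD with momentum 0.9, initial learning rate 0.005 decayed with
#' per-batch cosine annealing, label smoothing 0.1.
#'
#' @param batch_size,epochs,lr0,momentum,epsilon optimizer settings.
#' @param seed integer seed controlling sampling, augmentation and weight
#'   initialization.
#' @param augment an [augment_config()], or `NULL` to disable augmentation.
#' @param target_size network input side (pixels).
#' @return List of class `octex_train_config`.
#' @export
train_config <- function(batch_size = 16L, epochs = 30L, lr0 = 0.005,
                         momentum = 0.9, epsilon = 0.1, seed = 1L,
                         augment = augment_config(), target_size = 224L) {
  stopifnot(batch_size >= 1, epochs >= 1, lr0 >= 0, momentum >= 0,
            momentum < 1)
  out <- list(batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), lr0 = lr0, momentum = momentum,
              epsilon = epsilon, seed = as.integer(seed), augment = augment,
              target_size = as.integer(target_size))
  class(out) <- "octex_train_config"
  out
}

#' Cosine-annealed learning rate
#'
#' `lr(step) = lr0/2 * (1 + cos(pi * step / total_steps))`: starts at
#' `lr0`, decays to 0, non-increasing.
#'
#' @param step current step, `0 <= step <= total_steps`.
#' @param total_steps total number of batches over all epochs (> 0).
#' @param lr0 initial learning rate.
#' @return Learning rate.
#' @export
cosine_lr <- function(step, total_steps, lr0 = 0.005) {
  if (any(total_steps <= 0)) stop("total_steps must be positive")
  stopifnot(all(step >= 0), all(step <= total_steps))
  lr0 / 2 * (1 + cos(pi * step / total_steps))
}

#' Patient-grouped cross-validation folds
#'
#' Partitions patients (not images) into k folds so no patient's data can
#' sit in both the training and the test side of any split. Fold sizes
#' differ by at most one patient; deterministic per seed.
#'
#' @param patient_ids character vector of unique patient ids.
#' @param k number of folds (<= number of patients).
#' @param seed integer seed.
#' @return Named integer vector: fold index (1..k) per patient.
#' @export
split_folds <- function(patient_ids, k = 10L, seed = 1L) {
  patient_ids <- unique(as.character(patient_ids))
  if (k > length(patient_ids)) stop("more folds than patients")
  with_seed(seed, {
    ord <- sample(patient_ids)
    folds <- rep(seq_len(k), length.out = length(ord))
    stats::setNames(folds, ord)[patient_ids]
  })
}

# Resize every patch once and stack into an (S, S, N) array.
prepare_patch_array <- function(dataset, target_size) {
  n <- length(dataset$patches)
  x <- array(0, c(target_size, target_size, n))
  for (i in seq_len(n)) {
    x[, , i] <- resize_bilinear(dataset$patches[[i]], target_size)
  }
  x
}

#' Train the classifier on a patch dataset
#'
#' Stochastic gradient descent with momentum and per-batch cosine
#' annealing. Batches are drawn with replacement under the
#' class-balancing oversampling weights; one epoch makes
#' `ceiling(n / batch_size)` draws of `batch_size`. Augmentation is applied
#' on the intensity scale before z-score normalization with the training
#' split's global statistics (stored in the returned model for use at
#' prediction time). Fully deterministic for a fixed config seed.
#'
#' @param dataset an `octex_patch_dataset` (see [generate_patch_dataset()]),
#'   with at least two classes represented.
#' @param model_cfg an [model_config()].
#' @param train_cfg an [train_config()].
#' @param verbose print per-epoch progress.
#' @return List of class `octex_fit`: `model` (with normalization stats
#'   attached) and `history` (data.frame with one row per epoch: mean total
#'   / main / auxiliary loss, training accuracy, last learning rate), plus
#'   `lr_log` (learning rate at every step).
#' @export
train_model <- function(dataset, model_cfg = model_config(),
                        train_cfg = train_config(), verbose = FALSE) {
  labels <- factor(dataset$meta$class, levels = model_cfg$classes)
  if (length(labels) == 0) stop("empty dataset")
  labels <- droplevels(labels)
  if (nlevels(labels) < 2) stop("training needs at least two classes")
  yi <- match(as.character(labels), model_cfg$classes)
  n <- length(yi)
  S <- train_cfg$target_size
  x <- prepare_patch_array(dataset, S)
  nstats <- list(mean = mean(x), sd = stats::sd(as.vector(x)))
  w <- oversampling_weights(as.character(labels))

  model <- build_model(model_cfg, seed = train_cfg$seed)
  model$norm_stats <- nstats
  model$input_size <- S
  vel <- NULL
  steps_per_epoch <- ceiling(n / train_cfg$batch_size)
  total_steps <- steps_per_epoch * train_cfg$epochs
  history <- vector("list", train_cfg$epochs)
  lr_log <- numeric(total_steps)
  step <- 0L
  with_seed(train_cfg$seed, {
    for (ep in seq_len(train_cfg$epochs)) {
      ep_loss <- ep_main <- ep_aux <- ep_acc <- 0
      for (it in seq_len(steps_per_epoch)) {
        lr <- cosine_lr(step, total_steps, train_cfg$lr0)
        lr_log[step + 1L] <- lr
        idx <- sample.int(n, train_cfg$batch_size, replace = TRUE, prob = w)
        xb <- array(0, c(S, S, length(idx), 1L))
        for (j in seq_along(idx)) {
          pj <- x[, , idx[j]]
          if (!is.null(train_cfg$augment)) {
            pj <- augment_patch(pj, train_cfg$augment)
          }
          xb[, , j, 1L] <- (pj - nstats$mean) / nstats$sd
        }
        out <- model_forward(model, xb, training = TRUE, keep_cache = TRUE)
        model <- out$model
        lb <- loss_batch(out$scale_logits, yi[idx], model_cfg)
        grads <- model_backward(model, out, lb$dlogits)
        upd <- sgd_step(model, grads, vel, lr, train_cfg$momentum)
        model <- upd$model
        vel <- upd$vel
        ep_loss <- ep_loss + lb$total
        ep_main <- ep_main + lb$main
        ep_aux <- ep_aux + sum(lb$aux)
        ep_acc <- ep_acc + lb$accuracy
        step <- step + 1L
      }
      history[[ep]] <- data.frame(
        epoch = ep, loss = ep_loss / steps_per_epoch,
        main_loss = ep_main / steps_per_epoch,
        aux_loss = ep_aux / steps_per_epoch,
        train_accuracy = ep_acc / steps_per_epoch, lr = lr)
      if (verbose) {
        message(sprintf("epoch %2d  loss %.4f  acc %.3f  lr %.5f", ep,
                        history[[ep]]$loss, history[[ep]]$train_accuracy, lr))
      }
    }
  })
  out <- list(model = model, history = do.call(rbind, history),
              lr_log = lr_log, steps_per_epoch = steps_per_epoch)
  class(out) <- "octex_fit"
  out
}

#' Predict class probabilities for patches
#'
#' @param model a trained `octex_model` (normalization statistics attached
#'   by [train_model()]).
#' @param patches list of patch matrices on the 0..255 scale, or an
#'   `octex_patch_dataset`.
#' @param batch_size forward batch size.
#' @return Matrix (n x C) of fused class probabilities, columns named by
#'   the class vocabulary.
#' @export
predict_patches <- function(model, patches, batch_size = 32L) {
  if (inherits(patches, "octex_patch_dataset")) patches <- patches$patches
  stopifnot(inherits(model, "octex_model"), length(patches) > 0)
  S <- if (is.null(model$input_size)) 224L else model$input_size
  ns <- model$norm_stats
  if (is.null(ns)) ns <- list(mean = 127.5, sd = 73.9)
  n <- length(patches)
  probs <- matrix(0, n, model$config$n_classes,
                  dimnames = list(NULL, model$config$classes))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- array(0, c(S, S, length(idx), 1L))
    for (j in seq_along(idx)) {
      xb[, , j, 1L] <- (resize_bilinear(patches[[idx[j]]], S) - ns$mean) /
        ns$sd
    }
    out <- model_forward(model, xb, training = FALSE)
    probs[idx, ] <- out$prob
  }
  probs
}

#' Predict a volume's patch grid and verdict
#'
#' Runs the classifier over every sliding-window patch of a volume,
#' assembles the (frame, window) grid of class probabilities and binary
#' risk scores `P(HSIL) + P(CC)`, and applies the cross-shaped threshold
#' voting rule.
#'
#' @param model trained `octex_model`.
#' @param volume an [oct_volume()].
#' @param window_size,stride sliding-window geometry.
#' @param tau,arm_length voting parameters (see [vote_volume()]).
#' @return List of class `octex_patch_grid`: `prob` (frames x windows x C
#'   array), `risk` (frames x windows matrix), `verdict` (an
#'   `octex_verdict`).
#' @export
predict_volume <- function(model, volume, window_size, stride, tau = 0.8,
                           arm_length = 1L) {
  grid <- extract_patches(volume, window_size, stride)
  nf <- length(grid$patches)
  nw <- length(grid$offsets)
  flat <- unlist(grid$patches, recursive = FALSE)
  probs <- predict_patches(model, flat)
  parr <- array(0, c(nf, nw, ncol(probs)),
                dimnames = list(NULL, NULL, colnames(probs)))
  k <- 1L
  for (f in seq_len(nf)) {
    for (w in seq_len(nw)) {
      parr[f, w, ] <- probs[k, ]
      k <- k + 1L
    }
  }
  risk <- parr[, , "HSIL", drop = FALSE][, , 1] +
    parr[, , "CC", drop = FALSE][, , 1]
  risk <- matrix(risk, nf, nw)
  out <- list(prob = parr, risk = risk,
              verdict = vote_volume(risk, tau, arm_length))
  class(out) <- "octex_patch_grid"
  out
}
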