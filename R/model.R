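# The full classifier: residual backbone -> per-scale feature-encoding
# modules (1x1 conv block + texton encoding) -> auxiliary classifiers
# (L2 normalization + fully connected) -> element-wise logit fusion.
# Deep supervision attaches a cross-entropy loss to every scale's
# auxiliary prediction in addition to the main loss on the fused one.

#' Default class vocabulary
#'
#' The five clinical categories: mild inflammation, cyst, ectropion (the
#' low-risk classes), HSIL and cervical cancer (the high-risk classes).
#' @export
oct_classes <- function() c("MI", "CY", "EP", "HSIL", "CC")

#' Classes mapped to the positive (high-risk) binary label
#' @export
positive_classes <- function() c("HSIL", "CC")

#' Model configuration
#'
#' @param profile backbone profile, `"test"` or `"reference"`
#'   (see [backbone_profile()]).
#' @param classes class vocabulary; the fused prediction and every
#'   auxiliary prediction have this length.
#' @param K,D number of textons and descriptor dimension. Defaults follow
#'   the reference setting (K = 32, D = 128); the test profile shrinks them
#'   to keep CPU training fast while preserving every structural contract.
#' @param use_fpn use all four pyramid scales (`FALSE`: last scale only).
#' @param use_encoding use the texton encoding block (`FALSE`: global
#'   average pooling over the conv-block output instead).
#' @param deep_supervision attach an auxiliary loss to every active scale.
#' @param epsilon label-smoothing parameter.
#' @return List of class `octex_model_config`.
#' @export
model_config <- function(profile = "test", classes = oct_classes(),
                         K = NULL, D = NULL, use_fpn = TRUE,
                         use_encoding = TRUE, deep_supervision = TRUE,
                         epsilon = 0.1) {
  stopifnot(epsilon >= 0, epsilon < 1, length(classes) >= 2)
  if (is.null(K)) K <- if (profile == "reference") 32L else 8L
  if (is.null(D)) D <- if (profile == "reference") 128L else 16L
  cfg <- list(profile = profile, classes = classes,
              n_classes = length(classes), K = as.integer(K),
              D = as.integer(D), use_fpn = isTRUE(use_fpn),
              use_encoding = isTRUE(use_encoding),
              deep_supervision = isTRUE(deep_supervision),
              epsilon = epsilon)
  class(cfg) <- "octex_model_config"
  cfg
}

active_scales <- function(config) if (config$use_fpn) 1:4 else 4L

#' Build an untrained model
#'
#' @param config an [model_config()] object.
#' @param seed integer seed for weight initialization.
#' @return List of class `octex_model`: backbone, per-scale heads, config.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  with_seed(seed, {
    backbone <- backbone_init(config$profile)
    heads <- vector("list", 4L)
    for (s in active_scales(config)) {
      c_in <- backbone$profile$channels[s]
      head <- list(
        conv = conv_init(1L, 1L, c_in, config$D),
        bn = bn_init(config$D)
      )
      if (config$use_encoding) {
        head$dict <- texton_dictionary(config$K, config$D)[c("C", "s")]
        head$fc <- fc_init(config$K * config$D, config$n_classes)
      } else {
        head$fc <- fc_init(config$D, config$n_classes)
      }
      heads[[s]] <- head
    }
    model <- list(config = config, backbone = backbone, heads = heads,
                  norm_stats = NULL)
    class(model) <- "octex_model"
    model
  })
}

# 1x1 conv + batch norm + rectifier: projects a stage's feature map to the
# common D-channel descriptor space.
conv_block_fwd <- function(x, head, training) {
  c1 <- conv_fwd(x, head$conv)
  b1 <- bn_fwd(c1$out, head$bn, training)
  r1 <- relu_fwd(b1$out)
  head$bn <- b1$layer
  list(out = r1$out, cache = list(c1 = c1, b1 = b1, r1 = r1), head = head)
}

l2_normalize_rows <- function(v, eps = 1e-12) {
  n <- sqrt(rowSums(v * v))
  keep <- n > eps
  out <- v / ifelse(keep, n, 1)
  out[!keep, ] <- 0
  list(out = out, n = n, keep = keep, v = out)
}

#' Model forward pass
#'
#' @param model an `octex_model`.
#' @param x image batch, array `dim c(H, W, B, 1)` of normalized
#'   intensities, or `c(H, W)`/`c(H, W, B)` which are promoted.
#' @param training logical, batch-norm mode.
#' @param keep_cache keep activations for a backward pass.
#' @return List: `prob` (B x C fused class probabilities), `logits` (fused),
#'   `scale_logits` (per active scale), `pyramid` sizes, updated `model`,
#'   and optionally `cache`.
#' @export
model_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x)[1:2], dim(x)[3], 1L)
  cfg <- model$config
  bb <- backbone_forward(model$backbone, x, training, keep_cache)
  model$backbone <- bb$backbone
  B <- dim(x)[3]
  scale_logits <- vector("list", 4L)
  hcaches <- vector("list", 4L)
  for (s in active_scales(cfg)) {
    head <- model$heads[[s]]
    cb <- conv_block_fwd(bb$pyramid[[s]], head, training)
    model$heads[[s]] <- cb$head
    if (cfg$use_encoding) {
      enc <- encode_batch_fwd(cb$out, head$dict)
      feats <- enc$feature
    } else {
      d <- dim(cb$out)
      fm <- cb$out
      dim(fm) <- c(d[1] * d[2], d[3] * d[4])
      feats <- matrix(colMeans(fm), d[3], d[4])
      enc <- list(dims = d)
    }
    l2 <- l2_normalize_rows(feats)
    fc <- fc_fwd(l2$out, head$fc)
    scale_logits[[s]] <- fc$out
    hcaches[[s]] <- list(cb = cb$cache, enc = enc, l2 = l2, fc = fc)
  }
  fused <- Reduce(`+`, scale_logits[active_scales(cfg)])
  out <- list(prob = softmax_rows(fused), logits = fused,
              scale_logits = scale_logits, model = model,
              pyramid_sizes = vapply(bb$pyramid, function(p) dim(p)[1],
                                     numeric(1)))
  if (keep_cache) out$cache <- list(bb = bb$cache, heads = hcaches,
                                    pyramid = bb$pyramid)
  out
}

#' Fuse per-scale logits into the final prediction
#'
#' Sums the auxiliary classifiers' logit vectors element-wise and applies a
#' softmax; the predicted label is the arg-max, ties broken toward the
#' lowest class index.
#'
#' @param scale_logits list of equal-length numeric logit vectors.
#' @return List with `prob` (probability vector summing to 1) and `label`
#'   (1-based index of the predicted class).
#' @export
fuse_logits <- function(scale_logits) {
  stopifnot(length(scale_logits) >= 1)
  len <- vapply(scale_logits, length, integer(1))
  if (length(unique(len)) != 1) stop("logit vectors differ in length")
  z <- Reduce(`+`, lapply(scale_logits, as.numeric))
  p <- as.vector(softmax_rows(matrix(z, 1)))
  list(prob = p, label = which.max(p)) # which.max takes the first maximum
}

#' Label-smoothed target distribution
#'
#' Mixes the one-hot label with the uniform distribution:
#' `y_i = (1 - epsilon) * 1[i == true] + epsilon / C`.
#'
#' @param true_class 1-based class index.
#' @param epsilon smoothing parameter in \[0, 1).
#' @param n_classes number of categories C.
#' @return Probability vector of length `n_classes` summing to 1.
#' @export
smooth_labels <- function(true_class, epsilon = 0.1, n_classes) {
  stopifnot(epsilon >= 0, epsilon < 1, true_class >= 1,
            true_class <= n_classes)
  y <- rep(epsilon / n_classes, n_classes)
  y[true_class] <- y[true_class] + 1 - epsilon
  y
}

cross_entropy <- function(pred, target, floor = 1e-12) {
  -sum(target * log(pmax(pred, floor)))
}

#' Deeply supervised loss breakdown
#'
#' Computes the training objective for one example: a cross-entropy
#' auxiliary loss per scale prediction against the label-smoothed target,
#' the main loss on the fused prediction, and their unweighted sum.
#'
#' @param scale_probs list of per-scale class-probability vectors.
#' @param fused_prob fused class-probability vector.
#' @param true_class 1-based class index.
#' @param epsilon label-smoothing parameter.
#' @return List of class `octex_loss`: `aux` (per-scale losses), `main`,
#'   `total` (= `sum(aux) + main` exactly), and `target`.
#' @export
loss_breakdown <- function(scale_probs, fused_prob, true_class,
                           epsilon = 0.1) {
  n_classes <- length(fused_prob)
  y <- smooth_labels(true_class, epsilon, n_classes)
  aux <- vapply(scale_probs, cross_entropy, numeric(1), target = y)
  out <- list(aux = aux, main = cross_entropy(fused_prob, y),
              target = y)
  out$total <- sum(out$aux) + out$main
  class(out) <- "octex_loss"
  out
}

# Batched loss + gradient w.r.t. every scale's logits.
# labels: integer vector (1..C) of length B. Returns mean losses and the
# list of per-scale logit gradients (already divided by B).
loss_batch <- function(scale_logits, labels, config) {
  scales <- active_scales(config)
  B <- length(labels)
  C <- config$n_classes
  Y <- t(vapply(labels, smooth_labels, numeric(C),
                epsilon = config$epsilon, n_classes = C))
  fused <- Reduce(`+`, scale_logits[scales])
  pm <- softmax_rows(fused)
  main <- mean(-rowSums(Y * log(pmax(pm, 1e-12))))
  dfused <- (pm - Y) / B
  dlogits <- vector("list", 4L)
  aux <- numeric(0)
  for (s in scales) dlogits[[s]] <- dfused
  if (config$deep_supervision) {
    for (s in scales) {
      pa <- softmax_rows(scale_logits[[s]])
      aux <- c(aux, mean(-rowSums(Y * log(pmax(pa, 1e-12)))))
      dlogits[[s]] <- dlogits[[s]] + (pa - Y) / B
    }
  }
  acc <- mean(max.col(pm, ties.method = "first") == labels)
  list(total = sum(aux) + main, main = main, aux = aux,
       dlogits = dlogits, accuracy = acc)
}

# Full backward pass. out: result of model_forward(keep_cache = TRUE);
# dlogits: per-scale logit gradients. Returns grads mirroring the model
# structure and optionally the gradient at each stage output.
model_backward <- function(model, out, dlogits, keep_stage_grads = FALSE) {
  cfg <- model$config
  cache <- out$cache
  dPyramid <- vector("list", 4L)
  hgrads <- vector("list", 4L)
  for (s in active_scales(cfg)) {
    head <- model$heads[[s]]
    hc <- cache$heads[[s]]
    fcb <- fc_bwd(dlogits[[s]], hc$fc, head$fc)
    # L2 normalization backward
    v <- hc$l2$out
    dv <- fcb$dv
    sdot <- rowSums(v * dv)
    dfeat <- (dv - v * sdot) / ifelse(hc$l2$keep, hc$l2$n, 1)
    dfeat[!hc$l2$keep, ] <- 0
    if (cfg$use_encoding) {
      eb <- encode_batch_bwd(dfeat, hc$enc, head$dict)
      dZ <- eb$dZ
      dict_g <- list(dC = eb$dC, ds = eb$ds)
    } else {
      d <- hc$enc$dims
      dZ <- array(0, d)
      for (b in seq_len(d[3])) {
        dZ[, , b, ] <- rep(dfeat[b, ] / (d[1] * d[2]), each = d[1] * d[2])
      }
      dict_g <- NULL
    }
    dr <- relu_bwd(dZ, hc$cb$r1)
    db <- bn_bwd(dr, hc$cb$b1)
    dc <- conv_bwd(db$dx, hc$cb$c1, head$conv)
    g <- list(conv = list(dW = dc$dW), bn = db[c("dgamma", "dbeta")],
              fc = fcb[c("dW", "db")])
    if (!is.null(dict_g)) g$dict <- dict_g
    hgrads[[s]] <- g
    dPyramid[[s]] <- dc$dx
  }
  bbk <- backbone_backward(model$backbone, cache$bb, dPyramid,
                           keep_stage_grads)
  list(backbone = bbk$grads, heads = hgrads,
       stage_grads = bbk$stage_grads)
}

# --- SGD with momentum over the nested parameter structure -----------------

# Gradient leaves are named "dW", "dgamma", ...; the matching parameter in
# the model subtree is the name without the leading "d".
sgd_apply <- function(obj, grad, vel, lr, momentum) {
  if (is.null(vel)) vel <- vector("list", length(grad))
  length(vel) <- length(grad)
  nms <- names(grad)
  for (i in seq_along(grad)) {
    nm <- if (is.null(nms)) "" else nms[i]
    gv <- grad[[i]]
    if (is.null(gv)) next
    if (is.numeric(gv) && nzchar(nm) && startsWith(nm, "d")) {
      pname <- substring(nm, 2)
      v0 <- vel[[i]]
      if (is.null(v0)) v0 <- gv * 0
      v0 <- momentum * v0 - lr * gv
      vel[[i]] <- v0
      obj[[pname]] <- obj[[pname]] + v0
    } else if (is.list(gv)) {
      key <- if (nzchar(nm)) nm else i
      r <- sgd_apply(obj[[key]], gv, vel[[i]], lr, momentum)
      obj[[key]] <- r$obj
      vel[[i]] <- r$vel
    }
  }
  list(obj = obj, vel = vel)
}

sgd_step <- function(model, grads, vel, lr, momentum = 0.9) {
  r <- sgd_apply(model[c("backbone", "heads")],
                 grads[c("backbone", "heads")], vel, lr, momentum)
  model$backbone <- r$obj$backbone
  model$heads <- r$obj$heads
  list(model = model, vel = r$vel)
}

#' Save / load a model checkpoint
#'
#' A checkpoint holds the weights, the model configuration, the class
#' vocabulary and the normalization statistics, so prediction is fully
#' reproducible from the file alone.
#'
#' @param model an `octex_model`.
#' @param path file path (RDS).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "octex_model")) stop("not an octex model checkpoint")
  model
}
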