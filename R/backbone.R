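# Four-stage residual backbone. A 224 x 224 input yields the four-scale
# feature pyramid 56x56 / 28x28 / 14x14 / 7x7 (stem downsamples by 4, each
# later stage by 2). Two profiles share this contract:
#   reference — bottleneck blocks stacked (3, 4, 23, 3), stage widths
#               256/512/1024/2048 (a 101-layer residual network);
#   test      — basic blocks, one per stage, widths 8/16/32/32, sized for
#               CPU-scale training on synthetic cohorts.

#' Backbone profile description
#'
#' @param profile `"reference"` (deep bottleneck network) or `"test"`
#'   (shallow residual network with the same four-scale contract).
#' @return List with block type, per-stage block counts and channel widths.
#' @export
backbone_profile <- function(profile = c("test", "reference")) {
  profile <- match.arg(profile)
  if (profile == "reference") {
    list(name = "reference", block = "bottleneck", blocks = c(3L, 4L, 23L, 3L),
         channels = c(256L, 512L, 1024L, 2048L),
         width = c(64L, 128L, 256L, 512L), stem_channels = 64L,
         stem_pool = TRUE)
  } else {
    list(name = "test", block = "basic", blocks = c(1L, 1L, 1L, 1L),
         channels = c(8L, 16L, 32L, 32L),
         width = c(8L, 16L, 32L, 32L), stem_channels = 8L,
         stem_pool = FALSE)
  }
}

block_init <- function(type, c_in, c_out, width, stride) {
  blk <- list(type = type, stride = stride)
  if (type == "basic") {
    blk$conv1 <- conv_init(3L, 3L, c_in, c_out)
    blk$conv1$stride <- as.integer(stride); blk$conv1$pad <- 1L
    blk$bn1 <- bn_init(c_out)
    blk$conv2 <- conv_init(3L, 3L, c_out, c_out)
    blk$conv2$pad <- 1L
    blk$bn2 <- bn_init(c_out)
  } else {
    blk$conv1 <- conv_init(1L, 1L, c_in, width)
    blk$bn1 <- bn_init(width)
    blk$conv2 <- conv_init(3L, 3L, width, width)
    blk$conv2$stride <- as.integer(stride); blk$conv2$pad <- 1L
    blk$bn2 <- bn_init(width)
    blk$conv3 <- conv_init(1L, 1L, width, c_out)
    blk$bn3 <- bn_init(c_out)
  }
  if (stride != 1L || c_in != c_out) {
    blk$sc_conv <- conv_init(1L, 1L, c_in, c_out)
    blk$sc_conv$stride <- as.integer(stride)
    blk$sc_bn <- bn_init(c_out)
  }
  blk
}

block_fwd <- function(x, blk, training) {
  cc <- list()
  cc$c1 <- conv_fwd(x, blk$conv1)
  cc$b1 <- bn_fwd(cc$c1$out, blk$bn1, training)
  cc$r1 <- relu_fwd(cc$b1$out)
  cc$c2 <- conv_fwd(cc$r1$out, blk$conv2)
  cc$b2 <- bn_fwd(cc$c2$out, blk$bn2, training)
  if (blk$type == "bottleneck") {
    cc$r2 <- relu_fwd(cc$b2$out)
    cc$c3 <- conv_fwd(cc$r2$out, blk$conv3)
    cc$b3 <- bn_fwd(cc$c3$out, blk$bn3, training)
    main <- cc$b3$out
  } else {
    main <- cc$b2$out
  }
  if (!is.null(blk$sc_conv)) {
    cc$sc <- conv_fwd(x, blk$sc_conv)
    cc$scb <- bn_fwd(cc$sc$out, blk$sc_bn, training)
    short <- cc$scb$out
  } else {
    short <- x
  }
  cc$rout <- relu_fwd(main + short)
  # batch-norm running statistics updated in-place on the returned block
  blk$bn1 <- cc$b1$layer; blk$bn2 <- cc$b2$layer
  if (!is.null(cc$b3)) blk$bn3 <- cc$b3$layer
  if (!is.null(cc$scb)) blk$sc_bn <- cc$scb$layer
  list(out = cc$rout$out, cache = cc, blk = blk)
}

block_bwd <- function(dy, cache, blk) {
  g <- list() # parameter gradients
  dsum <- relu_bwd(dy, cache$rout)
  if (blk$type == "bottleneck") {
    b3 <- bn_bwd(dsum, cache$b3)
    g$bn3 <- b3[c("dgamma", "dbeta")]
    c3 <- conv_bwd(b3$dx, cache$c3, blk$conv3)
    g$conv3 <- list(dW = c3$dW)
    dr2 <- relu_bwd(c3$dx, cache$r2)
    b2 <- bn_bwd(dr2, cache$b2)
  } else {
    b2 <- bn_bwd(dsum, cache$b2)
  }
  g$bn2 <- b2[c("dgamma", "dbeta")]
  c2 <- conv_bwd(b2$dx, cache$c2, blk$conv2)
  g$conv2 <- list(dW = c2$dW)
  dr1 <- relu_bwd(c2$dx, cache$r1)
  b1 <- bn_bwd(dr1, cache$b1)
  g$bn1 <- b1[c("dgamma", "dbeta")]
  c1 <- conv_bwd(b1$dx, cache$c1, blk$conv1)
  g$conv1 <- list(dW = c1$dW)
  dx <- c1$dx
  if (!is.null(blk$sc_conv)) {
    sb <- bn_bwd(dsum, cache$scb)
    g$sc_bn <- sb[c("dgamma", "dbeta")]
    sc <- conv_bwd(sb$dx, cache$sc, blk$sc_conv)
    g$sc_conv <- list(dW = sc$dW)
    dx <- dx + sc$dx
  } else {
    dx <- dx + dsum
  }
  list(dx = dx, grads = g)
}

backbone_init <- function(profile) {
  pr <- if (is.character(profile)) backbone_profile(profile) else profile
  # reference: stride-2 stem + 3x3/2 max pool; test: a single stride-4 stem
  # (both land on 1/4 resolution, 56x56 for a 224 input)
  stem_conv <- conv_init(7L, 7L, 1L, pr$stem_channels)
  stem_conv$stride <- if (isTRUE(pr$stem_pool)) 2L else 4L
  stem_conv$pad <- 3L
  stages <- vector("list", 4L)
  c_in <- pr$stem_channels
  for (s in 1:4) {
    stride <- if (s == 1L) 1L else 2L
    blocks <- vector("list", pr$blocks[s])
    for (b in seq_len(pr$blocks[s])) {
      blocks[[b]] <- block_init(pr$block, c_in, pr$channels[s], pr$width[s],
                                if (b == 1L) stride else 1L)
      c_in <- pr$channels[s]
    }
    stages[[s]] <- blocks
  }
  list(profile = pr, stem_conv = stem_conv, stem_bn = bn_init(pr$stem_channels),
       stages = stages)
}

#' Backbone forward pass
#'
#' Runs an image batch through the four-stage residual backbone and returns
#' the feature pyramid: four maps whose spatial sizes halve stage to stage
#' (56/28/14/7 for a 224 x 224 input).
#'
#' @param backbone a backbone as built inside [build_model()].
#' @param x numeric array `dim c(H, W, B, 1)` of normalized images.
#' @param training logical; use batch statistics (and update running
#'   statistics) in batch-norm layers.
#' @param keep_cache keep intermediate activations for a backward pass.
#' @return List with `pyramid` (four feature arrays), the updated
#'   `backbone`, and (optionally) `cache`.
#' @export
backbone_forward <- function(backbone, x, training = FALSE,
                             keep_cache = FALSE) {
  stopifnot(length(dim(x)) == 4, dim(x)[4] == 1)
  cc <- list()
  cc$stem_c <- conv_fwd(x, backbone$stem_conv)
  cc$stem_b <- bn_fwd(cc$stem_c$out, backbone$stem_bn, training)
  backbone$stem_bn <- cc$stem_b$layer
  cc$stem_r <- relu_fwd(cc$stem_b$out)
  if (isTRUE(backbone$profile$stem_pool)) {
    cc$pool <- maxpool_fwd(cc$stem_r$out, 3L, 2L, 1L)
    h <- cc$pool$out
  } else {
    h <- cc$stem_r$out
  }
  pyramid <- vector("list", 4L)
  cc$stages <- vector("list", 4L)
  for (s in 1:4) {
    caches <- vector("list", length(backbone$stages[[s]]))
    for (b in seq_along(backbone$stages[[s]])) {
      r <- block_fwd(h, backbone$stages[[s]][[b]], training)
      backbone$stages[[s]][[b]] <- r$blk
      caches[[b]] <- if (keep_cache) r$cache
      h <- r$out
    }
    cc$stages[[s]] <- caches
    pyramid[[s]] <- h
  }
  list(pyramid = pyramid, backbone = backbone,
       cache = if (keep_cache) cc)
}

# dPyramid: list of four gradients w.r.t. the stage outputs (NULL allowed).
# Returns parameter gradients mirroring the backbone structure and, when
# requested, the gradient arriving at each stage output (head + downstream),
# which Grad-CAM consumes.
backbone_backward <- function(backbone, cache, dPyramid,
                              keep_stage_grads = FALSE) {
  g <- list(stages = vector("list", 4L))
  stage_grads <- vector("list", 4L)
  dh <- NULL
  for (s in 4:1) {
    d_out <- dPyramid[[s]]
    if (is.null(d_out)) d_out <- 0
    dh <- if (is.null(dh)) d_out else dh + d_out
    if (keep_stage_grads) stage_grads[[s]] <- dh
    nb <- length(backbone$stages[[s]])
    g$stages[[s]] <- vector("list", nb)
    for (b in nb:1) {
      r <- block_bwd(dh, cache$stages[[s]][[b]], backbone$stages[[s]][[b]])
      g$stages[[s]][[b]] <- r$grads
      dh <- r$dx
    }
  }
  if (!is.null(cache$pool)) dh <- maxpool_bwd(dh, cache$pool)
  dr <- relu_bwd(dh, cache$stem_r)
  db <- bn_bwd(dr, cache$stem_b)
  g$stem_bn <- db[c("dgamma", "dbeta")]
  dc <- conv_bwd(db$dx, cache$stem_c, backbone$stem_conv, need_dx = FALSE)
  g$stem_conv <- list(dW = dc$dW)
  list(grads = g, stage_grads = if (keep_stage_grads) stage_grads)
}
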