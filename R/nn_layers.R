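# Low-level network layers. Tensors are numeric arrays with
# dim c(H, W, B, C): height, width, batch, channels (column-major, H fastest).
# Convolutions are im2col + gemm; the im2col/col2im/maxpool kernels live in
# src/octex_kernels.cpp. Forward functions return a cache consumed by the
# matching backward function; parameters are plain lists of arrays.

conv_init <- function(kh, kw, c_in, c_out, rng_sd = NULL) {
  fan_in <- kh * kw * c_in
  sd <- if (is.null(rng_sd)) sqrt(2 / fan_in) else rng_sd
  list(W = matrix(stats::rnorm(fan_in * c_out, 0, sd), fan_in, c_out),
       kh = kh, kw = kw, stride = 1L, pad = 0L)
}

bn_init <- function(c_out) {
  list(gamma = rep(1, c_out), beta = rep(0, c_out),
       rmean = rep(0, c_out), rvar = rep(1, c_out))
}

conv_fwd <- function(x, layer) {
  d <- dim(x)
  kh <- layer$kh; kw <- layer$kw; s <- layer$stride; p <- layer$pad
  if (kh == 1L && kw == 1L && s == 1L && p == 0L) {
    M <- x
    dim(M) <- c(d[1] * d[2] * d[3], d[4])
    oH <- d[1]; oW <- d[2]
  } else {
    M <- octex_im2col(x, d[1], d[2], d[3], d[4], kh, kw, s, p)
    oH <- (d[1] + 2 * p - kh) %/% s + 1
    oW <- (d[2] + 2 * p - kw) %/% s + 1
  }
  Y <- M %*% layer$W
  dim(Y) <- c(oH, oW, d[3], ncol(layer$W))
  list(out = Y, M = M, in_dim = d)
}

conv_bwd <- function(dY, cache, layer, need_dx = TRUE) {
  d <- cache$in_dim
  od <- dim(dY)
  dim(dY) <- c(od[1] * od[2] * od[3], od[4])
  dW <- crossprod(cache$M, dY)
  if (!need_dx) return(list(dx = NULL, dW = dW))
  dM <- dY %*% t(layer$W)
  if (layer$kh == 1L && layer$kw == 1L && layer$stride == 1L &&
      layer$pad == 0L) {
    dx <- dM
    dim(dx) <- d
  } else {
    dx <- octex_col2im(dM, d[1], d[2], d[3], d[4],
                       layer$kh, layer$kw, layer$stride, layer$pad)
  }
  list(dx = dx, dW = dW)
}

bn_fwd <- function(x, layer, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  n <- prod(d[1:3])
  r <- octex_bn_fwd(x, n, d[4], layer$gamma, layer$beta, layer$rmean,
                    layer$rvar, training, momentum, eps)
  if (training) {
    layer$rmean <- r$rmean
    layer$rvar <- r$rvar
  }
  y <- r$y
  dim(y) <- d
  list(out = y, xhat = r$xhat, invstd = r$invstd, layer = layer, dims = d,
       training = training)
}

bn_bwd <- function(dy, cache) {
  d <- cache$dims
  n <- prod(d[1:3])
  r <- octex_bn_bwd(dy, cache$xhat, cache$invstd, cache$layer$gamma, n,
                    d[4], cache$training)
  dx <- r$dx
  dim(dx) <- d
  list(dx = dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

relu_fwd <- function(x) {
  r <- octex_relu_fwd(x)
  out <- r$y
  dim(out) <- dim(x)
  list(out = out, mask = r$mask)
}

relu_bwd <- function(dy, cache) {
  dx <- octex_relu_bwd(dy, cache$mask)
  dim(dx) <- dim(dy)
  dx
}

maxpool_fwd <- function(x, k, stride, pad) {
  d <- dim(x)
  r <- octex_maxpool(x, d[1], d[2], d[3], d[4], k, stride, pad)
  list(out = r$out, argmax = r$argmax, in_dim = d)
}

maxpool_bwd <- function(dy, cache) {
  d <- cache$in_dim
  octex_maxpool_backward(dy, cache$argmax, d[1], d[2], d[3], d[4])
}

fc_init <- function(d_in, d_out) {
  lim <- 1 / sqrt(d_in)
  list(W = matrix(stats::runif(d_in * d_out, -lim, lim), d_in, d_out),
       b = rep(0, d_out))
}

fc_fwd <- function(v, layer) {
  # v: B x d_in
  out <- v %*% layer$W
  out <- sweep(out, 2, layer$b, `+`)
  list(out = out, v = v)
}

fc_bwd <- function(dy, cache, layer) {
  list(dv = dy %*% t(layer$W), dW = crossprod(cache$v, dy), db = colSums(dy))
}

# Row-wise numerically stable softmax.
softmax_rows <- function(z) {
  rmax <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - rmax)
  e / rowSums(e)
}
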