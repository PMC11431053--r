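# Texton-dictionary texture encoding: an orderless pooling that represents
# a set of descriptors by soft-assignment-weighted residuals to K learnable
# codewords. For descriptor x_i and codeword c_k with residual
# r_ik = x_i - c_k and smoothing factor s_k:
#   a_ik = exp(-s_k ||r_ik||^2) / sum_j exp(-s_j ||r_ij||^2)
#   e_k  = sum_i a_ik r_ik
# The K x D aggregate is flattened into one texture feature vector.

#' Create a texton dictionary
#'
#' @param K number of textons (codewords); the paper's reference setting
#'   is 32.
#' @param D descriptor dimension; reference setting 128.
#' @param seed optional integer seed for reproducible initialization.
#' @return List of class `octex_dictionary`: `C` (K x D codeword matrix,
#'   uniform in `(-1/sqrt(K), 1/sqrt(K))`) and `s` (K positive smoothing
#'   factors, uniform in `(0, 1]`); both are learnable.
#' @export
texton_dictionary <- function(K = 32L, D = 128L, seed = NULL) {
  stopifnot(K >= 1, D >= 1)
  run <- function() {
    lim <- 1 / sqrt(K)
    list(C = matrix(stats::runif(K * D, -lim, lim), K, D),
         s = stats::runif(K, .Machine$double.eps, 1))
  }
  dict <- if (is.null(seed)) run() else with_seed(seed, run())
  dict$K <- as.integer(K)
  dict$D <- as.integer(D)
  class(dict) <- "octex_dictionary"
  dict
}

#' Soft-assignment weights of descriptors to textons
#'
#' Computes the N x K matrix `a_ik` of assignment weights: a softmax over
#' codewords of the negated smoothed squared residual norms, evaluated with
#' max-subtraction for numerical stability. Every row sums to 1.
#'
#' @param X N x D matrix of descriptors (rows are descriptors).
#' @param dict an `octex_dictionary`, or a list with `C` (K x D) and `s` (K).
#' @return N x K matrix of weights in (0, 1), rows summing to 1.
#' @export
assign_weights <- function(X, dict) {
  X <- as.matrix(X)
  Cm <- as.matrix(dict$C)
  s <- as.numeric(dict$s)
  stopifnot(ncol(X) == ncol(Cm), length(s) == nrow(Cm),
            all(is.finite(X)), all(is.finite(Cm)), all(is.finite(s)))
  d2 <- sq_dist(X, Cm)
  softmax_rows(-d2 * rep(s, each = nrow(d2)))
}

# pairwise squared Euclidean distances, clamped at 0 against round-off
sq_dist <- function(X, Cm) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(Cm))) +
    outer(rep(1, nrow(X)), rowSums(Cm^2)) - 2 * tcrossprod(X, Cm)
  d2[d2 < 0] <- 0
  d2
}

#' Residual texture encoding of a descriptor set
#'
#' Aggregates descriptors into K weighted-residual vectors
#' `e_k = sum_i a_ik (x_i - c_k)` and flattens them into a single feature of
#' length `K * D`. The operation is orderless: permuting the descriptors
#' leaves the encoding unchanged.
#'
#' @inheritParams assign_weights
#' @return List with `E` (K x D matrix of aggregated residuals), `a`
#'   (N x K assignment weights), and `feature` (numeric vector of length
#'   `K * D`, the flattened `E`).
#' @export
texture_encode <- function(X, dict) {
  X <- as.matrix(X)
  Cm <- as.matrix(dict$C)
  a <- assign_weights(X, dict)
  E <- crossprod(a, X) - colSums(a) * Cm
  list(E = E, a = a, feature = as.vector(E))
}

# --- internal batched forward/backward used inside the model ---------------

# Z: (H, W, B, D) conv-block output. Returns B x (K*D) features plus cache.
encode_batch_fwd <- function(Z, dict) {
  d <- dim(Z)
  N <- d[1] * d[2]; B <- d[3]; D <- d[4]
  K <- nrow(dict$C)
  feats <- matrix(0, B, K * D)
  caches <- vector("list", B)
  for (b in seq_len(B)) {
    X <- matrix(Z[, , b, ], N, D) # descriptors of image b, rows = (h, w)
    d2 <- sq_dist(X, dict$C)
    a <- softmax_rows(-d2 * rep(dict$s, each = N))
    asum <- colSums(a)
    E <- crossprod(a, X) - asum * dict$C
    feats[b, ] <- as.vector(E)
    caches[[b]] <- list(X = X, a = a, asum = asum, d2 = d2)
  }
  list(feature = feats, caches = caches, dims = d)
}

# dFeat: B x (K*D). Returns dZ (H, W, B, D), dC (K x D), ds (K).
encode_batch_bwd <- function(dFeat, cache, dict) {
  d <- cache$dims
  N <- d[1] * d[2]; B <- d[3]; D <- d[4]
  K <- nrow(dict$C)
  dZ <- array(0, d)
  dC <- matrix(0, K, D)
  ds <- numeric(K)
  for (b in seq_len(B)) {
    cb <- cache$caches[[b]]
    dE <- matrix(dFeat[b, ], K, D)
    # through the aggregation e_k = sum_i a_ik x_i - asum_k c_k
    gmat <- tcrossprod(cb$X, dE) - # g_ik = de_k . (x_i - c_k)
      matrix(rowSums(dE * dict$C), N, K, byrow = TRUE)
    tmat <- cb$a * (gmat - rowSums(cb$a * gmat)) # softmax backward
    umat <- sweep(tmat, 2, dict$s, `*`)
    dX <- cb$a %*% dE - 2 * (cb$X * rowSums(umat) - umat %*% dict$C)
    dC <- dC - cb$asum * dE +
      2 * (crossprod(umat, cb$X) - dict$C * colSums(umat))
    ds <- ds - colSums(tmat * cb$d2)
    dZ[, , b, ] <- dX
  }
  list(dZ = dZ, dC = dC, ds = ds)
}
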