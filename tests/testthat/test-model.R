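test_that("conv block projects to D rectified channels, spatial size kept", {
  set.seed(2)
  head <- list(conv = octex:::conv_init(1L, 1L, 6L, 5L),
               bn = octex:::bn_init(5L))
  x <- array(rnorm(8 * 8 * 2 * 6), c(8, 8, 2, 6))
  r <- octex:::conv_block_fwd(x, head, training = TRUE)
  expect_equal(dim(r$out), c(8, 8, 2, 5))
  expect_true(all(r$out >= 0))
})

test_that("identity conv block with frozen normalization rectifies its input", {
  D <- 4L
  head <- list(conv = octex:::conv_init(1L, 1L, D, D),
               bn = octex:::bn_init(D))
  head$conv$W <- diag(D) # 1x1 identity projection
  # frozen normalization: running mean 0, running var 1 (evaluation mode)
  x <- array(rnorm(5 * 5 * 1 * D), c(5, 5, 1, D))
  r <- octex:::conv_block_fwd(x, head, training = FALSE)
  expect_equal(r$out, x * (x > 0) / sqrt(1 + 1e-5), tolerance = 1e-9)
})

test_that("auxiliary classifier is scale-invariant through L2 normalization", {
  set.seed(13)
  fc <- octex:::fc_init(6L, 3L)
  v <- matrix(rnorm(12), 2, 6)
  logits1 <- octex:::fc_fwd(octex:::l2_normalize_rows(v)$out, fc)$out
  logits2 <- octex:::fc_fwd(octex:::l2_normalize_rows(10 * v)$out, fc)$out
  expect_equal(logits1, logits2, tolerance = 1e-12)

  # zero weights: logits equal the bias; zero input maps through safely
  fc0 <- list(W = matrix(0, 6, 3), b = c(1, 2, 3))
  z <- octex:::fc_fwd(octex:::l2_normalize_rows(matrix(0, 1, 6))$out, fc0)$out
  expect_equal(as.vector(z), c(1, 2, 3))
})

test_that("fusion sums logits, normalizes, and breaks ties low", {
  f <- fuse_logits(list(c(0, 0), c(0, 0), c(0, 0), c(0, 0)))
  expect_equal(f$prob, c(0.5, 0.5))
  expect_equal(f$label, 1L)

  f2 <- fuse_logits(list(c(1, 0), c(0, 1), c(0, 0), c(0, 0)))
  expect_equal(f2$prob, c(0.5, 0.5))
  expect_equal(f2$label, 1L)

  v <- c(2, -1, 0.5)
  f3 <- fuse_logits(rep(list(v), 4))
  expect_equal(f3$prob, as.vector(exp(4 * v) / sum(exp(4 * v))))
  expect_equal(f3$label, which.max(v))
  expect_equal(sum(f3$prob), 1, tolerance = 1e-12)

  expect_error(fuse_logits(list(c(1, 2), c(1, 2, 3))), "length")
})

test_that("label smoothing mixes one-hot with uniform", {
  expect_equal(smooth_labels(3, 0, 5), c(0, 0, 1, 0, 0))
  expect_equal(smooth_labels(1, 0.1, 5), c(0.92, 0.02, 0.02, 0.02, 0.02))
  expect_equal(smooth_labels(1, 0.1, 2), c(0.95, 0.05))
  expect_equal(sum(smooth_labels(2, 0.3, 7)), 1, tolerance = 1e-12)
  expect_error(smooth_labels(1, 1, 5))
})

test_that("loss breakdown: identities and hand-computed values", {
  # uniform predictions: every term is ln C
  u <- rep(1 / 5, 5)
  lb <- loss_breakdown(rep(list(u), 4), u, true_class = 2, epsilon = 0.1)
  expect_equal(lb$aux, rep(log(5), 4), tolerance = 1e-12)
  expect_equal(lb$main, log(5), tolerance = 1e-12)
  expect_equal(lb$total, 5 * log(5), tolerance = 1e-12)

  # without smoothing a perfect fused prediction has zero main loss
  lb2 <- loss_breakdown(rep(list(u), 4), c(0, 1, 0, 0, 0), 2, epsilon = 0)
  expect_equal(lb2$main, 0, tolerance = 1e-9)

  # binary case against the smoothed target
  lb3 <- loss_breakdown(list(), c(0.7, 0.3), 1, epsilon = 0.1)
  expect_equal(lb3$main, -(0.95 * log(0.7) + 0.05 * log(0.3)),
               tolerance = 1e-12)

  # total is exactly the sum of its parts on random inputs
  set.seed(31)
  for (i in 1:10) {
    probs <- lapply(1:4, function(j) {
      p <- runif(5); p / sum(p)
    })
    pm <- runif(5); pm <- pm / sum(pm)
    lb4 <- loss_breakdown(probs, pm, sample(5, 1), epsilon = 0.1)
    expect_identical(lb4$total, sum(lb4$aux) + lb4$main)
  }

  # epsilon = 0 reduces the smoothed cross-entropy to the standard one
  p <- c(0.2, 0.5, 0.3)
  lb5 <- loss_breakdown(list(), p, 2, epsilon = 0)
  expect_equal(lb5$main, -log(0.5), tolerance = 1e-12)
})

test_that("batched forward matches per-item forward", {
  cfg <- model_config(profile = "test", K = 4, D = 8)
  m <- build_model(cfg, seed = 5)
  set.seed(6)
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3, 1))
  batch <- octex:::model_forward(m, x, training = FALSE)
  for (b in 1:3) {
    single <- octex:::model_forward(m, x[, , b, , drop = FALSE],
                                    training = FALSE)
    expect_equal(single$prob[1, ], batch$prob[b, ], tolerance = 1e-10)
  }
  expect_equal(rowSums(batch$prob), rep(1, 3), tolerance = 1e-6)
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- model_config(profile = "test", K = 3, D = 4)
  m <- build_model(cfg, seed = 3)
  set.seed(42)
  x <- array(rnorm(64 * 64 * 2), c(64, 64, 2, 1))
  labels <- c(2L, 5L)
  loss_of <- function(mm) {
    out <- octex:::model_forward(mm, x, training = TRUE, keep_cache = TRUE)
    lb <- octex:::loss_batch(out$scale_logits, labels, mm$config)
    list(loss = lb$total, out = out, lb = lb)
  }
  r <- loss_of(m)
  grads <- octex:::model_backward(m, r$out, r$lb$dlogits)
  num <- function(get, set, eps = 1e-5) {
    (loss_of(set(m, get(m) + eps))$loss -
       loss_of(set(m, get(m) - eps))$loss) / (2 * eps)
  }
  cases <- list(
    list(g = grads$heads[[4]]$dict$dC[1, 2],
         a = function(m) m$heads[[4]]$dict$C[1, 2],
         s = function(m, v) { m$heads[[4]]$dict$C[1, 2] <- v; m }),
    list(g = grads$heads[[4]]$dict$ds[2],
         a = function(m) m$heads[[4]]$dict$s[2],
         s = function(m, v) { m$heads[[4]]$dict$s[2] <- v; m }),
    list(g = grads$heads[[1]]$fc$dW[5, 3],
         a = function(m) m$heads[[1]]$fc$W[5, 3],
         s = function(m, v) { m$heads[[1]]$fc$W[5, 3] <- v; m }),
    list(g = grads$backbone$stem_conv$dW[10, 3],
         a = function(m) m$backbone$stem_conv$W[10, 3],
         s = function(m, v) { m$backbone$stem_conv$W[10, 3] <- v; m }),
    list(g = grads$backbone$stages[[3]][[1]]$conv2$dW[20, 5],
         a = function(m) m$backbone$stages[[3]][[1]]$conv2$W[20, 5],
         s = function(m, v) {
           m$backbone$stages[[3]][[1]]$conv2$W[20, 5] <- v; m
         })
  )
  for (ck in cases) {
    ng <- num(ck$a, ck$s)
    expect_equal(ck$g, ng, tolerance = 1e-4)
  }
})

test_that("ablation variants run forward and train a step end-to-end", {
  set.seed(8)
  variants <- list(
    b_te = model_config(profile = "test", K = 3, D = 4, use_fpn = FALSE,
                        deep_supervision = FALSE),
    b_fpn = model_config(profile = "test", D = 4, use_encoding = FALSE),
    b_f_t = model_config(profile = "test", K = 3, D = 4,
                         deep_supervision = FALSE)
  )
  x <- array(rnorm(64 * 64 * 4), c(64, 64, 4, 1))
  labels <- c(1L, 2L, 4L, 5L)
  for (nm in names(variants)) {
    m <- build_model(variants[[nm]], seed = 2)
    out <- octex:::model_forward(m, x, training = TRUE, keep_cache = TRUE)
    expect_equal(dim(out$prob), c(4L, 5L))
    lb <- octex:::loss_batch(out$scale_logits, labels, m$config)
    g <- octex:::model_backward(m, out, lb$dlogits)
    upd <- octex:::sgd_step(m, g, NULL, lr = 0.01)
    out2 <- octex:::model_forward(upd$model, x, training = TRUE,
                                  keep_cache = TRUE)
    lb2 <- octex:::loss_batch(out2$scale_logits, labels, m$config)
    expect_lt(lb2$total, lb$total) # one step on one batch reduces its loss
  }
})

test_that("checkpoints round-trip through disk", {
  m <- build_model(model_config(profile = "test", K = 2, D = 3), seed = 10)
  m$norm_stats <- list(mean = 100, sd = 50)
  p <- tempfile(fileext = ".rds")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  expect_identical(m2, m)
  set.seed(1)
  x <- array(rnorm(64 * 64), c(64, 64, 1, 1))
  expect_identical(octex:::model_forward(m, x)$prob,
                   octex:::model_forward(m2, x)$prob)
})
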