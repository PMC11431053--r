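test_that("TIFF volumes round-trip losslessly in page order", {
  sv <- generate_volume("CY", synthetic_config(), seed = 2)
  p <- tempfile(fileext = ".tiff")
  write_volume(sv$volume, p)
  back <- read_volume(p)
  expect_identical(back$frames, sv$volume$frames)

  # single-frame volume
  one <- oct_volume(sv$volume$frames[1])
  p1 <- tempfile(fileext = ".tiff")
  write_volume(one, p1)
  expect_length(read_volume(p1)$frames, 1)

  # RGB pages are rejected
  prgb <- tempfile(fileext = ".tiff")
  tiff::writeTIFF(array(runif(10 * 10 * 3), c(10, 10, 3)), prgb)
  expect_error(read_volume(prgb), "grayscale")

  expect_error(oct_volume(list(matrix(0, 4, 4), matrix(0, 5, 4))),
               "share one")
  unlink(c(p, p1, prgb))
})

test_that("sliding windows follow the count formula and crop exactly", {
  fr <- matrix(seq_len(50 * 1000), 50, 1000)
  vol <- oct_volume(rep(list(fr), 10))
  g <- extract_patches(vol, window_size = 50, stride = 200)
  expect_equal(g$offsets, c(0L, 200L, 400L, 600L, 800L))
  expect_equal(length(g$patches) * length(g$offsets), 50)
  expect_identical(g$patches[[3]][[2]], fr[1:50, 201:250])

  # window equal to frame width: a single window at offset 0
  g2 <- extract_patches(oct_volume(list(matrix(0, 30, 30))), 30, 10)
  expect_equal(g2$offsets, 0L)

  # degenerate stride larger than the slack still yields one window
  g3 <- extract_patches(oct_volume(list(matrix(0, 30, 40))), 30, 100)
  expect_equal(g3$offsets, 0L)

  expect_error(extract_patches(vol, 2000, 10), "width")
  expect_error(extract_patches(oct_volume(list(matrix(0, 20, 100))), 50, 10),
               "shorter")
})

test_that("preprocessing resizes and z-scores as specified", {
  patch <- matrix(100, 60, 60)
  out <- preprocess_patch(patch, 224, stats = list(mean = 100, sd = 1))
  expect_equal(dim(out), c(224L, 224L))
  expect_true(all(out == 0))

  # per-image statistics give mean 0, sd 1
  set.seed(4)
  p2 <- matrix(runif(600 * 600, 0, 255), 600, 600)
  z <- preprocess_patch(p2, 224)
  expect_equal(dim(z), c(224L, 224L))
  expect_lt(abs(mean(z)), 1e-3)
  expect_lt(abs(stats::sd(as.vector(z)) - 1), 1e-3)

  expect_error(preprocess_patch(patch, 224, stats = list(mean = 0, sd = 0)),
               "sd > 0")
})

test_that("augmentation transforms are involutive, optional, and seeded", {
  set.seed(10)
  patch <- matrix(runif(48 * 48, 0, 255), 48, 48)

  hflip_only <- augment_config(p_hflip = 1, p_vflip = 0, p_noise = 0,
                               p_brightness = 0)
  once <- augment_patch(patch, hflip_only, seed = 1)
  twice <- augment_patch(once, hflip_only, seed = 1)
  expect_identical(twice, patch)

  off <- augment_config(p_hflip = 0, p_vflip = 0, p_noise = 0,
                        p_brightness = 0)
  expect_identical(augment_patch(patch, off, seed = 1), patch)

  full <- augment_config()
  expect_identical(augment_patch(patch, full, seed = 3),
                   augment_patch(patch, full, seed = 3))
  aug <- augment_patch(patch, full, seed = 3)
  expect_true(all(aug >= 0 & aug <= 255))
})

test_that("oversampling weights equalize expected class frequencies", {
  w <- oversampling_weights(c("A", "A", "A", "B"))
  expect_equal(w, c(1 / 3, 1 / 3, 1 / 3, 1))
  # expected sampled frequency of the rare class is 1/2
  expect_equal(sum(w[4]) / sum(w), 0.5)

  expect_equal(oversampling_weights(c("A", "B", "A", "B")), rep(0.5, 4))
  expect_error(oversampling_weights(character(0)), "empty")

  labels <- c(rep("A", 90), rep("B", 10))
  w2 <- oversampling_weights(labels)
  set.seed(99)
  draws <- sample(labels, 1e4, replace = TRUE, prob = w2)
  freq <- mean(draws == "B")
  expect_lt(abs(freq - 0.5), 0.02)
  expect_gt(stats::chisq.test(table(draws), p = c(0.5, 0.5))$p.value, 0.01)
})
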