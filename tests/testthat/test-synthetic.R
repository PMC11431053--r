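cfg <- synthetic_config()

test_that("volumes are seeded, bounded, and carry masks only when lesional", {
  v1 <- generate_volume("HSIL", cfg, seed = 7)
  v2 <- generate_volume("HSIL", cfg, seed = 7)
  expect_identical(v1, v2) # bit-identical under a fixed seed
  expect_false(identical(v1, generate_volume("HSIL", cfg, seed = 8)))

  mi <- generate_volume("MI", cfg, seed = 7)
  expect_false(any(mi$lesion_mask))
  expect_true(any(v1$lesion_mask))
  expect_length(mi$volume$frames, cfg$frame_count)
  rng <- range(unlist(mi$volume$frames))
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 255)

  expect_error(generate_volume("XX", cfg), "unknown class")
  expect_error(synthetic_config(frame_width = 96, window_size = 96,
                                lesion_min_extent = c(3, 5)),
               "window grid")
})

test_that("lesion masks span at least the configured extent, window-aligned", {
  for (s in 1:10) {
    sv <- generate_volume(sample(c("HSIL", "CC"), 1), cfg, seed = s)
    fr <- which(apply(sv$lesion_mask, 1, any))
    xs <- which(apply(sv$lesion_mask, 2, any))
    expect_gte(length(fr), cfg$lesion_min_extent[1])
    expect_identical(fr, seq(min(fr), max(fr))) # contiguous frames
    min_px <- cfg$window_size + (cfg$lesion_min_extent[2] - 1) * cfg$stride
    expect_gte(length(xs), min_px)
    expect_equal((min(xs) - 1) %% cfg$stride, 0) # aligned to the window grid
  }
})

test_that("the layering statistic separates stratified from lesional tissue", {
  stat <- sapply(oct_classes(), function(cl) {
    sapply(1:20, function(s) layering_statistic(generate_volume(cl, cfg, s)))
  })
  neg <- as.vector(stat[, c("MI", "CY", "EP")])
  pos <- as.vector(stat[, c("HSIL", "CC")])
  # class-conditional separation on every one of the 100 volumes
  expect_gte(mean(outer(neg, pos, `-`) > 0), 0.95)
  thr <- (min(neg) + max(pos)) / 2
  expect_gte(mean(c(neg > thr, pos < thr)), 0.95)

  # the worked pairing: carcinoma vs inflammation at one seed
  d <- layering_statistic(generate_volume("MI", cfg, 3)) -
    layering_statistic(generate_volume("CC", cfg, 3))
  expect_gt(abs(d), cfg$separation_margin)
})

test_that("cohorts honor the mix, the binary mapping, and the seed", {
  co <- generate_cohort(10, c(MI = 1, CY = 0, EP = 0, HSIL = 0, CC = 0),
                        volumes_per_patient = 2, cfg, seed = 1)
  expect_length(co$patients, 10)
  expect_true(all(vapply(co$patients, function(p) !p$binary, logical(1))))
  expect_equal(sum(lengths(lapply(co$patients, `[[`, "volumes"))), 20)

  expect_identical(generate_cohort(5, rep(0.2, 5), 1, cfg, seed = 2),
                   generate_cohort(5, rep(0.2, 5), 1, cfg, seed = 2))
  expect_error(generate_cohort(5, c(0.5, 0.2, 0.1, 0.1, 0.2), 1, cfg),
               "sum to 1")

  pos <- generate_cohort(6, c(0, 0, 0, 0.5, 0.5), 1, cfg, seed = 3)
  expect_true(all(vapply(pos$patients, `[[`, logical(1), "binary")))
})

test_that("sampled class counts fit a multinomial over many seeds", {
  tiny <- synthetic_config(frame_count = 3, frame_height = 32,
                           frame_width = 96, window_size = 32, stride = 32)
  counts <- matrix(0, 50, 5, dimnames = list(NULL, oct_classes()))
  for (s in 1:50) {
    co <- generate_cohort(100, rep(0.2, 5), 1, tiny, seed = 1000 + s)
    cls <- vapply(co$patients, `[[`, character(1), "class")
    counts[s, ] <- table(factor(cls, levels = oct_classes()))
  }
  expect_equal(unname(colMeans(counts)), rep(20, 5), tolerance = 0.12)
  p <- stats::chisq.test(colSums(counts), p = rep(0.2, 5))$p.value
  expect_gt(p, 0.01)
})

test_that("patch datasets follow the window-count formula and purity rule", {
  one <- generate_cohort(1, c(1, 0, 0, 0, 0), 1, cfg, seed = 4)
  ds <- generate_patch_dataset(one, window_size = 96, stride = 64)
  n_win <- (cfg$frame_width - 96) %/% 64 + 1
  expect_equal(length(ds$patches), n_win * cfg$frame_count)
  expect_true(all(ds$meta$class == "MI"))
  expect_equal(dim(ds$patches[[1]]), c(96L, 96L))

  # lesional volume: only mask-covered windows survive
  pos <- generate_cohort(1, c(0, 0, 0, 1, 0), 1, cfg, seed = 5)
  sv <- pos$patients[[1]]$volumes[[1]]
  dsp <- generate_patch_dataset(pos)
  for (i in seq_len(nrow(dsp$meta))) {
    row <- dsp$meta[i, ]
    if (row$volume_id != sprintf("%s_V01", pos$patients[[1]]$patient_id)) next
    xs <- row$offset + seq_len(96)
    expect_gte(mean(sv$lesion_mask[row$frame, xs]), 0.5)
  }
  # provenance columns are present and consistent
  expect_true(all(c("patient_id", "volume_id", "frame", "window_index",
                    "offset", "class", "binary") %in% names(dsp$meta)))

  empty <- generate_cohort(1, c(1, 0, 0, 0, 0), 1, cfg, seed = 6)
  empty$patients <- list()
  expect_equal(length(generate_patch_dataset(empty)$patches), 0)
})

test_that("cohorts round-trip to TIFF + manifest on disk", {
  dir <- file.path(tempdir(), "cohort-test")
  co <- generate_cohort(2, c(0.5, 0, 0, 0.5, 0), 2, cfg, seed = 9)
  mp <- write_cohort(co, dir)
  man <- read.csv(mp, stringsAsFactors = FALSE)
  expect_equal(nrow(man), 4)
  v <- read_volume(file.path(dir, man$volume_path[1]))
  expect_identical(v$frames, co$patients[[1]]$volumes[[1]]$volume$frames)
  expect_setequal(unique(man$binary_label),
                  as.integer(unique(vapply(co$patients, `[[`, logical(1),
                                           "binary"))))
  unlink(dir, recursive = TRUE)
})
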