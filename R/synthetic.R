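# Seeded synthetic cervical OCT volumes. Each class renders the texture
# motif its OCT appearance is known for: stratified epithelium with a
# bright basement-membrane (BM) line for inflammation; dark cystic voids
# for cysts; bright-edged papillary undulations for ectropion; loss of
# stratification for HSIL; loss of stratification with alternating
# light/dark vertical attenuation bands for carcinoma. Lesional classes
# carry a ground-truth (frame, x-position) mask.

#' Synthetic cohort configuration
#'
#' @param frame_count frames per volume (>= 3; cross-frame voting needs
#'   neighbors). Ten matches the clinical acquisition.
#' @param frame_height,frame_width frame size in pixels.
#' @param window_size,stride sliding-window geometry used to align lesions
#'   and to cut patches (`stride` defaults to `window_size / 3`, an
#'   overlapping grid).
#' @param noise_sigma standard deviation of the additive Gaussian noise on
#'   the 0..255 intensity scale (a simple stand-in for OCT speckle).
#' @param lesion_min_extent integer pair `(frames, windows)`: the minimum
#'   lesion footprint, at least `(3, 3)` so a true lesion can always fire
#'   the cross-shaped voting rule.
#' @param separation_margin minimum gap in the layering statistic
#'   ([layering_statistic()]) between negative and lesional volumes; fixed
#'   by a one-off calibration over seeded volumes.
#' @param motif per-class motif parameters; see the function body for the
#'   full set (amplitudes, periods, geometry).
#' @return List of class `octex_synth_config`.
#' @export
synthetic_config <- function(frame_count = 10L, frame_height = 96L,
                             frame_width = 224L, window_size = 96L,
                             stride = NULL, noise_sigma = 8,
                             lesion_min_extent = c(3L, 3L),
                             separation_margin = 0.6,
                             motif = list()) {
  if (is.null(stride)) stride <- max(1L, round(window_size / 3))
  stopifnot(frame_count >= 3, noise_sigma >= 0,
            window_size <= frame_height, window_size <= frame_width,
            length(lesion_min_extent) == 2, all(lesion_min_extent >= 3))
  n_windows <- (frame_width - window_size) %/% stride + 1L
  if (lesion_min_extent[2] > n_windows) {
    stop("lesion_min_extent exceeds the window grid (",
         n_windows, " windows per frame)")
  }
  if (lesion_min_extent[1] > frame_count) {
    stop("lesion_min_extent exceeds the frame count")
  }
  defaults <- list(
    base = 120, layer_period = 12, layer_amplitude = 35,
    bm_depth = 0.55, bm_width = 2.5, bm_gain = 90,
    cyst_n = c(2L, 4L), cyst_level = 35, cyst_rx = c(10, 24),
    cyst_ry = c(6, 14),
    ep_wavelength = 45, ep_amp = 12, ep_edge_depth = 0.3,
    ep_edge_gain = 110, ep_lumen = 70,
    lesion_level = 110, lesion_smooth_amp = 6,
    cc_band_period = 28, cc_band_contrast = 50
  )
  defaults[names(motif)] <- motif
  cfg <- list(frame_count = as.integer(frame_count),
              frame_height = as.integer(frame_height),
              frame_width = as.integer(frame_width),
              window_size = as.integer(window_size),
              stride = as.integer(stride),
              n_windows = as.integer(n_windows),
              intensity_range = c(0, 255),
              noise_sigma = noise_sigma,
              lesion_min_extent = as.integer(lesion_min_extent),
              separation_margin = separation_margin,
              motif = defaults)
  class(cfg) <- "octex_synth_config"
  cfg
}

render_layers <- function(H, W, p, phase) {
  prof <- p$base + p$layer_amplitude * sin(2 * pi * (seq_len(H) + phase) /
                                             p$layer_period)
  matrix(prof, H, W)
}

add_bm_line <- function(img, p) {
  H <- nrow(img)
  y_bm <- p$bm_depth * H
  img + p$bm_gain * exp(-((seq_len(H) - y_bm) / p$bm_width)^2)
}

render_mi <- function(H, W, p, phase) add_bm_line(render_layers(H, W, p, phase), p)

render_cy <- function(H, W, p, phase) {
  img <- render_mi(H, W, p, phase)
  n <- sample(p$cyst_n[1]:p$cyst_n[2], 1)
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (i in seq_len(n)) {
    cx <- stats::runif(1, 0.1 * W, 0.9 * W)
    cy <- stats::runif(1, 0.25 * H, 0.8 * H)
    rx <- stats::runif(1, p$cyst_rx[1], p$cyst_rx[2])
    ry <- stats::runif(1, p$cyst_ry[1], p$cyst_ry[2])
    d <- ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2
    w <- clamp(1.6 * (1 - d), 0, 1) # soft-edged void
    img <- img * (1 - w) + p$cyst_level * w
  }
  img
}

render_ep <- function(H, W, p, phase) {
  img <- render_layers(H, W, p, phase)
  edge <- p$ep_edge_depth * H +
    p$ep_amp * sin(2 * pi * seq_len(W) / p$ep_wavelength + phase)
  yy <- matrix(seq_len(H), H, W)
  ee <- matrix(edge, H, W, byrow = TRUE)
  img[yy < ee] <- p$ep_lumen # low-signal lumen above the papillary surface
  img + p$ep_edge_gain * exp(-((yy - ee) / 2.5)^2) # hyper-scattering fringe
}

# destratified lesion texture: no layering, only a weak smooth modulation
render_lesion <- function(H, W, p, phase, bands = FALSE) {
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  img <- p$lesion_level +
    p$lesion_smooth_amp * sin(2 * pi * yy / (H / 1.3) + phase) *
    sin(2 * pi * xx / (W / 1.7) + 2 * phase)
  if (bands) { # alternating light/dark attenuation columns
    img <- img + p$cc_band_contrast * sin(2 * pi * xx / p$cc_band_period +
                                            phase)
  }
  img
}

#' Generate one synthetic OCT volume
#'
#' Renders a seeded multi-frame volume with the class motif, additive
#' Gaussian noise clipped to the intensity range, and — for the lesional
#' classes HSIL and CC — a ground-truth lesion mask: a uniformly placed
#' contiguous block of frames and window-aligned x-positions whose extent
#' is at least `config$lesion_min_extent`.
#'
#' @param class_label one of `oct_classes()`.
#' @param config an [synthetic_config()].
#' @param seed integer; identical arguments and seed give a bit-identical
#'   volume.
#' @return List of class `octex_synth_volume`: `volume` (an
#'   [oct_volume()]), `class_label`, `binary` (high-risk flag), and
#'   `lesion_mask` (frame x x-position logical matrix; all-`FALSE` for
#'   negative classes).
#' @export
generate_volume <- function(class_label, config = synthetic_config(),
                            seed = 1L) {
  if (!class_label %in% oct_classes()) {
    stop("unknown class label: ", class_label)
  }
  H <- config$frame_height; W <- config$frame_width
  p <- config$motif
  positive <- class_label %in% positive_classes()
  with_seed(seed, {
    mask <- matrix(FALSE, config$frame_count, W)
    lesion <- NULL
    if (positive) {
      minf <- config$lesion_min_extent[1]
      minw <- config$lesion_min_extent[2]
      nf <- sample(minf:config$frame_count, 1)
      f0 <- sample(seq_len(config$frame_count - nf + 1L), 1)
      nw <- sample(minw:config$n_windows, 1)
      w0 <- sample(seq_len(config$n_windows - nw + 1L), 1)
      x0 <- (w0 - 1L) * config$stride + 1L
      x1 <- x0 + config$window_size + (nw - 1L) * config$stride - 1L
      lesion <- list(frames = f0:(f0 + nf - 1L), x = x0:x1)
      mask[lesion$frames, lesion$x] <- TRUE
    }
    frames <- vector("list", config$frame_count)
    for (f in seq_len(config$frame_count)) {
      phase <- stats::runif(1, 0, 2 * pi)
      img <- switch(class_label,
                    MI = render_mi(H, W, p, phase),
                    CY = render_cy(H, W, p, phase),
                    EP = render_ep(H, W, p, phase),
                    HSIL = ,
                    CC = render_mi(H, W, p, phase))
      if (positive && f %in% lesion$frames) {
        les <- render_lesion(H, W, p, phase, bands = class_label == "CC")
        img[, lesion$x] <- les[, lesion$x]
      }
      img <- img + stats::rnorm(H * W, 0, config$noise_sigma)
      frames[[f]] <- round(clamp(img, config$intensity_range[1],
                                 config$intensity_range[2]))
    }
    out <- list(volume = oct_volume(frames, label = class_label),
                class_label = class_label, binary = positive,
                lesion_mask = mask)
    class(out) <- "octex_synth_volume"
    out
  })
}

#' Layering statistic: periodicity contrast of depth profiles
#'
#' A fixed texture statistic that separates stratified (negative-class)
#' from de-stratified (lesional) tissue: for every sampled image column the
#' centered depth profile's autocorrelation is evaluated at the layering
#' period and at half the period, and their difference is averaged over
#' columns and frames. Stratified tissue scores high (the profile repeats
#' at the period and anti-repeats at half of it); de-stratified tissue
#' scores near zero.
#'
#' @param x an `octex_synth_volume`, an [oct_volume()], or a list of frame
#'   matrices. For a synthetic volume with a non-empty lesion mask the
#'   statistic is computed inside the mask.
#' @param lag layering period in pixels (defaults to the motif default).
#' @param col_step evaluate every `col_step`-th column.
#' @return Numeric scalar.
#' @export
layering_statistic <- function(x, lag = 12L, col_step = 2L) {
  mask <- NULL
  if (inherits(x, "octex_synth_volume")) {
    if (any(x$lesion_mask)) mask <- x$lesion_mask
    x <- x$volume
  }
  frames <- if (inherits(x, "octex_volume")) x$frames else x
  lag <- as.integer(lag)
  half <- max(1L, lag %/% 2L)
  vals <- numeric(0)
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    cols <- seq(1L, ncol(fr), by = col_step)
    if (!is.null(mask)) {
      cols <- cols[mask[f, cols]]
      if (length(cols) == 0) next
    }
    H <- nrow(fr)
    sub <- fr[, cols, drop = FALSE]
    sub <- sweep(sub, 2, colMeans(sub))
    denom <- colSums(sub^2)
    denom[denom == 0] <- 1
    ac <- function(L) {
      colSums(sub[1:(H - L), , drop = FALSE] *
                sub[(1 + L):H, , drop = FALSE]) / denom
    }
    vals <- c(vals, ac(lag) - ac(half))
  }
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

#' Generate a synthetic patient cohort
#'
#' Samples a class per patient from the mix, renders that patient's
#' volumes, and attaches the patient-level binary label (positive iff the
#' class is HSIL or CC). Deterministic for a fixed seed.
#'
#' @param n_patients number of patients (>= 1).
#' @param class_mix per-class proportions over `oct_classes()` (named or in
#'   vocabulary order); must sum to 1 within 1e-6.
#' @param volumes_per_patient volumes rendered per patient.
#' @param config an [synthetic_config()].
#' @param seed integer seed.
#' @return List of class `octex_cohort`: `patients` (each with
#'   `patient_id`, `class`, `binary`, `volumes` — a list of
#'   `octex_synth_volume`) and the `config`.
#' @export
generate_cohort <- function(n_patients, class_mix = rep(0.2, 5),
                            volumes_per_patient = 2L,
                            config = synthetic_config(), seed = 1L) {
  stopifnot(n_patients >= 1, volumes_per_patient >= 1)
  classes <- oct_classes()
  if (!is.null(names(class_mix))) class_mix <- class_mix[classes]
  stopifnot(length(class_mix) == length(classes), all(class_mix >= 0))
  if (abs(sum(class_mix) - 1) > 1e-6) {
    stop("class_mix proportions must sum to 1")
  }
  with_seed(seed, {
    pat_class <- sample(classes, n_patients, replace = TRUE,
                        prob = class_mix)
    vol_seeds <- matrix(sample.int(.Machine$integer.max,
                                   n_patients * volumes_per_patient),
                        n_patients, volumes_per_patient)
    patients <- vector("list", n_patients)
    for (i in seq_len(n_patients)) {
      pid <- sprintf("P%04d", i)
      vols <- vector("list", volumes_per_patient)
      for (v in seq_len(volumes_per_patient)) {
        sv <- generate_volume(pat_class[i], config, vol_seeds[i, v])
        sv$volume$patient_id <- pid
        sv$volume$position_tag <- sprintf("%02d:00", v)
        vols[[v]] <- sv
      }
      patients[[i]] <- list(patient_id = pid, class = pat_class[i],
                            binary = pat_class[i] %in% positive_classes(),
                            volumes = vols)
    }
    out <- list(patients = patients, config = config)
    class(out) <- "octex_cohort"
    out
  })
}

#' Cut a labeled patch dataset from a cohort
#'
#' Extracts sliding-window patches from every frame of every volume. Each
#' patch inherits its source volume's class, except that patches of a
#' lesional (HSIL/CC) volume whose window overlaps the lesion mask on less
#' than `purity_min_overlap` of its width are excluded: their content is
#' normal tissue and would poison the labels. Full provenance (patient,
#' volume, frame, window) is retained.
#'
#' @param cohort an `octex_cohort`.
#' @param window_size,stride sliding-window geometry (default: the
#'   cohort config's).
#' @param purity_min_overlap minimum fraction of a patch's width that the
#'   lesion mask must cover for the patch of a lesional volume to be kept.
#' @return List of class `octex_patch_dataset`: `patches` (list of square
#'   matrices), `meta` (data.frame with `patient_id`, `volume_id`, `frame`,
#'   `window_index`, `offset`, `class`, `binary`), `window_size`, `stride`.
#' @export
generate_patch_dataset <- function(cohort, window_size = NULL, stride = NULL,
                                   purity_min_overlap = 0.5) {
  stopifnot(inherits(cohort, "octex_cohort"))
  if (is.null(window_size)) window_size <- cohort$config$window_size
  if (is.null(stride)) stride <- cohort$config$stride
  patches <- list()
  meta <- list()
  for (pat in cohort$patients) {
    for (v in seq_along(pat$volumes)) {
      sv <- pat$volumes[[v]]
      vid <- sprintf("%s_V%02d", pat$patient_id, v)
      grid <- extract_patches(sv$volume, window_size, stride)
      keep_mask <- NULL
      if (any(sv$lesion_mask)) {
        keep_mask <- matrix(FALSE, length(sv$volume$frames),
                            length(grid$offsets))
        for (f in seq_len(nrow(keep_mask))) {
          for (w in seq_along(grid$offsets)) {
            xs <- grid$offsets[w] + seq_len(window_size)
            keep_mask[f, w] <-
              mean(sv$lesion_mask[f, xs]) >= purity_min_overlap
          }
        }
      }
      for (f in seq_along(sv$volume$frames)) {
        for (w in seq_along(grid$offsets)) {
          if (!is.null(keep_mask) && !keep_mask[f, w]) next
          patches[[length(patches) + 1L]] <- grid$patches[[f]][[w]]
          meta[[length(meta) + 1L]] <- data.frame(
            patient_id = pat$patient_id, volume_id = vid, frame = f,
            window_index = w, offset = grid$offsets[w],
            class = sv$class_label, binary = sv$binary,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- list(patches = patches,
              meta = if (length(meta)) do.call(rbind, meta) else
                data.frame(patient_id = character(), volume_id = character(),
                           frame = integer(), window_index = integer(),
                           offset = integer(), class = character(),
                           binary = logical()),
              window_size = as.integer(window_size),
              stride = as.integer(stride))
  class(out) <- "octex_patch_dataset"
  out
}

#' Write a cohort to disk
#'
#' Writes each volume as a multi-page 8-bit grayscale TIFF (and, for
#' lesional volumes, the mask as a single-page binary TIFF) plus a
#' `manifest.csv` with `patient_id`, `volume_path`, `mask_path`, `class`,
#' `binary_label`.
#'
#' @param cohort an `octex_cohort`.
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (pat in cohort$patients) {
    for (v in seq_along(pat$volumes)) {
      sv <- pat$volumes[[v]]
      vid <- sprintf("%s_V%02d", pat$patient_id, v)
      vpath <- file.path(dir, paste0(vid, ".tiff"))
      write_volume(sv$volume, vpath)
      mpath <- ""
      if (any(sv$lesion_mask)) {
        mpath <- file.path(dir, paste0(vid, "_mask.tiff"))
        tiff::writeTIFF(sv$lesion_mask * 1, mpath, bits.per.sample = 8L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pat$patient_id, volume_path = basename(vpath),
        mask_path = basename(mpath), class = sv$class_label,
        binary_label = as.integer(sv$binary), stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}
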