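# Multi-page TIFF volume input/output, sliding-window patch extraction,
# and the preprocessing / augmentation / oversampling pipeline.

#' Construct an OCT volume
#'
#' An ordered stack of equally sized 2-D grayscale frames plus subject
#' metadata; the unit of clinical diagnosis.
#'
#' @param frames list of numeric matrices on the 0..255 intensity scale,
#'   all of one size, in acquisition order.
#' @param patient_id,position_tag subject id and o'clock position tag.
#' @param label optional class label.
#' @return List of class `octex_volume`.
#' @export
oct_volume <- function(frames, patient_id = "", position_tag = "",
                       label = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1,
            all(vapply(frames, is.matrix, logical(1))))
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share one (height, width)")
  }
  out <- list(frames = frames, patient_id = patient_id,
              position_tag = position_tag, label = label)
  class(out) <- "octex_volume"
  out
}

#' Read / write a multi-page grayscale TIFF volume
#'
#' Volumes round-trip losslessly: `read_volume(write_volume(v))` returns
#' frames bit-identical to `v`, in page order.
#'
#' @param path TIFF file path.
#' @param volume an [oct_volume()] with integer intensities in 0..255.
#' @return `read_volume`: an `octex_volume` with frames on the 0..255
#'   scale. `write_volume`: the path, invisibly.
#' @export
read_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(seq_along(pages), function(i) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3L) {
      if (dim(pg)[3] == 1L) pg <- pg[, , 1]
      else stop("page ", i, " is not grayscale (",
                dim(pg)[3], " channels); unsupported photometric layout")
    }
    round(pg * 255)
  })
  oct_volume(frames)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "octex_volume"))
  tiff::writeTIFF(lapply(volume$frames, function(f) f / 255), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' Extract sliding-window patches from a volume
#'
#' Cuts one row of square windows per frame at x-offsets
#' `0, stride, 2 stride, ...`; the last window that fits is included. The
#' window count per frame is `floor((frame_width - window_size)/stride) + 1`.
#' Patches are exact frame crops of size `window_size x window_size`;
#' frames shorter than the window are rejected.
#'
#' @param volume an [oct_volume()].
#' @param window_size window side in pixels.
#' @param stride horizontal step in pixels.
#' @return List of class `octex_patch_grid_raw`: `patches` (list per frame
#'   of lists per window), `offsets` (0-based x-offsets), `window_size`,
#'   `stride`.
#' @export
extract_patches <- function(volume, window_size, stride) {
  stopifnot(inherits(volume, "octex_volume"), window_size >= 1, stride >= 1)
  H <- nrow(volume$frames[[1]])
  W <- ncol(volume$frames[[1]])
  if (window_size > W) stop("window_size exceeds frame width")
  if (window_size > H) stop("frames are shorter than the window")
  offsets <- seq.int(0L, W - window_size, by = stride)
  patches <- lapply(volume$frames, function(fr) {
    lapply(offsets, function(o) {
      fr[seq_len(window_size), (o + 1L):(o + window_size), drop = FALSE]
    })
  })
  out <- list(patches = patches, offsets = as.integer(offsets),
              window_size = as.integer(window_size),
              stride = as.integer(stride))
  class(out) <- "octex_patch_grid_raw"
  out
}

#' Preprocess a patch for the network
#'
#' Resizes to `target_size x target_size` (bilinear) and applies z-score
#' normalization `(x - mean)/sd`. The statistics are normally the training
#' split's global mean and standard deviation; with `stats = NULL` the
#' patch's own statistics are used (per-image mode).
#'
#' @param patch numeric matrix on the 0..255 scale.
#' @param target_size output side in pixels.
#' @param stats list with `mean` and `sd` (sd > 0), or `NULL`.
#' @return `target_size x target_size` numeric matrix.
#' @export
preprocess_patch <- function(patch, target_size = 224L, stats = NULL) {
  stopifnot(is.matrix(patch), length(patch) > 0)
  m <- resize_bilinear(patch, target_size)
  if (is.null(stats)) {
    stats <- list(mean = mean(m), sd = stats::sd(as.vector(m)))
    if (is.na(stats$sd) || stats$sd == 0) stats$sd <- 1
  }
  if (stats$sd <= 0) stop("z-score normalization needs sd > 0")
  (m - stats$mean) / stats$sd
}

resize_bilinear <- function(m, target_size) {
  if (nrow(m) == target_size && ncol(m) == target_size) return(m)
  out <- EBImage::resize(m, w = target_size, h = target_size)
  matrix(EBImage::imageData(out), target_size, target_size)
}

#' Augmentation configuration
#'
#' The stated training-time transforms only: random horizontal/vertical
#' flips, additive Gaussian noise, and multiplicative brightness jitter.
#'
#' @param p_hflip,p_vflip,p_noise,p_brightness per-transform probabilities.
#' @param noise_sd noise standard deviation as a fraction of the dynamic
#'   range (0..255).
#' @param brightness_range multiplicative jitter bounds.
#' @return List of class `octex_augment_config`.
#' @export
augment_config <- function(p_hflip = 0.5, p_vflip = 0.5, p_noise = 0.5,
                           p_brightness = 0.5, noise_sd = 0.02,
                           brightness_range = c(0.8, 1.2)) {
  probs <- c(p_hflip, p_vflip, p_noise, p_brightness)
  stopifnot(all(probs >= 0), all(probs <= 1), noise_sd >= 0)
  out <- list(p_hflip = p_hflip, p_vflip = p_vflip, p_noise = p_noise,
              p_brightness = p_brightness, noise_sd = noise_sd,
              brightness_range = brightness_range)
  class(out) <- "octex_augment_config"
  out
}

#' Randomly augment a patch
#'
#' Applies the configured transforms with their probabilities; intensities
#' are clamped back to 0..255. Seeded and reproducible.
#'
#' @param patch numeric matrix on the 0..255 scale.
#' @param config an [augment_config()].
#' @param seed optional integer seed; `NULL` draws from the current RNG
#'   stream.
#' @return Augmented matrix of the same size.
#' @export
augment_patch <- function(patch, config = augment_config(), seed = NULL) {
  run <- function() {
    if (stats::runif(1) < config$p_hflip) patch <- patch[, ncol(patch):1]
    if (stats::runif(1) < config$p_vflip) patch <- patch[nrow(patch):1, ]
    if (stats::runif(1) < config$p_brightness) {
      patch <- patch * stats::runif(1, config$brightness_range[1],
                                    config$brightness_range[2])
    }
    if (stats::runif(1) < config$p_noise) {
      patch <- patch + stats::rnorm(length(patch), 0,
                                    config$noise_sd * 255)
    }
    clamp(patch, 0, 255)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Weighted-oversampling weights against class imbalance
#'
#' Each patch gets weight `1 / (count of its class)`, so sampling with
#' replacement under these weights draws every class with equal expected
#' frequency.
#'
#' @param labels character or factor vector of patch labels.
#' @return Numeric weights, one per patch.
#' @export
oversampling_weights <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0) stop("empty label list")
  counts <- table(labels)
  as.numeric(1 / counts[labels])
}
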