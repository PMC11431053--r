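# Grad-CAM: gradient-weighted class activation maps per pyramid scale.

#' Grad-CAM heatmaps at the four scales
#'
#' For a target class, computes the gradient of the fused (pre-softmax)
#' class logit with respect to each backbone stage's output feature map,
#' averages the gradient spatially per channel to obtain channel weights,
#' and rectifies the weighted channel sum. Each heatmap is max-normalized
#' to \[0, 1\]; its size matches the scale (56/28/14/7 for a 224 input).
#'
#' @param model trained `octex_model`.
#' @param image normalized input image (matrix `target_size x target_size`),
#'   e.g. the output of [preprocess_patch()].
#' @param target_class class name or 1-based index.
#' @param scales which scales to compute (subset of active scales).
#' @return List of class `octex_cam`: `heatmaps` (one matrix per requested
#'   scale, values in \[0, 1\]) and `target_class`.
#' @export
grad_cam <- function(model, image, target_class,
                     scales = active_scales(model$config)) {
  stopifnot(inherits(model, "octex_model"), is.matrix(image))
  if (is.character(target_class)) {
    target_class <- match(target_class, model$config$classes)
  }
  stopifnot(!is.na(target_class), target_class >= 1,
            target_class <= model$config$n_classes)
  x <- array(image, c(dim(image), 1L, 1L))
  out <- model_forward(model, x, training = FALSE, keep_cache = TRUE)
  # d(fused logit_c)/d(scale logits) is one-hot on every active scale
  # because fusion is an element-wise sum
  dl <- matrix(0, 1, model$config$n_classes)
  dl[1, target_class] <- 1
  dlogits <- vector("list", 4L)
  for (s in active_scales(model$config)) dlogits[[s]] <- dl
  bk <- model_backward(out$model, out, dlogits, keep_stage_grads = TRUE)
  heatmaps <- vector("list", 4L)
  for (s in scales) {
    feat <- out$cache$pyramid[[s]] # (H, W, 1, C)
    grad <- bk$stage_grads[[s]]
    d <- dim(feat)
    wts <- apply(matrix(grad, d[1] * d[2], d[4]), 2, mean)
    fm <- matrix(feat, d[1] * d[2], d[4])
    cam <- matrix(pmax(fm %*% wts, 0), d[1], d[2])
    mx <- max(cam)
    heatmaps[[s]] <- if (mx > 0) cam / mx else cam
  }
  out <- list(heatmaps = heatmaps, target_class = target_class)
  class(out) <- "octex_cam"
  out
}

#' Overlay a heatmap on a grayscale image
#'
#' Upsamples the heatmap bilinearly to the image size, maps it through a
#' blue-to-red colormap and alpha-blends it over the image.
#'
#' @param image grayscale matrix (any intensity scale; rescaled to 0..1).
#' @param heatmap matrix of values in \[0, 1\].
#' @param alpha blending weight of the heatmap.
#' @return `H x W x 3` RGB array in \[0, 1\].
#' @export
overlay_heatmap <- function(image, heatmap, alpha = 0.4) {
  stopifnot(is.matrix(image), is.matrix(heatmap), alpha >= 0, alpha <= 1)
  rng <- range(image)
  g <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  hm <- EBImage::resize(heatmap, w = nrow(image), h = ncol(image))
  hm <- clamp(matrix(EBImage::imageData(hm), nrow(image), ncol(image)), 0, 1)
  ramp <- grDevices::colorRamp(c("#00007F", "#007FFF", "#7FFF7F",
                                 "#FF7F00", "#7F0000"))
  cols <- ramp(as.vector(hm)) / 255
  out <- array(0, c(nrow(image), ncol(image), 3))
  for (ch in 1:3) {
    out[, , ch] <- (1 - alpha) * g + alpha * matrix(cols[, ch], nrow(image))
  }
  clamp(out, 0, 1)
}

#' Write Grad-CAM overlays as PNG files
#'
#' @param model trained model.
#' @param patch raw patch matrix (0..255 scale).
#' @param target_class class name.
#' @param out_dir output directory.
#' @param alpha blending weight.
#' @return Character vector of written paths, invisibly.
#' @export
write_cam_pngs <- function(model, patch, target_class, out_dir,
                           alpha = 0.4) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ns <- model$norm_stats
  if (is.null(ns)) ns <- list(mean = mean(patch),
                              sd = max(stats::sd(as.vector(patch)), 1))
  S <- if (is.null(model$input_size)) 224L else model$input_size
  img <- (resize_bilinear(patch, S) - ns$mean) / ns$sd
  cam <- grad_cam(model, img, target_class)
  paths <- character(0)
  for (s in active_scales(model$config)) {
    ov <- overlay_heatmap(resize_bilinear(patch, S), cam$heatmaps[[s]],
                          alpha)
    p <- file.path(out_dir, sprintf("cam_scale%d_%s.png", s, target_class))
    png::writePNG(ov, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
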