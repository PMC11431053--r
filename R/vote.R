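#' Patch-level risk score and high-risk flag
#'
#' The binary risk score of a patch is the summed probability of the two
#' positive classes, `P(HSIL) + P(CC)`; a patch is flagged high-risk when
#' the score reaches the threshold (inclusive).
#'
#' @param prob named probability vector over the class vocabulary (must
#'   include `HSIL` and `CC`), summing to 1 within 1e-4.
#' @param tau high-risk threshold in (0, 1].
#' @return List with `score` and logical `high_risk`.
#' @export
patch_risk <- function(prob, tau = 0.8) {
  stopifnot(is.numeric(prob), !is.null(names(prob)),
            all(c("HSIL", "CC") %in% names(prob)),
            tau > 0, tau <= 1)
  if (abs(sum(prob) - 1) > 1e-4) {
    stop("probability vector does not sum to 1")
  }
  score <- unname(prob[["HSIL"]] + prob[["CC"]])
  list(score = score, high_risk = score >= tau)
}

#' Cross-shaped threshold voting over a volume's patch grid
#'
#' Lifts per-patch risk scores to a volume-level binary verdict. A patch
#' grid is indexed by (frame, window): windows are in-frame (cross-sectional)
#' neighbors, frames are cross-frame (axial) neighbors. The volume is called
#' positive when some high-risk patch has at least `arm_length` contiguous
#' high-risk neighbors on BOTH axes — at least one in-frame neighbor
#' (window +/- 1..arm_length within the same frame, on either side) and at
#' least one cross-frame neighbor (frame +/- 1..arm_length at the same
#' window). The high-risk pattern around such a center looks like a cross;
#' isolated high-risk patches never fire the rule.
#'
#' @param risk matrix of risk scores, rows = frames, cols = windows; or an
#'   `octex_patch_grid` from [predict_volume()].
#' @param tau high-risk threshold (score >= tau is high-risk).
#' @param arm_length minimum number of contiguous high-risk patches required
#'   in each of the two directions (counted on either side of the center).
#' @return List of class `octex_verdict`: `positive` (logical) and
#'   `cross_centers`, a two-column matrix of (frame, window) centers.
#' @export
vote_volume <- function(risk, tau = 0.8, arm_length = 1L) {
  if (inherits(risk, "octex_patch_grid")) risk <- risk$risk
  stopifnot(is.matrix(risk), length(risk) > 0, !anyNA(risk),
            tau > 0, tau <= 1, arm_length >= 1)
  arm_length <- as.integer(arm_length)
  hi <- risk >= tau
  nf <- nrow(hi); nw <- ncol(hi)

  # contiguous high-risk run length available on each side of every cell
  run <- function(m) { # per column of m: length of TRUE-run ending just above
    out <- m * 0L
    if (nrow(m) < 2) return(out)
    for (i in 2:nrow(m)) {
      out[i, ] <- ifelse(m[i - 1L, ], out[i - 1L, ] + 1L, 0L)
    }
    out
  }
  up    <- run(hi)
  down  <- run(hi[rev(seq_len(nf)), , drop = FALSE])[rev(seq_len(nf)), , drop = FALSE]
  left  <- t(run(t(hi)))
  right <- t(run(t(hi)[rev(seq_len(nw)), , drop = FALSE])[rev(seq_len(nw)), , drop = FALSE])

  axial <- pmax(up, down)        # cross-frame support
  inframe <- pmax(left, right)   # in-frame support
  centers <- hi & axial >= arm_length & inframe >= arm_length
  idx <- which(centers, arr.ind = TRUE)
  colnames(idx) <- c("frame", "window")
  out <- list(positive = nrow(idx) > 0, cross_centers = idx)
  class(out) <- "octex_verdict"
  out
}

#' Patient-level verdict
#'
#' A subject is positive if any of her OCT volumes is positive — the same
#' rule used in colposcopy-directed biopsy.
#'
#' @param volume_verdicts list of `octex_verdict` objects or logical vector.
#' @return Logical scalar.
#' @export
patient_verdict <- function(volume_verdicts) {
  stopifnot(length(volume_verdicts) > 0)
  if (is.list(volume_verdicts)) {
    volume_verdicts <- vapply(volume_verdicts, function(v) {
      if (inherits(v, "octex_verdict")) v$positive else as.logical(v)
    }, logical(1))
  }
  any(as.logical(volume_verdicts))
}
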