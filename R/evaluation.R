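#' Confusion counts from binary predictions
#'
#' Tallies true/false positives and negatives from logical (or 0/1) vectors
#' of predictions and ground truth at any level (patch, volume, patient).
#'
#' @param pred logical vector of predicted positives.
#' @param truth logical vector of true positives, same length.
#' @return An object of class `octex_confusion`: a list with integer fields
#'   `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as.logical(pred)
  truth <- as.logical(truth)
  stopifnot(length(pred) == length(truth), length(pred) > 0L,
            !anyNA(pred), !anyNA(truth))
  out <- list(
    TP = sum(pred & truth), FP = sum(pred & !truth),
    FN = sum(!pred & truth), TN = sum(!pred & !truth)
  )
  out <- lapply(out, as.integer)
  class(out) <- "octex_confusion"
  out
}

#' Diagnostic metrics from a confusion matrix
#'
#' Computes the six clinical classification metrics used to assess a binary
#' cervical-lesion screen: accuracy, sensitivity, specificity, positive and
#' negative predictive value, and the F1 score (harmonic mean of sensitivity
#' and PPV). A metric whose denominator is zero is reported as `NA`, never
#' coerced to 0 or 1.
#'
#' @param counts an `octex_confusion` object, or a list/vector with fields
#'   `TP`, `FP`, `FN`, `TN`.
#' @param conf.level if non-`NULL`, attach exact Clopper-Pearson confidence
#'   intervals at this level to every proportion metric (F1 gets no interval:
#'   it is not a binomial proportion, see [clopper_pearson()]).
#' @return A list of class `octex_metrics` with elements `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `f1` (proportions in
#'   \[0, 1\]), the `counts`, and — when `conf.level` is given — a `ci` list
#'   of `(lower, upper)` pairs.
#' @examples
#' m <- classification_metrics(list(TP = 42, FP = 10, FN = 9, TN = 44))
#' round(100 * m$sensitivity, 2) # 82.35
#' @export
classification_metrics <- function(counts, conf.level = NULL) {
  cnt <- lapply(counts[c("TP", "FP", "FN", "TN")], as.numeric)
  stopifnot(!anyNA(unlist(cnt)), all(unlist(cnt) >= 0))
  TP <- cnt$TP; FP <- cnt$FP; FN <- cnt$FN; TN <- cnt$TN
  n <- TP + FP + FN + TN
  stopifnot(n > 0)
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  m <- list(
    accuracy    = frac(TP + TN, n),
    sensitivity = frac(TP, TP + FN),
    specificity = frac(TN, TN + FP),
    ppv         = frac(TP, TP + FP),
    npv         = frac(TN, TN + FN)
  )
  m$f1 <- if (!is.na(m$sensitivity) && !is.na(m$ppv) &&
              (m$sensitivity + m$ppv) > 0) {
    2 * m$ppv * m$sensitivity / (m$ppv + m$sensitivity)
  } else NA_real_
  m$counts <- lapply(cnt, as.integer)
  if (!is.null(conf.level)) {
    alpha <- 1 - conf.level
    ks <- list(accuracy = c(TP + TN, n), sensitivity = c(TP, TP + FN),
               specificity = c(TN, TN + FP), ppv = c(TP, TP + FP),
               npv = c(TN, TN + FN))
    m$ci <- lapply(ks, function(kn) {
      if (kn[2] == 0) c(lower = NA_real_, upper = NA_real_)
      else clopper_pearson(kn[1], kn[2], alpha = alpha)
    })
  }
  class(m) <- "octex_metrics"
  m
}

#' @export
print.octex_metrics <- function(x, ...) {
  cat("Binary classification metrics (n =", sum(unlist(x$counts)), ")\n")
  for (nm in c("accuracy", "sensitivity", "specificity", "ppv", "npv", "f1")) {
    v <- x[[nm]]
    line <- sprintf("  %-12s %s", nm,
                    if (is.na(v)) "undefined" else sprintf("%6.2f%%", 100 * v))
    if (!is.null(x$ci) && nm %in% names(x$ci) && !anyNA(x$ci[[nm]])) {
      line <- paste0(line, sprintf("  (%.2f-%.2f%%)",
                                   100 * x$ci[[nm]][1], 100 * x$ci[[nm]][2]))
    }
    cat(line, "\n")
  }
  invisible(x)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' The exact two-sided interval for a binomial proportion, obtained from
#' beta-distribution quantiles: the same interval `binom.test()` reports.
#' The lower bound is 0 when `k = 0` and the upper bound is 1 when `k = n`.
#'
#' @param k number of successes (0..n).
#' @param n number of trials (>= 1).
#' @param alpha two-sided error rate; 0.05 gives a 95\% interval.
#' @return Named numeric `c(lower, upper)`.
#' @examples
#' round(100 * clopper_pearson(42, 51), 2) # 69.13 91.60
#' @export
clopper_pearson <- function(k, n, alpha = 0.05) {
  stopifnot(length(k) == 1, length(n) == 1, n >= 1, k >= 0, k <= n,
            k == round(k), n == round(n), alpha > 0, alpha < 1)
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Area under the ROC curve
#'
#' AUC computed as the normalized Mann-Whitney rank statistic
#' `U / (n1 * n2)`, with tied scores contributing one half. For the binary
#' high-risk task the score is the summed positive-class probability
#' `P(HSIL) + P(CC)` (see [patch_risk()]).
#'
#' @param scores numeric risk scores.
#' @param labels logical (or 0/1) true class, `TRUE` = positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("roc_auc requires both positive and negative labels")
  }
  r <- rank(scores) # midranks handle ties as half-wins
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mann-Whitney U test
#'
#' Nonparametric comparison of two independent groups. Reports the U
#' statistic for `x` (number of (x, y) pairs with `x > y`, ties counting
#' one half) and a two-sided p-value: exact by enumeration when both groups
#' have at most `exact_max` observations and there are no ties, otherwise
#' the tie-corrected normal approximation (continuity-corrected), as
#' provided by [stats::wilcox.test()].
#'
#' @param x,y numeric samples.
#' @param exact_max largest per-group size for which the exact null
#'   distribution is enumerated.
#' @return List with `U`, `p.value`, and `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  stopifnot(length(x) > 0, length(y) > 0, !anyNA(x), !anyNA(y))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided")
  )
  list(U = U, p.value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}
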