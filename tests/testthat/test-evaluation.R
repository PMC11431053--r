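test_that("confusion metrics match hand-computed proportions and identities", {
  m <- classification_metrics(list(TP = 42, FP = 10, FN = 9, TN = 44))
  expect_equal(round(100 * m$sensitivity, 2), 82.35)
  expect_equal(round(100 * m$specificity, 2), 81.48)
  expect_equal(round(100 * m$ppv, 2), 80.77)
  expect_equal(round(100 * m$npv, 2), 83.02)
  expect_equal(round(100 * m$f1, 2), 81.55)
  expect_equal(m$accuracy, 86 / 105)

  perfect <- classification_metrics(list(TP = 5, FP = 0, FN = 0, TN = 7))
  for (nm in c("accuracy", "sensitivity", "specificity", "ppv", "npv", "f1")) {
    expect_equal(perfect[[nm]], 1)
  }

  # identities on random counts, and agreement with a per-sample recount
  set.seed(11)
  for (i in 1:20) {
    truth <- runif(60) < 0.4
    pred <- xor(truth, runif(60) < 0.3)
    cc <- confusion_counts(pred, truth)
    m <- classification_metrics(cc)
    expect_equal(m$f1,
                 2 * m$ppv * m$sensitivity / (m$ppv + m$sensitivity),
                 tolerance = 1e-12)
    expect_equal(cc$TP, sum(pred & truth))
    expect_equal(m$accuracy, mean(pred == truth), tolerance = 1e-12)
  }
})

test_that("undefined metrics are reported as NA, never coerced", {
  m <- classification_metrics(list(TP = 0, FP = 0, FN = 0, TN = 10))
  expect_true(is.na(m$sensitivity)) # no positives in truth
  expect_true(is.na(m$ppv))         # no positive predictions
  expect_equal(m$specificity, 1)
})

test_that("Clopper-Pearson interval matches printed values and closed forms", {
  ci <- clopper_pearson(42, 51)
  expect_equal(round(100 * ci[["lower"]], 2), 69.13)
  expect_equal(round(100 * ci[["upper"]], 2), 91.60)

  ci0 <- clopper_pearson(0, 20)
  expect_equal(ci0[["lower"]], 0)
  expect_equal(ci0[["upper"]], 1 - 0.025^(1 / 20), tolerance = 1e-12)
  ci1 <- clopper_pearson(20, 20)
  expect_equal(ci1[["upper"]], 1)

  # brute-force tail inversion oracle on a p-grid
  set.seed(3)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    k <- sample(0:n, 1)
    ci <- clopper_pearson(k, n)
    ps <- seq(1e-4, 1 - 1e-4, by = 1e-4)
    inside <- vapply(ps, function(p) {
      stats::pbinom(k - 1, n, p, lower.tail = FALSE) >= 0.025 &&
        stats::pbinom(k, n, p) >= 0.025
    }, logical(1))
    expect_lt(abs(min(ps[inside]) - max(ci[["lower"]], 1e-4)), 2e-4)
    expect_lt(abs(max(ps[inside]) - min(ci[["upper"]], 1 - 1e-4)), 2e-4)
  }

  # matches binom.test
  bt <- stats::binom.test(17, 60)$conf.int
  expect_equal(unname(clopper_pearson(17, 60)), as.numeric(bt),
               tolerance = 1e-10)
})

test_that("AUC equals exhaustive pair counting and handles edge behavior", {
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.1)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  pairs <- 0
  for (i in which(labels)) {
    for (j in which(!labels)) {
      pairs <- pairs + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  expect_equal(roc_auc(scores, labels), pairs / (3 * 3))

  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T)), 1)
  set.seed(5)
  s <- runif(4000); l <- runif(4000) < 0.5
  expect_lt(abs(roc_auc(s, l) - 0.5), 0.03)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both")

  # identity with the rank-sum statistic on tied data
  s2 <- sample(1:5, 200, replace = TRUE)
  l2 <- runif(200) < 0.4
  U <- mann_whitney(s2[l2], s2[!l2])$U
  expect_equal(roc_auc(s2, l2), U / (sum(l2) * sum(!l2)), tolerance = 1e-12)

  # independent cross-check against pROC
  skip_if_not_installed("pROC")
  a <- as.numeric(pROC::auc(pROC::roc(l2, s2, quiet = TRUE,
                                      direction = "<")))
  expect_equal(roc_auc(s2, l2), a, tolerance = 1e-12)
})

test_that("Mann-Whitney U: exact enumerable case, ties, and power", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p.value, 2 / 6, tolerance = 1e-12)
  expect_equal(r$method, "exact")

  x <- c(1, 2, 2, 5)
  r2 <- mann_whitney(x, x)
  expect_equal(r2$U, length(x)^2 / 2)

  set.seed(7)
  r3 <- mann_whitney(rnorm(50, 2), rnorm(50, 0))
  expect_lt(r3$p.value, 0.01)
  expect_equal(r3$method, "normal approximation")
})
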