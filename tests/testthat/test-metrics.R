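make_counts <- function(n_pos, n_neg, fn, fp) {
  structure(list(n_pos = n_pos, n_neg = n_neg, fn = fn, fp = fp),
            class = "confusion_counts")
}

test_that("confusion counts labels vs calls", {
  ct <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unclass(ct), list(n_pos = 2L, n_neg = 2L, fn = 1L, fp = 1L))
  perfect <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$fn + perfect$fp, 0L)
  inverted <- confusion(c(1, 1, 0), c(0, 0, 1))
  expect_equal(inverted$fn, inverted$n_pos)
  expect_equal(inverted$fp, inverted$n_neg)
  expect_error(confusion(integer(0), integer(0)), "empty")
})

test_that("threshold metrics match the worked confusion example", {
  tm <- threshold_metrics(make_counts(10, 100, 2, 10))
  expect_equal(tm$sn, 0.8)
  expect_equal(tm$sp, 0.9)
  expect_equal(tm$acc, 98 / 110)
  expect_equal(tm$gmean, sqrt(0.72))
  expect_equal(tm$mcc, mcc_standard(10, 100, 2, 10), tolerance = 1e-12)

  perfect <- threshold_metrics(make_counts(5, 5, 0, 0))
  expect_equal(unlist(perfect), c(sn = 1, sp = 1, acc = 1, mcc = 1, gmean = 1))

  # all positives missed with no false positives: a zero column
  degen <- threshold_metrics(make_counts(4, 4, 4, 0))
  expect_equal(degen$sn, 0)
  expect_true(is.nan(degen$mcc))
})

test_that("ratio-form MCC equals the four-product MCC on random tables", {
  set.seed(19)
  n <- 2000  # heavier sweep lives in the acceptance suite
  for (i in seq_len(n)) {
    np <- sample(1:200, 1); nn <- sample(1:200, 1)
    fn <- sample(0:np, 1); fp <- sample(0:nn, 1)
    oracle <- mcc_standard(np, nn, fn, fp)
    if (is.nan(oracle)) next
    expect_equal(threshold_metrics(make_counts(np, nn, fn, fp))$mcc,
                 oracle, tolerance = 1e-12)
  }
})

test_that("the verbatim accuracy-numerator MCC variant diverges", {
  strict <- threshold_metrics(make_counts(10, 100, 2, 10),
                              strict_eq13 = TRUE)$mcc
  expect_equal(strict, (98 / 110) / sqrt(1.8 * 0.92), tolerance = 1e-12)
  expect_gt(abs(strict - mcc_standard(10, 100, 2, 10)), 0.1)
})

test_that("pairwise AUC follows the strict-inequality rule with opt-in ties", {
  expect_equal(auc_rank(0.9, 0.1), 1)
  expect_equal(auc_rank(0.5, 0.5), 0)                         # tie scores 0
  expect_equal(auc_rank(0.5, 0.5, tie_correction = TRUE), 0.5)
  expect_equal(auc_rank(c(0.8, 0.4), c(0.6, 0.2)), 3 / 4)
  expect_error(auc_rank(numeric(0), 1), "non-empty")
})

test_that("rank-based AUC equals full pairwise enumeration", {
  set.seed(29)
  for (rep in 1:50) {
    pos <- round(runif(sample(1:30, 1)), 2)  # rounding forces ties
    neg <- round(runif(sample(1:30, 1)), 2)
    expect_equal(auc_rank(pos, neg), auc_outer(pos, neg))
    expect_equal(auc_rank(pos, neg, tie_correction = TRUE),
                 auc_outer(pos, neg, tie_correction = TRUE))
  }
})

test_that("tie-corrected AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(37)
  labels <- rep(c(1, 0), each = 40)
  scores <- c(rnorm(40, 1), rnorm(40))
  ours <- auc_rank(scores[labels == 1], scores[labels == 0],
                   tie_correction = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("Acc decomposes as the class-weighted mean of Sn and Sp", {
  set.seed(53)
  for (rep in 1:30) {
    np <- sample(1:100, 1); nn <- sample(1:100, 1)
    tm <- threshold_metrics(make_counts(np, nn, sample(0:np, 1),
                                        sample(0:nn, 1)))
    expect_equal(tm$acc, (np * tm$sn + nn * tm$sp) / (np + nn))
  }
})

test_that("metrics are invariant under permutation of sample order", {
  set.seed(59)
  labels <- rbinom(60, 1, 0.4)
  labels[1:2] <- c(1, 0)
  scores <- runif(60)
  perm <- sample(60)
  r1 <- metrics_report(labels, scores)
  r2 <- metrics_report(labels[perm], scores[perm])
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("average_reports reproduces the published per-metric means", {
  rep1 <- metrics_report(c(1, 0), c(0.9, 0.1))
  expect_equal(as.data.frame(average_reports(list(rep1))),
               as.data.frame(rep1))  # single report is its own mean

  # three per-encoding reports at a fixed subset count -> printed means
  published <- list(
    c(0.7520, 0.7268, 0.7279, 0.2129, 0.8150, 0.7393),
    c(0.7228, 0.7124, 0.7128, 0.1906, 0.7963, 0.7176),
    c(0.7375, 0.7228, 0.7233, 0.2038, 0.8002, 0.7301))
  reports <- lapply(published, function(v) {
    metrics_from_values(sn = v[1], sp = v[2], acc = v[3], mcc = v[4],
                        auc = v[5], gmean = v[6])
  })
  avg <- average_reports(reports)
  expect_equal(round(avg$sn, 4), 0.7374)
  expect_equal(round(avg$sp, 4), 0.7207)
  expect_equal(round(avg$acc, 4), 0.7213)
  expect_equal(round(avg$mcc, 4), 0.2024)
  expect_equal(round(avg$auc, 4), 0.8038)
  expect_equal(round(avg$gmean, 4), 0.7290)
})

test_that("ROC coordinates step from (0,0) to (1,1) and integrate to AUC", {
  labels <- c(1L, 1L, 0L, 0L)
  scores <- c(0.9, 0.4, 0.6, 0.1)
  roc <- roc_points(labels, scores)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  # trapezoidal area equals the tie-corrected pairwise AUC
  area <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  expect_equal(area, auc_rank(scores[labels == 1], scores[labels == 0],
                              tie_correction = TRUE))
})

test_that("metrics serialize to JSON with full precision", {
  rep1 <- metrics_report(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  js <- jsonlite::fromJSON(metrics_to_json(rep1))
  expect_equal(js$Sn, rep1$sn)
  expect_equal(js$counts$n_pos, 2)
})
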