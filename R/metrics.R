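#' Confusion counts from labels and calls
#'
#' Counts are parameterized as the class sizes plus the two error
#' counts: `fn` (positives called negative) and `fp` (negatives called
#' positive), matching the error-rate form of the evaluation formulas.
#'
#' @param labels Binary 0/1 truth vector.
#' @param calls Binary 0/1 prediction vector of the same length.
#' @return An object of class `"confusion_counts"` with fields
#'   `n_pos`, `n_neg`, `fn`, `fp`.
#' @export
confusion <- function(labels, calls) {
  if (length(labels) == 0L) stop("empty input")
  stopifnot(length(labels) == length(calls),
            all(labels %in% c(0L, 1L)), all(calls %in% c(0L, 1L)))
  structure(
    list(n_pos = sum(labels == 1L), n_neg = sum(labels == 0L),
         fn = sum(labels == 1L & calls == 0L),
         fp = sum(labels == 0L & calls == 1L)),
    class = "confusion_counts"
  )
}

#' Threshold metrics: Sn, Sp, Acc, MCC, G-mean
#'
#' Sensitivity `Sn = 1 - fn/N+`, specificity `Sp = 1 - fp/N-`,
#' accuracy `Acc = 1 - (fn + fp)/(N+ + N-)` and
#' `G-mean = sqrt(Sn * Sp)`.
#'
#' MCC is computed in a ratio form with numerator
#' `1 - (fn/N+ + fp/N-)` and denominator
#' `sqrt((1 + (fp - fn)/N+) * (1 + (fn - fp)/N-))`, which is
#' algebraically identical to the standard four-product MCC. A
#' published variant of this formula carries numerator
#' `1 - (fn + fp)/(N+ + N-)` — the accuracy numerator — which is not a
#' valid MCC (it disagrees with the four-product form, e.g. 0.6924
#' vs 0.5440 on `N+ = 10, N- = 100, fn = 2, fp = 10`); that variant is
#' regarded as a typo but is reproducible verbatim via
#' `strict_eq13 = TRUE` for auditability. When a denominator factor is
#' zero MCC is reported as `NaN` with the remaining metrics intact.
#'
#' @param counts A [confusion()] result.
#' @param strict_eq13 Use the accuracy-style numerator variant
#'   (default `FALSE`).
#' @return A list with `sn`, `sp`, `acc`, `mcc`, `gmean`.
#' @export
threshold_metrics <- function(counts, strict_eq13 = FALSE) {
  stopifnot(inherits(counts, "confusion_counts"))
  np <- counts$n_pos; nn <- counts$n_neg
  fn <- counts$fn; fp <- counts$fp
  if (np == 0L || nn == 0L) stop("both classes must be present")
  sn <- 1 - fn / np
  sp <- 1 - fp / nn
  acc <- 1 - (fn + fp) / (np + nn)
  gmean <- sqrt(sn * sp)
  den <- (1 + (fp - fn) / np) * (1 + (fn - fp) / nn)
  num <- if (strict_eq13) acc else 1 - (fn / np + fp / nn)
  mcc <- if (den <= 0) NaN else num / sqrt(den)
  list(sn = sn, sp = sp, acc = acc, mcc = mcc, gmean = gmean)
}

#' Pairwise-rank AUC
#'
#' `AUC = sum_i sum_j u(f_i+, f_j-) / (N+ * N-)` where `u(a, b)` is 1
#' when `a > b` and 0 otherwise — so tied scores contribute 0 by
#' default. `tie_correction = TRUE` scores ties as 0.5, recovering the
#' conventional Mann-Whitney AUC. Computed via the rank-sum identity
#' with exact tie accounting (equivalent to full pairwise enumeration).
#'
#' @param scores_pos Scores of the positive samples.
#' @param scores_neg Scores of the negative samples.
#' @param tie_correction Score ties as 0.5 instead of 0.
#' @return The AUC in `[0, 1]`.
#' @examples
#' auc_rank(c(0.8, 0.4), c(0.6, 0.2))  # 3/4
#' @export
auc_rank <- function(scores_pos, scores_neg, tie_correction = FALSE) {
  if (length(scores_pos) == 0L || length(scores_neg) == 0L) {
    stop("both score vectors must be non-empty")
  }
  np <- length(scores_pos); nn <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg))
  u_half <- sum(r[seq_len(np)]) - np * (np + 1) / 2  # ties counted 0.5
  if (tie_correction) return(u_half / (np * nn))
  vals <- unique(scores_pos[scores_pos %in% scores_neg])
  tie_pairs <- sum(vapply(vals, function(v) {
    sum(scores_pos == v) * sum(scores_neg == v)
  }, numeric(1)))
  (u_half - tie_pairs / 2) / (np * nn)
}

#' Full evaluation report from scores
#'
#' Thresholds the positive-class scores (call = 1 when
#' `score >= threshold`), computes the confusion counts, the threshold
#' metrics and the pairwise-rank AUC.
#'
#' @param labels Binary 0/1 truth vector.
#' @param scores Positive-class scores in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @param strict_eq13,tie_correction See [threshold_metrics()] and
#'   [auc_rank()].
#' @return An object of class `"metrics_report"` with fields `sn`,
#'   `sp`, `acc`, `mcc`, `gmean`, `auc` and `counts`.
#' @export
metrics_report <- function(labels, scores, threshold = 0.5,
                           strict_eq13 = FALSE, tie_correction = FALSE) {
  stopifnot(length(labels) == length(scores))
  calls <- as.integer(scores >= threshold)
  counts <- confusion(labels, calls)
  tm <- threshold_metrics(counts, strict_eq13 = strict_eq13)
  auc <- auc_rank(scores[labels == 1L], scores[labels == 0L],
                  tie_correction = tie_correction)
  structure(c(tm, list(auc = auc, counts = counts)),
            class = "metrics_report")
}

# Assemble a metrics_report from already-computed metric values (used
# when averaging reports and when tabulating published values).
new_metrics_report <- function(sn, sp, acc, mcc, gmean, auc, counts = NULL) {
  structure(list(sn = sn, sp = sp, acc = acc, mcc = mcc, gmean = gmean,
                 auc = auc, counts = counts),
            class = "metrics_report")
}

#' Assemble a metrics report from known metric values
#'
#' Builds a `"metrics_report"` from externally obtained values (for
#' example a published results table), so they can be averaged or
#' tabulated alongside reports computed by [metrics_report()].
#'
#' @param sn,sp,acc,mcc,auc,gmean The metric values.
#' @return An object of class `"metrics_report"` with `NULL` counts.
#' @export
metrics_from_values <- function(sn, sp, acc, mcc, auc, gmean) {
  vals <- c(sn, sp, acc, auc, gmean)
  stopifnot(all(vals >= 0 & vals <= 1),
            is.nan(mcc) || (mcc >= -1 && mcc <= 1))  # NaN: undefined MCC
  new_metrics_report(sn = sn, sp = sp, acc = acc, mcc = mcc,
                     gmean = gmean, auc = auc)
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("<metrics_report>\n")
  print(round(as.data.frame(x), digits))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(Sn = x$sn, Sp = x$sp, Acc = x$acc, MCC = x$mcc,
             AUC = x$auc, `G-mean` = x$gmean, check.names = FALSE)
}

#' Average several evaluation reports
#'
#' Arithmetic mean of each metric across reports, e.g. across
#' cross-validation folds or across encodings at a fixed subset count.
#' Values are stored at full precision; the print method rounds to 4
#' decimals for display.
#'
#' @param reports List of [metrics_report()] objects (at least one).
#' @return A `"metrics_report"` whose metrics are the means; `counts`
#'   is `NULL` and the number of averaged reports is recorded in
#'   attribute `"n_reports"`.
#' @export
average_reports <- function(reports) {
  stopifnot(is.list(reports), length(reports) >= 1L,
            all(vapply(reports, inherits, logical(1), "metrics_report")))
  avg <- function(field) mean(vapply(reports, `[[`, numeric(1), field))
  out <- new_metrics_report(sn = avg("sn"), sp = avg("sp"), acc = avg("acc"),
                            mcc = avg("mcc"), gmean = avg("gmean"),
                            auc = avg("auc"))
  attr(out, "n_reports") <- length(reports)
  out
}

#' ROC curve coordinates
#'
#' (FPR, TPR) pairs at every distinct score threshold, from (0, 0) to
#' (1, 1), suitable for export or plotting with any graphics layer.
#'
#' @param labels Binary 0/1 truth vector.
#' @param scores Positive-class scores.
#' @return Data.frame with columns `threshold`, `fpr`, `tpr`; the
#'   leading row uses threshold `Inf`.
#' @export
roc_points <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), length(labels) > 0,
            all(labels %in% c(0L, 1L)))
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / np,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / nn,
                numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Serialize a metrics report to JSON
#'
#' @param report A [metrics_report()].
#' @return A JSON string with the metric fields (and confusion counts
#'   when present).
#' @export
metrics_to_json <- function(report) {
  stopifnot(inherits(report, "metrics_report"))
  obj <- list(Sn = report$sn, Sp = report$sp, Acc = report$acc,
              MCC = report$mcc, AUC = report$auc, `G-mean` = report$gmean)
  if (!is.null(report$counts)) obj$counts <- unclass(report$counts)
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "string")
}
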