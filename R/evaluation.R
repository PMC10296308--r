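# Evaluation: one-vs-rest confusion accounting, the four derived metrics,
# macro averages, ROC/AUC, stratified 70-15-15 splits and
# leave-one-subject-out folds.
#
# The per-class "accuracy" here uses the confusion-count denominator
# TN+FN+TP+FP exactly as the counts are given (counts or percentage
# proportions); this is nonstandard but is the convention the reference
# tables follow, and proportions and raw counts give identical metrics
# (scale invariance). Plain multiclass fraction-correct is exposed
# separately as overall_accuracy().

#' One-vs-rest confusion counts
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive_class the class treated as positive.
#' @param normalize divide counts by the total number of labels (yielding
#'   proportions; metrics are unchanged).
#' @return object of class \code{confusion_counts}: list with \code{tp, tn,
#'   fp, fn} and the class name.
#' @export
confusion_counts <- function(y_true, y_pred, positive_class, normalize = FALSE) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ (", length(y_true), " vs ",
         length(y_pred), ")")
  tp <- sum(y_true == positive_class & y_pred == positive_class)
  tn <- sum(y_true != positive_class & y_pred != positive_class)
  fp <- sum(y_true != positive_class & y_pred == positive_class)
  fn <- sum(y_true == positive_class & y_pred != positive_class)
  out <- list(tp = tp, tn = tn, fp = fp, fn = fn, class = positive_class)
  if (normalize) {
    n <- length(y_true)
    out[c("tp", "tn", "fp", "fn")] <- lapply(out[c("tp", "tn", "fp", "fn")],
                                             function(v) v / n)
  }
  structure(out, class = "confusion_counts")
}

#' Bundle confusion proportions directly
#'
#' For working with published confusion tables given as percentages.
#'
#' @param tp,tn,fp,fn non-negative counts or proportions.
#' @param class optional class name.
#' @return a \code{confusion_counts} object.
#' @export
confusion_from_counts <- function(tp, tn, fp, fn, class = NA_character_) {
  v <- c(tp, tn, fp, fn)
  if (any(v < 0) || !all(is.finite(v))) stop("counts must be finite and >= 0")
  if (sum(v) <= 0) stop("counts sum to zero")
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, class = class),
            class = "confusion_counts")
}

# round half away from zero to `digits` decimals (printed-table convention)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

metric_guard <- function(den, what) {
  if (den <= 0) stop("undefined metric: ", what, " denominator is zero")
}

#' Per-class accuracy from confusion counts
#'
#' \code{100 * (TN + TP) / (TN + FN + TP + FP)}, reported to 2 decimals.
#' Note this is the one-vs-rest variant over the supplied counts; use
#' \code{\link{overall_accuracy}} for plain multiclass fraction-correct.
#'
#' @param c a \code{confusion_counts}.
#' @param rounded round half away from zero to 2 decimals.
#' @return percentage.
#' @export
accuracy <- function(c, rounded = TRUE) {
  den <- c$tn + c$fn + c$tp + c$fp
  metric_guard(den, "accuracy")
  v <- 100 * (c$tn + c$tp) / den
  if (rounded) round_half_up(v) else v
}

#' Precision from confusion counts
#'
#' \code{100 * TP / (TP + FP)}.
#' @inheritParams accuracy
#' @return percentage.
#' @export
precision <- function(c, rounded = TRUE) {
  metric_guard(c$tp + c$fp, "precision")
  v <- 100 * c$tp / (c$tp + c$fp)
  if (rounded) round_half_up(v) else v
}

#' Recall from confusion counts
#'
#' \code{100 * TP / (TP + FN)}.
#' @inheritParams accuracy
#' @return percentage.
#' @export
recall <- function(c, rounded = TRUE) {
  metric_guard(c$tp + c$fn, "recall")
  v <- 100 * c$tp / (c$tp + c$fn)
  if (rounded) round_half_up(v) else v
}

#' F1 score from confusion counts
#'
#' Harmonic mean of precision and recall, computed from the unrounded values.
#' @inheritParams accuracy
#' @return percentage.
#' @export
f1 <- function(c, rounded = TRUE) {
  p <- precision(c, rounded = FALSE)
  r <- recall(c, rounded = FALSE)
  metric_guard(p + r, "f1")
  v <- 2 * p * r / (p + r)
  if (rounded) round_half_up(v) else v
}

#' Plain multiclass accuracy
#'
#' Fraction of correctly classified samples, in percent.
#' @param y_true,y_pred equal-length label vectors.
#' @return percentage (unrounded).
#' @export
overall_accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("label lengths differ")
  100 * mean(y_true == y_pred)
}

#' Unweighted macro average
#'
#' @param per_class numeric vector of per-class metric values.
#' @param rounded round half away from zero to 2 decimals.
#' @return the arithmetic mean.
#' @export
macro_average <- function(per_class, rounded = TRUE) {
  if (length(per_class) == 0) stop("no per-class values to average")
  v <- mean(per_class)
  if (rounded) round_half_up(v) else v
}

#' Full per-class metrics report
#'
#' One-vs-rest metrics for every class plus macro averages and (optionally)
#' one-vs-rest AUCs from a score matrix.
#'
#' @param y_true,y_pred label vectors.
#' @param scores optional samples x classes score matrix (column names =
#'   classes) for AUC.
#' @return object of class \code{metrics_report}: data.frame \code{per_class}
#'   (\code{class, accuracy, precision, recall, f1, auc}), list \code{macro}.
#' @export
metrics_report <- function(y_true, y_pred, scores = NULL) {
  classes <- sort(unique(as.character(y_true)))
  na_if_undefined <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  rows <- lapply(classes, function(cl) {
    cc <- confusion_counts(y_true, y_pred, cl)
    auc <- NA_real_
    if (!is.null(scores) && cl %in% colnames(scores) &&
        length(unique(y_true == cl)) == 2)
      auc <- roc_auc(scores[, cl], y_true == cl)$auc
    data.frame(class = cl,
               accuracy = na_if_undefined(accuracy(cc)),
               precision = na_if_undefined(precision(cc)),
               recall = na_if_undefined(recall(cc)),
               f1 = na_if_undefined(f1(cc)), auc = auc,
               stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  macro <- list(precision = macro_average(per_class$precision[!is.na(per_class$precision)]),
                recall = macro_average(per_class$recall[!is.na(per_class$recall)]),
                f1 = macro_average(per_class$f1[!is.na(per_class$f1)]))
  structure(list(per_class = per_class, macro = macro,
                 overall_accuracy = overall_accuracy(y_true, y_pred)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-class metrics (%):\n")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("Macro: precision %.2f, recall %.2f, F1 %.2f; overall accuracy %.2f%%\n",
              x$macro$precision, x$macro$recall, x$macro$f1,
              x$overall_accuracy))
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC via the rank (Mann-Whitney pair-counting) formulation, with ties
#' counted as half-concordant; the curve is the threshold-swept (FPR, TPR)
#' path.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels logical (or 0/1) true class membership; both classes must be
#'   present.
#' @return list with \code{auc} and a \code{curve} data.frame
#'   (\code{threshold, fpr, tpr}).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores/labels lengths differ")
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) stop("both classes must be present for ROC")
  r <- rank(scores)
  auc <- (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord]); fp <- cumsum(!labels[ord])
  thr <- scores[ord]
  keep <- c(diff(thr) != 0, TRUE)   # one point per distinct threshold
  curve <- data.frame(threshold = c(Inf, thr[keep]),
                      fpr = c(0, fp[keep] / nn),
                      tpr = c(0, tp[keep] / np))
  list(auc = auc, curve = curve)
}

#' Stratified 70-15-15 split
#'
#' Random split into train/validation/test with per-stratum proportions
#' matching the ratio within integer rounding (largest-remainder
#' allocation). Strata smaller than 3 produce a warning and a best-effort
#' allocation.
#'
#' @param items vector of item identifiers (or indices).
#' @param strata stratum label per item.
#' @param seed integer seed.
#' @param ratio length-3 proportions summing to 1.
#' @return list of class \code{split_plan} with index vectors \code{train},
#'   \code{val}, \code{test} (indices into \code{items}).
#' @export
split_70_15_15 <- function(items, strata = rep("all", length(items)), seed = 1L,
                           ratio = c(0.70, 0.15, 0.15)) {
  if (length(items) != length(strata)) stop("items/strata lengths differ")
  if (abs(sum(ratio) - 1) > 1e-8) stop("ratio must sum to 1")
  out <- list(train = integer(), val = integer(), test = integer())
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n <- length(idx)
    if (n < 3) warning("stratum '", s, "' has fewer than 3 items; ",
                       "best-effort allocation", call. = FALSE)
    idx <- with_seed(seed + utf8_sum(s), sample(idx))
    base <- floor(ratio * n)
    rem <- n - sum(base)
    if (rem > 0) {
      frac <- ratio * n - base
      add <- order(frac, decreasing = TRUE)[seq_len(rem)]
      base[add] <- base[add] + 1
    }
    cuts <- cumsum(base)
    out$train <- c(out$train, idx[seq_len(base[1])])
    if (base[2] > 0) out$val <- c(out$val, idx[(cuts[1] + 1):cuts[2]])
    if (base[3] > 0) out$test <- c(out$test, idx[(cuts[2] + 1):cuts[3]])
  }
  structure(c(out, list(strata = strata, n = length(items))),
            class = "split_plan")
}

utf8_sum <- function(s) sum(utf8ToInt(as.character(s))) %% 10000L

#' Leave-one-subject-out folds
#'
#' @param subjects vector of subject identifiers (>= 2 unique).
#' @return list of \code{list(train, test)}; each subject is the test
#'   subject exactly once.
#' @export
loso_folds <- function(subjects) {
  subjects <- unique(as.character(subjects))
  if (length(subjects) < 2) stop("need at least 2 subjects for LOSO")
  lapply(subjects, function(s) list(train = setdiff(subjects, s), test = s))
}

#' Write a metrics report to CSV and JSON
#'
#' @param report a \code{metrics_report}.
#' @param csv_path,json_path output paths (either may be NULL to skip).
#' @return (invisibly) the report.
#' @export
write_metrics <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    write.csv(report$per_class, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(per_class = report$per_class,
                              macro = report$macro,
                              overall_accuracy = report$overall_accuracy),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
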