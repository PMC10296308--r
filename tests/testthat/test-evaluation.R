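test_that("the reference confusion proportions reproduce the published metric table", {
  tab <- table_confusion()
  for (i in seq_len(nrow(tab))) {
    cc <- confusion_from_counts(tab$tp[i], tab$tn[i], tab$fp[i], tab$fn[i],
                                tab$class[i])
    expect_equal(accuracy(cc), tab$accuracy[i], tolerance = 0.011)
    expect_equal(precision(cc), tab$precision[i], tolerance = 0.011)
    expect_equal(recall(cc), tab$recall[i], tolerance = 0.011)
    expect_equal(f1(cc), tab$f1[i], tolerance = 0.011)
  }
  # the 16 one-vs-rest cells are proportions of the same test set: sum 100%
  expect_equal(sum(tab$tp, tab$tn, tab$fp, tab$fn), 100)
})

test_that("macro averages of the reference table match the published values", {
  tab <- table_confusion()
  ccs <- lapply(seq_len(nrow(tab)), function(i)
    confusion_from_counts(tab$tp[i], tab$tn[i], tab$fp[i], tab$fn[i]))
  ref <- reference_macro()
  expect_equal(macro_average(vapply(ccs, precision, numeric(1), rounded = FALSE)),
               ref[["precision"]], tolerance = 0.011)
  expect_equal(macro_average(vapply(ccs, recall, numeric(1), rounded = FALSE)),
               ref[["recall"]], tolerance = 0.011)
  expect_equal(macro_average(vapply(ccs, f1, numeric(1), rounded = FALSE)),
               ref[["f1"]], tolerance = 0.011)
  expect_equal(macro_average(c(7, 7, 7)), 7)
  expect_error(macro_average(numeric(0)), "no per-class")
})

test_that("confusion counting matches hand enumeration", {
  y_true <- c("A", "A", "A", "B", "B", "B", "B", "C", "C", "C")
  y_pred <- c("A", "A", "A", "A", "B", "B", "B", "C", "C", "B")
  cc <- confusion_counts(y_true, y_pred, "A")
  expect_equal(cc$tp, 3); expect_equal(cc$fp, 1)
  expect_equal(cc$fn, 0); expect_equal(cc$tn, 6)

  same <- confusion_counts(y_true, y_true, "B")
  expect_equal(same$fp, 0); expect_equal(same$fn, 0)

  norm <- confusion_counts(y_true, y_pred, "A", normalize = TRUE)
  expect_equal(norm$tp, 0.3)
  expect_error(confusion_counts(y_true, y_pred[-1], "A"), "lengths differ")
})

test_that("metrics are invariant to positive rescaling of counts", {
  cc <- confusion_from_counts(17.7, 1.6, 0.9, 1.3)
  for (s in c(0.01, 3, 1000)) {
    sc <- confusion_from_counts(17.7 * s, 1.6 * s, 0.9 * s, 1.3 * s)
    expect_equal(accuracy(sc, rounded = FALSE), accuracy(cc, rounded = FALSE))
    expect_equal(f1(sc, rounded = FALSE), f1(cc, rounded = FALSE))
  }
})

test_that("metric edge cases behave as documented", {
  expect_equal(accuracy(confusion_from_counts(5, 5, 0, 0)), 100)
  expect_equal(precision(confusion_from_counts(0, 1, 3, 0)), 0)
  expect_equal(recall(confusion_from_counts(4, 0, 0, 0)), 100)
  expect_error(precision(confusion_from_counts(0, 5, 0, 2)), "undefined")
  expect_error(recall(confusion_from_counts(0, 5, 2, 0)), "undefined")
  expect_error(confusion_from_counts(0, 0, 0, 0), "zero")
  expect_error(confusion_from_counts(-1, 1, 1, 1), ">= 0")

  # F1 equals P when P == R, never exceeds max(P, R)
  cc <- confusion_from_counts(10, 5, 2, 2)
  expect_equal(f1(cc), precision(cc))
  set.seed(2)
  for (i in 1:20) {
    v <- runif(4, 0.1, 30)
    cx <- confusion_from_counts(v[1], v[2], v[3], v[4])
    expect_lte(f1(cx, rounded = FALSE),
               max(precision(cx, rounded = FALSE), recall(cx, rounded = FALSE)) + 1e-9)
  }
})

test_that("AUC equals brute-force pair counting and is rank-invariant", {
  brute_auc <- function(scores, labels) {
    pos <- scores[labels]; neg <- scores[!labels]
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    mean(pairs)
  }
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T))$auc, 1)
  set.seed(14)
  for (i in 1:20) {
    n <- sample(6:15, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
    scores <- sample(round(rnorm(n), 1))   # ties likely
    expect_equal(roc_auc(scores, labels)$auc, brute_auc(scores, labels))
    # strictly monotone transform leaves AUC unchanged
    expect_equal(roc_auc(exp(2 * scores), labels)$auc,
                 roc_auc(scores, labels)$auc)
  }
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")

  # curve endpoints span (0,0) to (1,1)
  r <- roc_auc(rnorm(50), rep(c(TRUE, FALSE), 25))
  expect_equal(unlist(r$curve[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- rnorm(60)
  labels <- runif(60) < plogis(scores)
  if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
  ours <- roc_auc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("stratified split honours the 70-15-15 ratio per stratum", {
  plan <- split_70_15_15(1:100, rep("all", 100), seed = 4)
  expect_length(plan$train, 70)
  expect_length(plan$val, 15)
  expect_length(plan$test, 15)
  expect_setequal(c(plan$train, plan$val, plan$test), 1:100)

  plan2 <- split_70_15_15(1:100, rep("all", 100), seed = 4)
  expect_identical(plan, plan2)

  strata <- rep(c("g1", "g2", "g3"), each = 20)
  p3 <- split_70_15_15(1:60, strata, seed = 8)
  for (g in unique(strata)) {
    idx <- which(strata == g)
    expect_equal(sum(p3$train %in% idx), 14)
    expect_equal(sum(p3$val %in% idx), 3)
    expect_equal(sum(p3$test %in% idx), 3)
  }
  expect_warning(split_70_15_15(1:5, c("a", "a", "a", "b", "b"), seed = 1),
                 "fewer than 3")
})

test_that("LOSO folds cover every subject exactly once with disjoint sides", {
  subs <- c("s1", "s2", "s3", "s4", "s5")
  folds <- loso_folds(subs)
  expect_length(folds, 5)
  expect_setequal(vapply(folds, `[[`, character(1), "test"), subs)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), subs)
  }
  expect_error(loso_folds("only-one"), "at least 2")
})

test_that("metrics_report assembles per-class rows, macros and files", {
  set.seed(33)
  y <- sample(EMOTION_QUADRANTS, 80, replace = TRUE)
  pred <- ifelse(runif(80) < 0.7, y, sample(EMOTION_QUADRANTS, 80, replace = TRUE))
  scores <- matrix(runif(80 * 4), 80, 4, dimnames = list(NULL, EMOTION_QUADRANTS))
  rep_ <- metrics_report(y, pred, scores)
  expect_setequal(rep_$per_class$class, EMOTION_QUADRANTS)
  ok <- !is.na(rep_$per_class$precision)
  expect_true(all(rep_$per_class$accuracy >= 0 & rep_$per_class$accuracy <= 100))
  expect_equal(rep_$macro$precision,
               macro_average(rep_$per_class$precision[ok]))
  csvp <- withr::local_tempfile(fileext = ".csv")
  jsonp <- withr::local_tempfile(fileext = ".json")
  write_metrics(rep_, csvp, jsonp)
  expect_equal(nrow(read.csv(csvp)), 4)
  expect_equal(jsonlite::read_json(jsonp)$overall_accuracy,
               rep_$overall_accuracy)
})
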