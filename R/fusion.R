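# Fusion of the two branches and the final-stage classifier bank.
# The emotion-branch contribution (features or class scores) is concatenated
# with the five personality outputs, CNN part first, and fed to one of four
# classical classifiers; SVM hyperparameters are chosen by nested
# cross-validation (inner grid search strictly inside each outer training
# fold).

#' Fuse branch outputs
#'
#' Concatenates the emotion-branch vector(s) and the personality outputs,
#' CNN part first. Accepts vectors or row-aligned matrices.
#'
#' @param cnn_part numeric vector or matrix (samples x d1).
#' @param lstm_part numeric vector or matrix (samples x 5).
#' @return fused vector or matrix of width d1 + 5.
#' @export
fuse <- function(cnn_part, lstm_part) {
  if (is.matrix(cnn_part) || is.matrix(lstm_part)) {
    cnn_part <- as.matrix(cnn_part); lstm_part <- as.matrix(lstm_part)
    if (nrow(cnn_part) != nrow(lstm_part))
      stop("row counts differ: ", nrow(cnn_part), " vs ", nrow(lstm_part))
    out <- cbind(cnn_part, lstm_part)
  } else {
    out <- c(cnn_part, lstm_part)
  }
  if (!all(is.finite(out))) stop("fused vector contains non-finite entries")
  out
}

FINAL_CLASSIFIERS <- c("svm", "mlp", "knn", "bn")

default_svm_grid <- function(d) expand.grid(cost = c(1, 10, 100),
                                            gamma = c(0.3, 1, 3) / d)

stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- with_seed(seed + utf8_sum(cl), sample(idx))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

svm_grid_search <- function(x, y, grid, k, seed) {
  fold <- stratified_folds(y, k, seed)
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    accs <- vapply(seq_len(k), function(f) {
      tr <- fold != f; te <- fold == f
      if (length(unique(y[tr])) < 2 || !any(te)) return(NA_real_)
      m <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = grid$cost[g], gamma = grid$gamma[g], scale = TRUE)
      mean(predict(m, x[te, , drop = FALSE]) == y[te])
    }, numeric(1))
    acc <- mean(accs, na.rm = TRUE)
    if (is.null(best) || acc > best$acc)
      best <- list(acc = acc, cost = grid$cost[g], gamma = grid$gamma[g])
  }
  best
}

fit_classifier <- function(x, y, kind, seed, svm_par = NULL, inner_k = 3,
                           svm_grid = NULL, knn_k = 5) {
  # drop constant columns (dead ReLU units etc.); remember which for predict
  keep <- which(apply(x, 2, function(v) diff(range(v)) > 0))
  if (length(keep) == 0) stop("all feature columns are constant")
  x <- x[, keep, drop = FALSE]
  subset_cols <- function(newx) as.matrix(newx)[, keep, drop = FALSE]
  out <- switch(kind,
    svm = {
      if (is.null(svm_par))
        svm_par <- svm_grid_search(x, y, svm_grid, inner_k, seed)
      m <- e1071::svm(x, y, kernel = "radial", cost = svm_par$cost,
                      gamma = svm_par$gamma, scale = TRUE, probability = TRUE)
      list(fit = m, par = svm_par,
           predict = function(newx) as.character(predict(m, subset_cols(newx))))
    },
    mlp = {
      fit <- with_seed(seed, nnet::nnet(scale(x), class.ind(y), size = 16,
                                        decay = 1e-3, maxit = 200,
                                        softmax = TRUE, trace = FALSE,
                                        MaxNWts = 100000))
      lv <- levels(y)
      ctr <- attr(scale(x), "scaled:center"); scl <- attr(scale(x), "scaled:scale")
      list(fit = fit, par = list(size = 16, decay = 1e-3),
           predict = function(newx)
             lv[max.col(predict(fit, scale(subset_cols(newx), ctr, scl)))])
    },
    knn = {
      ctr <- colMeans(x); scl <- pmax(apply(x, 2, sd), 1e-12)
      xs <- scale(x, ctr, scl)
      list(fit = list(x = xs, y = y, k = knn_k), par = list(k = knn_k),
           predict = function(newx)
             as.character(class::knn(xs, scale(subset_cols(newx), ctr, scl),
                                     y, k = knn_k)))
    },
    bn = {
      fit <- e1071::naiveBayes(x, y)
      list(fit = fit, par = list(),
           predict = function(newx)
             as.character(predict(fit, subset_cols(newx))))
    },
    stop("unknown final classifier kind '", kind, "'"))
  out
}

class.ind <- function(y) {
  y <- as.factor(y)
  m <- diag(nlevels(y))[as.integer(y), , drop = FALSE]
  colnames(m) <- levels(y)
  m
}

#' Train the final-stage classifier with nested cross-validation
#'
#' Outer k-fold cross-validation produces held-out predictions for every
#' sample; for the SVM, cost and gamma are grid-searched by inner
#' cross-validation strictly inside each outer training fold (nested CV).
#' The other classifiers (MLP, kNN, naive Bayes) use fixed documented
#' defaults. A final model, tuned on all data, is also returned for
#' deployment on new samples.
#'
#' @param x numeric feature matrix (fused vectors), samples x dim.
#' @param y class labels (>= 2 classes).
#' @param kind one of \code{"svm"}, \code{"mlp"}, \code{"knn"}, \code{"bn"}.
#' @param outer_k,inner_k fold counts of the nested scheme.
#' @param seed integer seed for fold assignment and initialization.
#' @param svm_grid data.frame of \code{cost}, \code{gamma} candidates;
#'   default a small RBF grid with gamma scaled by 1/dim.
#' @param knn_k neighbours for kNN.
#' @return object of class \code{final_classifier}: held-out
#'   \code{predictions}, \code{fold} assignment, per-fold hyperparameters,
#'   outer-fold accuracies and the refit \code{final} model.
#' @export
train_final_classifier <- function(x, y, kind = "svm", outer_k = 5, inner_k = 3,
                                   seed = 1L, svm_grid = NULL, knn_k = 5) {
  x <- as.matrix(x)
  y <- factor(y)
  if (!kind %in% FINAL_CLASSIFIERS)
    stop("unknown final classifier kind '", kind, "'")
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (is.null(svm_grid))
    svm_grid <- default_svm_grid(ncol(x))
  fold <- stratified_folds(y, outer_k, seed)
  preds <- rep(NA_character_, length(y))
  fold_par <- vector("list", outer_k)
  fold_acc <- numeric(outer_k)
  for (f in seq_len(outer_k)) {
    tr <- fold != f; te <- fold == f
    m <- fit_classifier(x[tr, , drop = FALSE], droplevels(y[tr]), kind,
                        seed + f, inner_k = inner_k, svm_grid = svm_grid,
                        knn_k = knn_k)
    preds[te] <- m$predict(x[te, , drop = FALSE])
    fold_par[[f]] <- m$par
    fold_acc[f] <- mean(preds[te] == as.character(y[te]))
  }
  final <- fit_classifier(x, y, kind, seed, inner_k = inner_k,
                          svm_grid = svm_grid, knn_k = knn_k)
  structure(list(kind = kind, predictions = preds, fold = fold,
                 fold_params = fold_par, fold_accuracy = fold_acc,
                 accuracy = overall_accuracy(as.character(y), preds),
                 levels = levels(y), final = final),
            class = "final_classifier")
}

#' Fit a final-stage classifier on a fixed training set
#'
#' Like \code{\link{train_final_classifier}} but without the outer fold loop:
#' hyperparameters are still selected by inner cross-validation on the
#' training data only, and the fitted model is applied to held-out data via
#' \code{predict}. This is the path the pipeline uses with an explicit
#' train/validation/test split.
#'
#' @inheritParams train_final_classifier
#' @return a \code{final_classifier} (without outer-fold predictions).
#' @export
fit_final_classifier <- function(x, y, kind = "svm", inner_k = 3, seed = 1L,
                                 svm_grid = NULL, knn_k = 5) {
  x <- as.matrix(x)
  y <- factor(y)
  if (!kind %in% FINAL_CLASSIFIERS)
    stop("unknown final classifier kind '", kind, "'")
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (is.null(svm_grid)) svm_grid <- default_svm_grid(ncol(x))
  final <- fit_classifier(x, y, kind, seed, inner_k = inner_k,
                          svm_grid = svm_grid, knn_k = knn_k)
  structure(list(kind = kind, predictions = NULL, fold = NULL,
                 fold_params = list(final$par), fold_accuracy = numeric(),
                 accuracy = NA_real_, levels = levels(y), final = final),
            class = "final_classifier")
}

#' @export
predict.final_classifier <- function(object, newx, ...) {
  object$final$predict(as.matrix(newx))
}

#' @export
print.final_classifier <- function(x, ...) {
  cat(sprintf("<final_classifier> %s, %d-fold nested CV accuracy %.2f%%\n",
              x$kind, length(x$fold_accuracy), x$accuracy))
  invisible(x)
}
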