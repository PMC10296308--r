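# Personality branch: a stacked LSTM over window-feature sequences with a
# five-unit sigmoid dense output, trained with Adam on mean squared error
# against unit-scaled Big Five trait targets. Written directly on matrix
# primitives: forward pass, full backpropagation through time, gradient-norm
# clipping.

sigmoid <- function(x) 1 / (1 + exp(-x))

act_fun <- function(name) {
  switch(name,
    relu = list(f = function(x) pmax(x, 0), df = function(x, fx) (x > 0) * 1),
    sigmoid = list(f = sigmoid, df = function(x, fx) fx * (1 - fx)),
    tanh = list(f = tanh, df = function(x, fx) 1 - fx^2),
    stop("unknown activation '", name, "'"))
}

#' Build the stacked LSTM personality model
#'
#' Three LSTM layers by default (64, 32, 16 units; relu, relu, sigmoid cell
#' activations) followed by a dense layer emitting five sigmoid trait values
#' in (0, 1).
#'
#' @param cfg a \code{\link{model_config}}.
#' @param input_dim dimension of the per-step feature vectors.
#' @return object of class \code{lstm_model} with seeded initial weights.
#' @export
build_lstm <- function(cfg = model_config(), input_dim) {
  widths <- cfg$lstm_layers
  acts <- cfg$lstm_activations
  layers <- with_seed(cfg$seed, {
    din <- input_dim
    lapply(seq_along(widths), function(l) {
      n <- widths[l]
      sdw <- 1 / sqrt(din + n)
      W <- matrix(rnorm(4 * n * (din + n), sd = sdw), 4 * n, din + n)
      b <- rep(0, 4 * n)
      b[(n + 1):(2 * n)] <- 1          # forget-gate bias
      din <<- n
      list(W = W, b = b, n = n, act = acts[l])
    })
  })
  n_last <- widths[length(widths)]
  dense <- with_seed(cfg$seed + 1L, list(
    V = matrix(rnorm(cfg$traits_dim * n_last, sd = 1 / sqrt(n_last)),
               cfg$traits_dim, n_last),
    c = rep(0, cfg$traits_dim)))
  structure(list(layers = layers, dense = dense, input_dim = input_dim,
                 widths = widths, activations = acts,
                 traits_dim = cfg$traits_dim, cfg = cfg,
                 x_mu = rep(0, input_dim), x_sd = rep(1, input_dim)),
            class = "lstm_model")
}

#' @export
print.lstm_model <- function(x, ...) {
  cat(sprintf("<lstm_model> input %d -> LSTM [%s] (%s) -> dense %d (sigmoid)\n",
              x$input_dim, paste(x$widths, collapse = ", "),
              paste(x$activations, collapse = ", "), x$traits_dim))
  invisible(x)
}

# Forward pass over one sequence (T x input_dim). Returns caches for BPTT.
lstm_forward <- function(model, X, keep_cache = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("empty sequence at inference")
  X <- sweep(sweep(X, 2, model$x_mu), 2, model$x_sd, `/`)
  Tlen <- nrow(X)
  caches <- vector("list", length(model$layers))
  inp <- X
  for (l in seq_along(model$layers)) {
    ly <- model$layers[[l]]
    n <- ly$n
    af <- act_fun(ly$act)
    H <- matrix(0, Tlen, n); Cc <- matrix(0, Tlen, n)
    gi <- matrix(0, Tlen, n); gf <- matrix(0, Tlen, n)
    go <- matrix(0, Tlen, n); gg <- matrix(0, Tlen, n)
    ag <- matrix(0, Tlen, n)  # pre-activation of candidate
    hc <- matrix(0, Tlen, n)  # act(c_t)
    h_prev <- rep(0, n); c_prev <- rep(0, n)
    for (t in seq_len(Tlen)) {
      a <- as.numeric(ly$W %*% c(inp[t, ], h_prev) + ly$b)
      ai <- a[1:n]; afo <- a[(n + 1):(2 * n)]
      ao <- a[(2 * n + 1):(3 * n)]; ac <- a[(3 * n + 1):(4 * n)]
      i_t <- sigmoid(ai); f_t <- sigmoid(afo); o_t <- sigmoid(ao)
      g_t <- af$f(ac)
      c_t <- f_t * c_prev + i_t * g_t
      hc_t <- af$f(c_t)
      h_t <- o_t * hc_t
      gi[t, ] <- i_t; gf[t, ] <- f_t; go[t, ] <- o_t; gg[t, ] <- g_t
      ag[t, ] <- ac; hc[t, ] <- hc_t
      Cc[t, ] <- c_t; H[t, ] <- h_t
      h_prev <- h_t; c_prev <- c_t
    }
    caches[[l]] <- list(inp = inp, H = H, C = Cc, i = gi, f = gf, o = go,
                        g = gg, ag = ag, hc = hc)
    inp <- H
  }
  h_last <- inp[Tlen, ]
  z <- as.numeric(model$dense$V %*% h_last + model$dense$c)
  y <- sigmoid(z)
  out <- list(y = y, z = z, h_last = h_last)
  if (keep_cache) out$caches <- caches
  out
}

#' Predict Big Five outputs for feature sequences
#'
#' @param object an \code{lstm_model}.
#' @param sequences a single T x d matrix or a list of them.
#' @param ... unused.
#' @return matrix of sigmoid outputs in (0, 1), one row per sequence.
#' @export
predict.lstm_model <- function(object, sequences, ...) {
  if (is.matrix(sequences)) sequences <- list(sequences)
  out <- t(vapply(sequences, function(X) lstm_forward(object, X)$y,
                  numeric(object$traits_dim)))
  colnames(out) <- TRAIT_NAMES[seq_len(object$traits_dim)]
  out
}

# BPTT for one sequence. dy: gradient of loss w.r.t. sigmoid output y.
lstm_backward <- function(model, fw, dy) {
  caches <- fw$caches
  Tlen <- nrow(caches[[1]]$H)
  L <- length(model$layers)
  grads <- list(layers = vector("list", L))

  dz <- dy * fw$y * (1 - fw$y)
  grads$dense <- list(V = outer(dz, fw$h_last), c = dz)
  dH_top <- matrix(0, Tlen, model$layers[[L]]$n)
  dH_top[Tlen, ] <- as.numeric(t(model$dense$V) %*% dz)

  dH_next_layer <- dH_top
  for (l in L:1) {
    ly <- model$layers[[l]]
    ca <- caches[[l]]
    n <- ly$n
    af <- act_fun(ly$act)
    din <- ncol(ca$inp)
    dW <- matrix(0, 4 * n, din + n); db <- rep(0, 4 * n)
    dInp <- matrix(0, Tlen, din)
    dh_rec <- rep(0, n); dc_next <- rep(0, n)
    for (t in Tlen:1) {
      dh <- dH_next_layer[t, ] + dh_rec
      o_t <- ca$o[t, ]; hc_t <- ca$hc[t, ]; c_t <- ca$C[t, ]
      i_t <- ca$i[t, ]; f_t <- ca$f[t, ]; g_t <- ca$g[t, ]
      do_ <- dh * hc_t
      dc <- dc_next + dh * o_t * af$df(c_t, hc_t)
      c_prev <- if (t > 1) ca$C[t - 1, ] else rep(0, n)
      df_ <- dc * c_prev
      di_ <- dc * g_t
      dg_ <- dc * i_t
      dc_next <- dc * f_t
      da <- c(di_ * i_t * (1 - i_t),
              df_ * f_t * (1 - f_t),
              do_ * o_t * (1 - o_t),
              dg_ * af$df(ca$ag[t, ], g_t))
      h_prev <- if (t > 1) ca$H[t - 1, ] else rep(0, n)
      xh <- c(ca$inp[t, ], h_prev)
      dW <- dW + outer(da, xh)
      db <- db + da
      dxh <- as.numeric(t(ly$W) %*% da)
      dInp[t, ] <- dxh[1:din]
      dh_rec <- dxh[(din + 1):(din + n)]
    }
    grads$layers[[l]] <- list(W = dW, b = db)
    dH_next_layer <- dInp
  }
  grads
}

clip_by_norm <- function(grads, max_norm = 5) {
  flat <- c(unlist(lapply(grads$layers, function(g) c(g$W, g$b))),
            grads$dense$V, grads$dense$c)
  nrm <- sqrt(sum(flat^2))
  if (is.finite(nrm) && nrm > max_norm) {
    s <- max_norm / nrm
    grads$layers <- lapply(grads$layers, function(g)
      list(W = g$W * s, b = g$b * s))
    grads$dense <- list(V = grads$dense$V * s, c = grads$dense$c * s)
  }
  grads
}

#' Train the personality LSTM
#'
#' Minimizes mean squared error between sigmoid outputs and unit-scaled trait
#' targets with Adam and full backpropagation through time. Optionally runs
#' leave-one-subject-out cross-validation, retaining per-fold held-out
#' predictions.
#'
#' @param sequences list of entries \code{list(x = T x d matrix,
#'   subject = id)} (see \code{\link{make_sequences}}).
#' @param traits named list of \code{\link{personality_profile}} (or a
#'   subjects x 5 matrix with rownames) on the questionnaire scale; targets
#'   are scaled to [0, 1] internally.
#' @param cfg a \code{\link{model_config}}.
#' @param loso run leave-one-subject-out cross-validation.
#' @param scale_bounds questionnaire scale for target scaling.
#' @param clip gradient-norm clip.
#' @return For \code{loso = FALSE}: list with the trained \code{model} and a
#'   per-epoch \code{history}. For \code{loso = TRUE}: additionally
#'   \code{folds} (per-subject held-out predictions and MSE) and
#'   \code{predictions} (subjects x traits, each row predicted by the fold
#'   that held that subject out).
#' @export
train_personality_lstm <- function(sequences, traits, cfg = model_config(),
                                   loso = FALSE, scale_bounds = c(1, 5),
                                   clip = 5) {
  if (length(sequences) == 0) stop("no sequences to train on")
  subj <- vapply(sequences, function(s) as.character(s$subject), character(1))
  tr_mat <- traits_matrix(traits)
  missing_subj <- setdiff(unique(subj), rownames(tr_mat))
  if (length(missing_subj) > 0)
    stop("traits missing for subject(s): ", paste(missing_subj, collapse = ", "))
  targets <- scale_traits_unit(tr_mat, scale_bounds)

  if (!loso) {
    return(train_lstm_once(sequences, subj, targets, cfg, clip))
  }
  subjects <- sort(unique(subj))
  folds <- loso_folds(subjects)
  preds <- matrix(NA_real_, length(subjects), ncol(targets),
                  dimnames = list(subjects, colnames(targets)))
  fold_out <- vector("list", length(folds))
  for (k in seq_along(folds)) {
    te <- folds[[k]]$test
    tr_seq <- sequences[subj != te]
    fit <- train_lstm_once(tr_seq, subj[subj != te], targets, cfg, clip)
    te_seq <- sequences[subj == te]
    p <- predict(fit$model, lapply(te_seq, `[[`, "x"))
    p_subj <- colMeans(p)
    preds[te, ] <- p_subj
    mse <- mean((p_subj - targets[te, ])^2)
    fold_out[[k]] <- list(test = te, prediction = p_subj,
                          target = targets[te, ], mse = mse)
  }
  list(folds = fold_out, predictions = preds, targets = targets)
}

traits_matrix <- function(traits) {
  if (is.matrix(traits)) {
    if (is.null(rownames(traits))) stop("traits matrix needs subject rownames")
    return(traits[, TRAIT_NAMES, drop = FALSE])
  }
  m <- do.call(rbind, lapply(traits, unclass))
  rownames(m) <- names(traits)
  m[, TRAIT_NAMES, drop = FALSE]
}

train_lstm_once <- function(sequences, subj, targets, cfg, clip = 5) {
  Xs <- lapply(sequences, `[[`, "x")
  d <- ncol(Xs[[1]])
  model <- build_lstm(cfg, input_dim = d)
  allX <- do.call(rbind, Xs)
  model$x_mu <- colMeans(allX)
  model$x_sd <- pmax(apply(allX, 2, sd), 1e-8)

  Y <- targets[subj, , drop = FALSE]
  n_seq <- length(sequences)
  shapes_l <- lapply(model$layers, function(ly) list(W = dim(ly$W), b = length(ly$b)))
  stL <- lapply(shapes_l, function(s) list(W = adam_state(list(s$W))[[1]],
                                           b = adam_state(list(s$b))[[1]]))
  stV <- adam_state(list(dim(model$dense$V)))[[1]]
  stc <- adam_state(list(length(model$dense$c)))[[1]]

  bs <- min(cfg$batch_size, n_seq)
  t_adam <- 0
  history <- data.frame()
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(cfg$seed + 1000L + ep, sample(n_seq))
    ep_loss <- 0; n_b <- 0
    for (start in seq(1, n_seq, by = bs)) {
      bi <- ord[start:min(start + bs - 1L, n_seq)]
      acc <- NULL
      b_loss <- 0
      for (j in bi) {
        fw <- lstm_forward(model, Xs[[j]], keep_cache = TRUE)
        err <- fw$y - Y[j, ]
        b_loss <- b_loss + mean(err^2)
        dy <- 2 * err / (length(err) * length(bi))
        g <- lstm_backward(model, fw, dy)
        if (is.null(acc)) acc <- g
        else {
          for (l in seq_along(acc$layers)) {
            acc$layers[[l]]$W <- acc$layers[[l]]$W + g$layers[[l]]$W
            acc$layers[[l]]$b <- acc$layers[[l]]$b + g$layers[[l]]$b
          }
          acc$dense$V <- acc$dense$V + g$dense$V
          acc$dense$c <- acc$dense$c + g$dense$c
        }
      }
      acc <- clip_by_norm(acc, clip)
      t_adam <- t_adam + 1
      for (l in seq_along(model$layers)) {
        up <- adam_update(model$layers[[l]]$W, acc$layers[[l]]$W, stL[[l]]$W,
                          cfg$learning_rate, t_adam)
        model$layers[[l]]$W <- up$par; stL[[l]]$W <- up$state
        up <- adam_update(model$layers[[l]]$b, acc$layers[[l]]$b, stL[[l]]$b,
                          cfg$learning_rate, t_adam)
        model$layers[[l]]$b <- as.numeric(up$par); stL[[l]]$b <- up$state
      }
      up <- adam_update(model$dense$V, acc$dense$V, stV, cfg$learning_rate, t_adam)
      model$dense$V <- up$par; stV <- up$state
      up <- adam_update(model$dense$c, acc$dense$c, stc, cfg$learning_rate, t_adam)
      model$dense$c <- as.numeric(up$par); stc <- up$state
      ep_loss <- ep_loss + b_loss / length(bi); n_b <- n_b + 1
    }
    history <- rbind(history, data.frame(epoch = ep, split = "train",
                                         loss = ep_loss / n_b, accuracy = NA_real_))
  }
  list(model = model, history = history)
}

#' Group window features into per-block training sequences
#'
#' For every subject and stimulus-category block, the time-ordered series of
#' window feature vectors forms one sequence (the order of the input rows is
#' irrelevant; ordering by window start is internal). A stride subsamples
#' long sequences (stride 4 with 1-second hops keeps one step per 4 s).
#'
#' @param features numeric matrix, windows x feature dim.
#' @param meta data.frame with one row per window: \code{subject_id},
#'   \code{category}, \code{start_sample} (see \code{\link{window_metadata}}).
#' @param stride keep every \code{stride}-th window of each block.
#' @return list of \code{list(x, subject, category)}.
#' @export
make_sequences <- function(features, meta, stride = 1L) {
  stopifnot(nrow(features) == nrow(meta))
  keep <- !is.na(meta$category)
  features <- features[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  out <- list()
  for (s in unique(meta$subject_id)) {
    rows_s <- which(meta$subject_id == s)
    if (length(rows_s) == 0) next
    for (cat in unique(meta$category[rows_s])) {
      rows <- rows_s[meta$category[rows_s] == cat]
      rows <- rows[order(meta$start_sample[rows])]
      rows <- rows[seq(1, length(rows), by = stride)]
      out[[length(out) + 1]] <- list(x = features[rows, , drop = FALSE],
                                     subject = s, category = cat)
    }
  }
  if (length(out) == 0) warning("no labeled windows; no sequences produced")
  out
}

#' Window metadata table
#'
#' @param windows list of \code{eeg_window} objects.
#' @return data.frame with \code{subject_id, group, category, modality,
#'   start_sample, emotion_label} per window (NA where unlabeled).
#' @export
window_metadata <- function(windows) {
  do.call(rbind, lapply(windows, function(w) data.frame(
    subject_id = w$subject_id,
    group = if (is.null(w$group)) NA_character_ else w$group,
    category = if (is.null(w$stimulus)) NA_character_ else w$stimulus$category,
    modality = if (is.null(w$stimulus)) NA_character_ else w$stimulus$modality,
    start_sample = w$start_sample,
    emotion_label = w$emotion_label,
    stringsAsFactors = FALSE)))
}
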