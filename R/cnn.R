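# Convolutional emotion branch. Two backbones:
#  - "vgg16": the 13-conv / 3-dense reference architecture (3x3 kernels,
#    max-pooling between stages). Built as an architecture description;
#    weights are materialized on request only, and pretrained weights are an
#    explicit configuration error (nothing is ever downloaded).
#  - "small_cnn": a 4-block reduced analogue (3x3 conv + ReLU + 2x2 pool)
#    sized for desk-scale experiments; always materialized.
# The emotion head is a softmax classifier over flattened features of the
# last convolutional stage, trained with Adam on cross-entropy.

VGG16_CONV_WIDTHS <- list(c(64, 64), c(128, 128), c(256, 256, 256),
                          c(512, 512, 512), c(512, 512, 512))
VGG16_DENSE_WIDTHS <- c(4096, 4096, 4)

#' Model configuration
#'
#' Hyperparameters of the network branches and training protocol. Defaults
#' follow the reference training recipe (Adam, learning rate 0.001, batch 64,
#' 500 epochs, three LSTM layers of 64/32/16 units with relu/relu/sigmoid
#' activations, five-trait sigmoid output, MSE loss for the personality
#' branch).
#'
#' @param backbone \code{"small_cnn"} or \code{"vgg16"}.
#' @param pretrained request pretrained backbone weights. No weights ship
#'   with the package and none are downloaded, so \code{TRUE} is an error
#'   unless a weight file is supplied to \code{\link{build_cnn}}.
#' @param input_shape image input, \code{c(height, width, channels)}.
#' @param lstm_layers integer widths of the stacked LSTM layers.
#' @param lstm_activations activation per LSTM layer (\code{"relu"},
#'   \code{"sigmoid"} or \code{"tanh"}).
#' @param traits_dim number of personality outputs (5).
#' @param learning_rate,batch_size,epochs Adam training protocol.
#' @param seed integer seed for weight initialization and batching.
#' @return list of class \code{model_config}.
#' @export
model_config <- function(backbone = "small_cnn", pretrained = FALSE,
                         input_shape = c(32, 32, 1),
                         lstm_layers = c(64, 32, 16),
                         lstm_activations = c("relu", "relu", "sigmoid"),
                         traits_dim = 5L, learning_rate = 0.001,
                         batch_size = 64L, epochs = 500L, seed = 1L) {
  if (length(lstm_layers) != length(lstm_activations))
    stop("lstm_layers and lstm_activations must have equal length")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (traits_dim != 5L) stop("traits_dim must be 5 (Big Five)")
  structure(list(backbone = backbone, pretrained = pretrained,
                 input_shape = input_shape, lstm_layers = as.integer(lstm_layers),
                 lstm_activations = lstm_activations, traits_dim = traits_dim,
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "model_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Linear gather indices turning a zero-padded (h+2, w+2, cin) array into the
# (h*w) x (9*cin) patch matrix of a same-padded 3x3 convolution.
im2col_indices <- function(h, w, cin) {
  hp <- h + 2L
  pos_r <- rep(seq_len(h), times = w)        # output row (centre - 1 in pad)
  pos_c <- rep(seq_len(w), each = h)
  idx <- matrix(0L, h * w, 9L * cin)
  k <- 0L
  for (ch in seq_len(cin)) {
    off_ch <- (ch - 1L) * hp * (w + 2L)
    for (dc in 0:2) for (dr in 0:2) {
      k <- k + 1L
      idx[, k] <- off_ch + (pos_c + dc - 1L) * hp + (pos_r + dr)
    }
  }
  idx
}

conv_layer_spec <- function(cin, cout) list(kind = "conv", cin = cin, cout = cout,
                                            kernel = c(3L, 3L))
pool_layer_spec <- function() list(kind = "pool", size = c(2L, 2L))
dense_layer_spec <- function(din, dout) list(kind = "dense", din = din, dout = dout)

backbone_layers <- function(backbone, input_shape, n_classes = 4L) {
  h <- input_shape[1]; w <- input_shape[2]; cin <- input_shape[3]
  layers <- list()
  widths <- if (backbone == "vgg16") VGG16_CONV_WIDTHS
            else list(8L, 16L, 32L, 64L)
  cur <- cin
  for (block in widths) {
    for (cout in block) {
      layers[[length(layers) + 1L]] <- conv_layer_spec(cur, cout)
      cur <- cout
    }
    layers[[length(layers) + 1L]] <- pool_layer_spec()
    h <- h %/% 2L; w <- w %/% 2L
    if (h < 1 || w < 1) stop("input_shape too small for backbone '", backbone, "'")
  }
  feat_dim <- h * w * cur
  dense <- if (backbone == "vgg16") VGG16_DENSE_WIDTHS else n_classes
  din <- feat_dim
  for (dout in dense) {
    layers[[length(layers) + 1L]] <- dense_layer_spec(din, dout)
    din <- dout
  }
  list(layers = layers, feat_dim = feat_dim, out_shape = c(h, w, cur))
}

#' Build the convolutional emotion branch
#'
#' Constructs the backbone architecture and (optionally) materializes seeded
#' He-normal weights. \code{small_cnn} is always materialized; \code{vgg16}
#' defaults to an architecture-only build (its census is what downstream
#' checks rely on) because a materialized build allocates on the order of
#' 10^8 parameters.
#'
#' @param cfg a \code{\link{model_config}}.
#' @param n_classes size of the classification head (4 affect quadrants).
#' @param materialize allocate weights; default \code{TRUE} for
#'   \code{small_cnn}, \code{FALSE} for \code{vgg16}.
#' @param use_bias include bias terms (disable for linearity diagnostics).
#' @return object of class \code{cnn_model}.
#' @export
build_cnn <- function(cfg = model_config(), n_classes = 4L,
                      materialize = identical(cfg$backbone, "small_cnn"),
                      use_bias = TRUE) {
  if (!cfg$backbone %in% c("vgg16", "small_cnn"))
    stop("unknown backbone '", cfg$backbone, "'")
  if (isTRUE(cfg$pretrained))
    stop("pretrained weights requested but no weight source is configured; ",
         "supply weights explicitly or set pretrained = FALSE")
  arch <- backbone_layers(cfg$backbone, cfg$input_shape, n_classes)
  model <- list(backbone = cfg$backbone, input_shape = cfg$input_shape,
                layers = arch$layers, feat_dim = arch$feat_dim,
                out_shape = arch$out_shape, n_classes = n_classes,
                use_bias = use_bias, seed = cfg$seed, weights = NULL,
                head = NULL)
  if (materialize) {
    model$weights <- with_seed(cfg$seed, {
      lapply(arch$layers, function(l) {
        switch(l$kind,
          conv = {
            fan_in <- 9 * l$cin
            list(W = matrix(rnorm(fan_in * l$cout, sd = sqrt(2 / fan_in)),
                            fan_in, l$cout),
                 b = if (use_bias) rnorm(l$cout, sd = 0.01) else rep(0, l$cout))
          },
          pool = NULL,
          dense = list(W = matrix(rnorm(l$din * l$dout, sd = sqrt(2 / l$din)),
                                  l$din, l$dout),
                       b = if (use_bias) rnorm(l$dout, sd = 0.01) else rep(0, l$dout)))
      })
    })
    # cache im2col gather indices per conv layer
    h <- cfg$input_shape[1]; w <- cfg$input_shape[2]
    model$im2col <- vector("list", length(arch$layers))
    cin <- cfg$input_shape[3]
    for (i in seq_along(arch$layers)) {
      l <- arch$layers[[i]]
      if (l$kind == "conv") {
        model$im2col[[i]] <- im2col_indices(h, w, l$cin)
        cin <- l$cout
      } else if (l$kind == "pool") {
        h <- h %/% 2L; w <- w %/% 2L
      }
    }
  }
  structure(model, class = "cnn_model")
}

#' Layer census of a CNN model
#'
#' @param model a \code{cnn_model}.
#' @return list with counts of convolutional, pooling and dense layers and
#'   the kernel size.
#' @export
cnn_layer_census <- function(model) {
  kinds <- vapply(model$layers, `[[`, character(1), "kind")
  list(conv = sum(kinds == "conv"), pool = sum(kinds == "pool"),
       dense = sum(kinds == "dense"), kernel = c(3L, 3L))
}

#' @export
print.cnn_model <- function(x, ...) {
  cz <- cnn_layer_census(x)
  cat(sprintf("<cnn_model> %s: %d conv (3x3) + %d pool + %d dense, feature dim %d%s\n",
              x$backbone, cz$conv, cz$pool, cz$dense, x$feat_dim,
              if (is.null(x$weights)) " (architecture only)" else ""))
  invisible(x)
}

maxpool2 <- function(x) {
  d <- dim(x)
  ro <- seq(1L, d[1] - 1L, by = 2L); co <- seq(1L, d[2] - 1L, by = 2L)
  pmax(x[ro, co, , drop = FALSE], x[ro + 1L, co, , drop = FALSE],
       x[ro, co + 1L, , drop = FALSE], x[ro + 1L, co + 1L, , drop = FALSE])
}

cnn_forward_one <- function(model, img) {
  x <- img
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$kind == "conv") {
      d <- dim(x)
      xp <- array(0, dim = c(d[1] + 2L, d[2] + 2L, d[3]))
      xp[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- x
      patches <- matrix(xp[model$im2col[[i]]], d[1] * d[2])
      z <- patches %*% model$weights[[i]]$W
      z <- sweep(z, 2, model$weights[[i]]$b, `+`)
      x <- array(pmax(z, 0), dim = c(d[1], d[2], l$cout))
    } else if (l$kind == "pool") {
      x <- maxpool2(x)
    } else break
  }
  as.numeric(x)  # flattened last convolutional stage
}

#' Extract feature vectors from spectrogram images
#'
#' Runs the convolutional stages and returns the flattened activation of the
#' last convolutional layer (after its pooling stage), one row per image.
#'
#' @param model a materialized \code{cnn_model}.
#' @param images list of \code{spectro_image} objects (or arrays) matching
#'   the model input shape.
#' @return numeric matrix, images x feature dimension.
#' @export
extract_features <- function(model, images) {
  stopifnot(inherits(model, "cnn_model"))
  if (is.null(model$weights))
    stop("model is architecture-only; rebuild with materialize = TRUE")
  mats <- lapply(images, function(im) {
    px <- if (inherits(im, "spectro_image")) im$pixels else im
    if (!all(dim(px) == model$input_shape))
      stop("image shape (", paste(dim(px), collapse = "x"),
           ") does not match model input (",
           paste(model$input_shape, collapse = "x"), ")")
    cnn_forward_one(model, px)
  })
  do.call(rbind, mats)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

adam_state <- function(shapes) {
  lapply(shapes, function(s) list(m = array(0, dim = s), v = array(0, dim = s)))
}

adam_update <- function(par, grad, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), state = st)
}

#' Train the softmax emotion head
#'
#' Fits a softmax classifier over CNN feature vectors with Adam on
#' cross-entropy, recording per-epoch loss and accuracy on the training and
#' validation splits.
#'
#' @param features numeric matrix, samples x feature dim.
#' @param labels factor/character of emotion quadrants (>= 2 classes).
#' @param cfg a \code{\link{model_config}} (learning rate, batch size,
#'   epochs, seed).
#' @param val_frac fraction held out for validation when \code{val_idx} is
#'   not given.
#' @param val_idx optional explicit validation row indices.
#' @return object of class \code{emotion_head}: weights, feature scaling,
#'   class levels and a history data.frame (\code{epoch, split, loss,
#'   accuracy}).
#' @export
train_emotion_head <- function(features, labels, cfg = model_config(),
                               val_frac = 0.15, val_idx = NULL) {
  features <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 classes to train the emotion head")
  n <- nrow(features)
  stopifnot(length(y) == n)
  if (is.null(val_idx)) {
    val_idx <- with_seed(cfg$seed + 1L,
                         sample(n, size = max(1L, round(val_frac * n))))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)

  mu <- colMeans(features[tr_idx, , drop = FALSE])
  sg <- apply(features[tr_idx, , drop = FALSE], 2, sd)
  sg[sg < 1e-12] <- 1
  X <- sweep(sweep(features, 2, mu), 2, sg, `/`)
  K <- nlevels(y)
  Y <- diag(K)[as.integer(y), , drop = FALSE]

  d <- ncol(X)
  W <- with_seed(cfg$seed, matrix(rnorm(d * K, sd = 0.01), d, K))
  b <- rep(0, K)
  stW <- adam_state(list(dim(W)))[[1]]
  stb <- adam_state(list(length(b)))[[1]]

  eval_split <- function(idx) {
    P <- softmax_rows(sweep(X[idx, , drop = FALSE] %*% W, 2, b, `+`))
    loss <- -mean(log(pmax(rowSums(P * Y[idx, , drop = FALSE]), 1e-12)))
    acc <- mean(max.col(P) == as.integer(y)[idx])
    c(loss = loss, accuracy = acc)
  }

  hist <- vector("list", cfg$epochs * 2L)
  t <- 0
  batches_seed <- cfg$seed + 17L
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(batches_seed + ep, sample(tr_idx))
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      bi <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      Xb <- X[bi, , drop = FALSE]
      P <- softmax_rows(sweep(Xb %*% W, 2, b, `+`))
      G <- (P - Y[bi, , drop = FALSE]) / length(bi)
      gW <- crossprod(Xb, G)
      gb <- colSums(G)
      t <- t + 1
      up <- adam_update(W, gW, stW, cfg$learning_rate, t); W <- up$par; stW <- up$state
      up <- adam_update(b, gb, stb, cfg$learning_rate, t); b <- up$par; stb <- up$state
    }
    tr <- eval_split(tr_idx); va <- eval_split(val_idx)
    hist[[2 * ep - 1]] <- data.frame(epoch = ep, split = "train",
                                     loss = tr["loss"], accuracy = tr["accuracy"])
    hist[[2 * ep]] <- data.frame(epoch = ep, split = "val",
                                 loss = va["loss"], accuracy = va["accuracy"])
  }
  history <- do.call(rbind, hist)
  rownames(history) <- NULL
  structure(list(W = W, b = b, mu = mu, sigma = sg, levels = levels(y),
                 history = history, val_idx = val_idx),
            class = "emotion_head")
}

#' Predict emotion quadrants (or class scores) from features
#'
#' @param object an \code{emotion_head}.
#' @param features feature matrix.
#' @param type \code{"class"} for labels, \code{"prob"} for softmax scores.
#' @param ... unused.
#' @return character vector or probability matrix.
#' @export
predict.emotion_head <- function(object, features, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- sweep(sweep(as.matrix(features), 2, object$mu), 2, object$sigma, `/`)
  P <- softmax_rows(sweep(X %*% object$W, 2, object$b, `+`))
  colnames(P) <- object$levels
  if (type == "prob") P else object$levels[max.col(P)]
}
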