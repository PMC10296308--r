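test_that("vgg16 census reports 13 convolutional and 3 dense layers", {
  m <- build_cnn(model_config(backbone = "vgg16"), materialize = FALSE)
  cz <- cnn_layer_census(m)
  expect_equal(cz$conv, 13)
  expect_equal(cz$dense, 3)
  expect_equal(cz$kernel, c(3L, 3L))
  expect_equal(cz$pool, 5)
  expect_error(extract_features(m, list()), "architecture-only")
  expect_error(build_cnn(model_config(backbone = "vgg16", pretrained = TRUE)),
               "pretrained")
  expect_error(build_cnn(model_config(backbone = "resnet")), "unknown backbone")
})

test_that("small_cnn forward pass has the contracted shapes and seeding", {
  cfg <- model_config(input_shape = c(32, 32, 2), seed = 5)
  m1 <- build_cnn(cfg)
  m2 <- build_cnn(cfg)
  expect_equal(m1$weights, m2$weights)   # seeded reproducibility

  imgs <- lapply(1:3, function(i) array(runif(32 * 32 * 2), c(32, 32, 2)))
  ft <- extract_features(m1, imgs)
  expect_equal(dim(ft), c(3, m1$feat_dim))
  expect_equal(m1$feat_dim, 2 * 2 * 64)

  # identical images give identical features
  ft2 <- extract_features(m1, list(imgs[[1]], imgs[[1]]))
  expect_equal(ft2[1, ], ft2[2, ])

  # wrong input shape is rejected
  expect_error(extract_features(m1, list(array(0, c(16, 16, 2)))), "shape")

  # zero input through a bias-free net yields zero features
  m0 <- build_cnn(cfg, use_bias = FALSE)
  f0 <- extract_features(m0, list(array(0, c(32, 32, 2))))
  expect_equal(max(abs(f0)), 0)
})

test_that("emotion head reaches 100% on separable clusters and is seeded", {
  set.seed(2)
  n_per <- 50
  centers <- rbind(c(4, 0), c(-4, 0), c(0, 4), c(0, -4))
  F <- do.call(rbind, lapply(1:4, function(k)
    cbind(matrix(rnorm(n_per * 2, sd = 0.5), ncol = 2) +
            matrix(centers[k, ], n_per, 2, byrow = TRUE),
          matrix(rnorm(n_per * 3), ncol = 3))))
  y <- rep(EMOTION_QUADRANTS, each = n_per)
  cfg <- model_config(epochs = 200, batch_size = 32, learning_rate = 0.01,
                      seed = 7)
  fit <- train_emotion_head(F, y, cfg)
  tr_acc <- subset(fit$history, split == "train")$accuracy
  expect_true(any(tr_acc == 1))
  expect_setequal(unique(fit$history$split), c("train", "val"))

  fit2 <- train_emotion_head(F, y, cfg)
  expect_equal(fit$history, fit2$history)
  expect_equal(fit$W, fit2$W)

  expect_error(train_emotion_head(F, rep("HV_HA", nrow(F)), cfg), "2 classes")
})

test_that("permuted labels leave validation accuracy near chance", {
  set.seed(3)
  F <- matrix(rnorm(400 * 10), 400, 10)
  y_perm <- sample(rep(EMOTION_QUADRANTS, each = 100))
  cfg <- model_config(epochs = 40, batch_size = 64, learning_rate = 0.005,
                      seed = 13)
  fit <- train_emotion_head(F, y_perm, cfg)
  val_acc <- tail(subset(fit$history, split == "val")$accuracy, 1)
  expect_gt(val_acc, 0.05)
  expect_lt(val_acc, 0.45)
})

test_that("LSTM builds with the default widths and sigmoid-bounded outputs", {
  cfg <- model_config()
  m <- build_lstm(cfg, input_dim = 12)
  expect_equal(m$widths, c(64, 32, 16))
  expect_equal(vapply(m$layers, function(l) nrow(l$W) / 4, numeric(1)),
               c(64, 32, 16))
  expect_equal(m$activations, c("relu", "relu", "sigmoid"))
  expect_equal(nrow(m$dense$V), 5)

  set.seed(4)
  for (len in c(1, 3, 20)) {
    y <- predict(m, matrix(rnorm(len * 12) * 5, len, 12))
    expect_true(all(y > 0 & y < 1))
  }
  expect_error(predict(m, matrix(0, 0, 12)), "empty sequence")
  expect_error(model_config(lstm_layers = c(8, 4),
                            lstm_activations = c("relu")), "equal length")
})

test_that("make_sequences groups by subject and block, ordered and shuffle-proof", {
  set.seed(6)
  n <- 30
  meta <- data.frame(
    subject_id = rep(c("a", "b"), each = 15),
    category = rep(rep(c("happy", "sad", "neutral"), each = 5), 2),
    start_sample = rep(seq(0, 1400, by = 100), 2),
    stringsAsFactors = FALSE)
  feats <- matrix(seq_len(n * 2), n, 2)
  seqs <- make_sequences(feats, meta)
  expect_length(seqs, 6)   # 2 subjects x 3 category blocks
  for (s in seqs) expect_equal(nrow(s$x), 5)

  # shuffling input rows leaves output sequences unchanged
  perm <- sample(n)
  seqs2 <- make_sequences(feats[perm, ], meta[perm, ])
  key <- function(ss) ss[order(vapply(ss, function(s)
    paste(s$subject, s$category), character(1)))]
  expect_equal(lapply(key(seqs2), `[[`, "x"), lapply(key(seqs), `[[`, "x"))

  # strictly increasing starts within each sequence are implied by ordering
  m2 <- meta; m2$category[1:15] <- NA
  expect_length(make_sequences(feats, m2), 3)
})

test_that("personality LSTM beats the predict-the-mean baseline on an affine family", {
  set.seed(31)
  subs <- sprintf("P%02d", 1:6)
  Evals <- seq(1.4, 4.6, length.out = 6)
  seqs <- list(); traits <- list()
  for (i in seq_along(subs)) {
    traits[[subs[i]]] <- personality_profile(Evals[i], 3, 3, 3, 3)
    for (b in 1:3)
      seqs[[length(seqs) + 1]] <- list(
        x = matrix(rnorm(20 * 6, mean = (Evals[i] - 3)), 20, 6),
        subject = subs[i])
  }
  cfg <- model_config(lstm_layers = c(16, 8, 4),
                      lstm_activations = c("relu", "relu", "sigmoid"),
                      epochs = 60, batch_size = 8, learning_rate = 0.01,
                      seed = 11)
  res <- train_personality_lstm(seqs, traits, cfg, loso = TRUE)
  expect_length(res$folds, 6)                       # LOSO: one fold per subject
  expect_setequal(rownames(res$predictions), subs)

  mse_E <- mean((res$predictions[, "E"] - res$targets[, "E"])^2)
  base_E <- mean((mean(res$targets[, "E"]) - res$targets[, "E"])^2)
  expect_lt(mse_E, base_E)

  expect_error(train_personality_lstm(seqs, traits[-1], cfg), "missing")
})

test_that("personality LSTM converges to constant targets", {
  set.seed(41)
  seqs <- lapply(1:6, function(i)
    list(x = matrix(rnorm(10 * 4), 10, 4), subject = sprintf("s%d", (i - 1) %/% 2)))
  traits <- list(s0 = personality_profile(3, 3, 3, 3, 3),
                 s1 = personality_profile(3, 3, 3, 3, 3),
                 s2 = personality_profile(3, 3, 3, 3, 3))
  cfg <- model_config(lstm_layers = c(8, 8, 4),
                      lstm_activations = c("relu", "relu", "sigmoid"),
                      epochs = 80, batch_size = 6, learning_rate = 0.02, seed = 2)
  fit <- train_personality_lstm(seqs, traits, cfg)
  preds <- predict(fit$model, lapply(seqs, `[[`, "x"))
  expect_lt(mean((preds - 0.5)^2), 0.01)
})

test_that("fusion concatenates CNN-first with exact dimensions", {
  a <- rnorm(512); b <- runif(5)
  f <- fuse(a, b)
  expect_length(f, 517)
  expect_equal(f[1:512], a)
  expect_equal(fuse(rep(0, 4), rep(0, 5)), rep(0, 9))
  A <- matrix(rnorm(12), 3); B <- matrix(runif(15), 3)
  expect_equal(dim(fuse(A, B)), c(3, 9))
  expect_error(fuse(matrix(0, 2, 2), matrix(0, 3, 5)), "row counts")
  expect_error(fuse(c(1, NA), c(1, 2)), "non-finite")
})

test_that("final classifiers separate clean clusters and expose nested folds", {
  set.seed(17)
  n_per <- 30
  centers <- rbind(c(5, 0, 0), c(0, 5, 0), c(0, 0, 5), c(-5, -5, -5))
  X <- do.call(rbind, lapply(1:4, function(k)
    matrix(rnorm(n_per * 3, sd = 0.4), ncol = 3) +
      matrix(centers[k, ], n_per, 3, byrow = TRUE)))
  y <- rep(EMOTION_QUADRANTS, each = n_per)

  svm_fit <- train_final_classifier(X, y, kind = "svm", seed = 3)
  expect_gt(svm_fit$accuracy, 95)
  # nested-CV audit: outer folds partition the data, every sample predicted once
  expect_setequal(unique(svm_fit$fold), 1:5)
  expect_false(any(is.na(svm_fit$predictions)))

  for (kind in c("mlp", "bn")) {
    fit <- train_final_classifier(X, y, kind = kind, seed = 3)
    expect_gt(fit$accuracy, 90)
  }

  # kNN with k = 1 memorizes its training set
  knn1 <- fit_final_classifier(X, y, kind = "knn", knn_k = 1)
  expect_equal(mean(predict(knn1, X) == y), 1)

  expect_error(train_final_classifier(X, y, kind = "forest"), "unknown")
  expect_error(train_final_classifier(X, rep("a", nrow(X))), "2 classes")
})

test_that("label permutation drops the final classifier to chance", {
  set.seed(23)
  X <- matrix(rnorm(160 * 5), 160, 5)
  y <- sample(rep(EMOTION_QUADRANTS, each = 40))
  fit <- train_final_classifier(X, y, kind = "svm", seed = 9,
                                svm_grid = data.frame(cost = 1, gamma = 0.2))
  expect_lt(fit$accuracy, 45)
})
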