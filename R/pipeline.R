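# End-to-end orchestration: simulate -> preprocess -> spectrogram images ->
# CNN features -> emotion head -> per-block sequences -> personality LSTM
# (leave-one-subject-out) -> fusion -> final classifier -> metrics reports.
# Every artifact is a pure function of (input data, config, seed); manifests
# record both.

#' Pipeline run configuration
#'
#' Nested defaults for every stage; any subset can be overridden via
#' \code{overrides} (recursively merged). The desk profile keeps the
#' reference hyperparameters (Adam, learning rate 0.001, batch 64) but caps
#' epochs at 50 and uses the small backbone; \code{paper_scale = TRUE}
#' restores 500 epochs and the vgg16 census backbone.
#'
#' @param overrides named list merged over the defaults.
#' @param seed master seed; stage seeds derive from it.
#' @param paper_scale use the full-scale training protocol.
#' @return nested list of class \code{run_config}.
#' @export
run_config <- function(overrides = list(), seed = 1L, paper_scale = FALSE) {
  cfg <- list(
    seed = as.integer(seed),
    preprocess = list(target_rate = 128,
                      bandpass = list(low = 0.4, high = 60, order = 2),
                      notch_hz = 50,
                      ica = list(enabled = TRUE, threshold = 0.8, seed = 1L,
                                 maxit = 40),
                      window = list(seconds = 2.0, overlap = 0.5,
                                    baseline_ms = 200)),
    stft = list(win_size = 128, step = 16, window_fn = "hamming",
                zero_pad = TRUE),
    band = c(0.4, 60),
    image = list(height = 32, width = 32, aggregation = "hemisphere"),
    model = list(backbone = if (paper_scale) "vgg16" else "small_cnn",
                 learning_rate = 0.001, batch_size = 64,
                 epochs = if (paper_scale) 500L else 50L,
                 lstm_epochs = if (paper_scale) 500L else 20L,
                 lstm_layers = c(64, 32, 16),
                 lstm_activations = c("relu", "relu", "sigmoid")),
    sequences = list(stride = 8L),
    final = list(kind = "svm", inner_k = 3, max_train = 1500L),
    eval = list(ratio = c(0.70, 0.15, 0.15))
  )
  cfg <- utils::modifyList(cfg, overrides)
  structure(cfg, class = "run_config")
}

#' Simulate a dataset to disk
#'
#' @param out_dir output directory.
#' @param subjects_per_group subjects per group.
#' @param seed master seed.
#' @param cfg optional \code{\link{synth_config}} overriding the two
#'   arguments above.
#' @return (invisibly) the \code{\link{make_dataset}} result.
#' @export
cmd_simulate <- function(out_dir, subjects_per_group = 2, seed = 1L,
                         cfg = NULL) {
  if (is.null(cfg))
    cfg <- synth_config(n_subjects_per_group = subjects_per_group, seed = seed)
  message("simulating ", 3 * cfg$n_subjects_per_group, " subjects into ", out_dir)
  invisible(make_dataset(cfg, out_dir = out_dir, write = TRUE))
}

image_channels_of <- function(aggregation) {
  switch(aggregation, hemisphere = 2L, mean = 1L, per_channel = 1L,
         stop("unknown aggregation '", aggregation, "'"))
}

# Featurize one recording: preprocess to windows, then spectrogram images,
# then CNN features. Returns features + per-window metadata.
featurize_recording <- function(rec, cnn, cfg) {
  wins <- preprocess_chain(rec, cfg$preprocess)
  if (length(wins) == 0) return(NULL)
  p <- stft_params(win_size = cfg$stft$win_size, step = cfg$stft$step,
                   window_fn = cfg$stft$window_fn, rate = cfg$preprocess$target_rate,
                   zero_pad = cfg$stft$zero_pad)
  imgs <- lapply(wins, function(w)
    window_to_images(w, p, agg = cfg$image$aggregation, band = cfg$band,
                     out_h = cfg$image$height, out_w = cfg$image$width)[[1]])
  feats <- extract_features(cnn, imgs)
  list(features = feats, meta = window_metadata(wins), windows = wins)
}

#' Run the full pipeline on a dataset directory
#'
#' Expects the layout written by \code{\link{cmd_simulate}}: one EDF per
#' subject, \code{traits.csv} with a \code{group} column. Writes metrics
#' (CSV/JSON), ROC points, confusion matrices, training histories and a
#' manifest into \code{out_dir}.
#'
#' @param input_dir dataset directory.
#' @param out_dir output directory (created if needed).
#' @param cfg a \code{\link{run_config}}.
#' @param verbose log stage progress.
#' @return (invisibly) list with the emotion-branch report
#'   (\code{cnn_metrics}), fused final-classifier report
#'   (\code{final_metrics}), personality results (\code{personality}) and
#'   output \code{paths}.
#' @export
cmd_run <- function(input_dir, out_dir, cfg = run_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message("[run] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  say("loading dataset from ", input_dir)
  traits_df <- stage("load", {
    p <- file.path(input_dir, "traits.csv")
    if (!file.exists(p)) stop("traits.csv not found in ", input_dir)
    read.csv(p, stringsAsFactors = FALSE)
  })
  edfs <- sort(list.files(input_dir, pattern = "\\.edf$", full.names = TRUE))
  if (length(edfs) == 0) stop("stage 'load' failed: no EDF files in ", input_dir)
  groups <- if ("group" %in% names(traits_df))
    stats::setNames(traits_df$group, traits_df$subject_id) else NULL

  mc <- model_config(backbone = cfg$model$backbone,
                     input_shape = c(cfg$image$height, cfg$image$width,
                                     image_channels_of(cfg$image$aggregation)),
                     lstm_layers = cfg$model$lstm_layers,
                     lstm_activations = cfg$model$lstm_activations,
                     learning_rate = cfg$model$learning_rate,
                     batch_size = cfg$model$batch_size,
                     epochs = cfg$model$epochs, seed = cfg$seed)
  cnn <- stage("build_cnn", build_cnn(mc, materialize = TRUE))

  say("featurizing ", length(edfs), " recordings")
  per_rec <- stage("featurize", lapply(edfs, function(f) {
    rec <- read_edf(f)
    if (!is.null(groups) && rec$subject_id %in% names(groups))
      rec$group <- groups[[rec$subject_id]]
    featurize_recording(rec, cnn, cfg)
  }))
  per_rec <- per_rec[!vapply(per_rec, is.null, logical(1))]
  features <- do.call(rbind, lapply(per_rec, `[[`, "features"))
  meta <- do.call(rbind, lapply(per_rec, `[[`, "meta"))

  labeled <- !is.na(meta$emotion_label)
  X <- features[labeled, , drop = FALSE]
  lab <- meta$emotion_label[labeled]
  strat <- paste(meta$group[labeled], lab, sep = "|")

  say("training emotion head on ", nrow(X), " windows")
  plan <- stage("split", split_70_15_15(seq_len(nrow(X)), strat,
                                        seed = cfg$seed, ratio = cfg$eval$ratio))
  head_fit <- stage("emotion_head", {
    trval <- c(plan$train, plan$val)
    train_emotion_head(X[trval, , drop = FALSE], lab[trval], mc,
                       val_idx = seq_along(trval)[trval %in% plan$val])
  })
  test_prob <- predict(head_fit, X[plan$test, , drop = FALSE], type = "prob")
  test_pred <- head_fit$levels[max.col(test_prob)]
  cnn_metrics <- metrics_report(lab[plan$test], test_pred, scores = test_prob)

  say("training personality branch (LOSO)")
  traits_list <- stats::setNames(
    lapply(seq_len(nrow(traits_df)), function(i)
      personality_profile(traits_df$E[i], traits_df$A[i], traits_df$C[i],
                          traits_df$N[i], traits_df$O[i])),
    traits_df$subject_id)
  seqs <- stage("sequences", make_sequences(features, meta,
                                            stride = cfg$sequences$stride))
  mc_lstm <- mc
  mc_lstm$epochs <- cfg$model$lstm_epochs
  mc_lstm$learning_rate <- 0.005   # MSE scale is far below cross-entropy
  mc_lstm$batch_size <- min(mc$batch_size, 8L)
  pers <- stage("personality_lstm",
                train_personality_lstm(seqs, traits_list, mc_lstm, loso = TRUE))

  say("fusing and training final classifier (", cfg$final$kind, ")")
  trait_rows <- pers$predictions[meta$subject_id[labeled], , drop = FALSE]
  fused <- fuse(X, trait_rows)
  trv <- c(plan$train, plan$val)
  if (length(trv) > cfg$final$max_train) {
    # stratified subsample keeps the classifier fit tractable at desk scale
    trv <- with_seed(cfg$seed + 23L, {
      keep_n <- round(cfg$final$max_train * table(lab[trv]) / length(trv))
      unlist(lapply(names(keep_n), function(cl) {
        idx <- trv[lab[trv] == cl]
        sample(idx, min(length(idx), keep_n[[cl]]))
      }), use.names = FALSE)
    })
  }
  final_fit <- stage("final_classifier",
                     fit_final_classifier(fused[trv, , drop = FALSE], lab[trv],
                                          kind = cfg$final$kind,
                                          inner_k = cfg$final$inner_k,
                                          seed = cfg$seed,
                                          svm_grid = expand.grid(
                                            cost = c(1, 10, 100),
                                            gamma = c(1, 3) / ncol(fused))))
  final_pred <- predict(final_fit, fused[plan$test, , drop = FALSE])
  final_metrics <- metrics_report(lab[plan$test], final_pred)

  say("writing reports to ", out_dir)
  paths <- stage("report", {
    p <- list(
      cnn_metrics_csv = file.path(out_dir, "cnn_metrics.csv"),
      cnn_metrics_json = file.path(out_dir, "cnn_metrics.json"),
      final_metrics_csv = file.path(out_dir,
        paste0("final_metrics_", cfg$final$kind, ".csv")),
      final_metrics_json = file.path(out_dir,
        paste0("final_metrics_", cfg$final$kind, ".json")),
      roc_csv = file.path(out_dir, "roc_cnn.csv"),
      confusion_csv = file.path(out_dir, "confusion_cnn.csv"),
      history_csv = file.path(out_dir, "history_emotion_head.csv"),
      personality_csv = file.path(out_dir, "personality_loso.csv"),
      manifest = file.path(out_dir, "manifest.json"))
    write_metrics(cnn_metrics, p$cnn_metrics_csv, p$cnn_metrics_json)
    write_metrics(final_metrics, p$final_metrics_csv, p$final_metrics_json)
    roc_rows <- do.call(rbind, lapply(colnames(test_prob), function(cl) {
      if (length(unique(lab[plan$test] == cl)) < 2) return(NULL)
      r <- roc_auc(test_prob[, cl], lab[plan$test] == cl)
      data.frame(class = cl, r$curve)
    }))
    write.csv(roc_rows, p$roc_csv, row.names = FALSE)
    conf <- as.data.frame.matrix(table(true = lab[plan$test], pred = test_pred))
    write.csv(cbind(true = rownames(conf), conf), p$confusion_csv,
              row.names = FALSE)
    write.csv(head_fit$history, p$history_csv, row.names = FALSE)
    pd <- data.frame(subject_id = rownames(pers$predictions),
                     pers$predictions,
                     mse = vapply(seq_len(nrow(pers$predictions)), function(i)
                       mean((pers$predictions[i, ] - pers$targets[
                         rownames(pers$predictions)[i], ])^2), numeric(1)))
    write.csv(pd, p$personality_csv, row.names = FALSE)
    jsonlite::write_json(
      list(config = unclass(cfg), seed = cfg$seed,
           n_windows = nrow(features), n_labeled = sum(labeled),
           subjects = unique(meta$subject_id),
           final_classifier = cfg$final$kind,
           test_accuracy_cnn = cnn_metrics$overall_accuracy,
           test_accuracy_final = final_metrics$overall_accuracy,
           input_checksums = as.list(tools::md5sum(edfs))),
      p$manifest, auto_unbox = TRUE, digits = NA)
    p
  })
  invisible(list(cnn_metrics = cnn_metrics, final_metrics = final_metrics,
                 personality = pers, split = plan, paths = paths,
                 head = head_fit, final = final_fit))
}

#' Render a human-readable summary of metrics reports
#'
#' Reads one or more metrics JSON files written by \code{\link{cmd_run}} and
#' prints a per-class table plus, when several classifier reports are given,
#' a comparison table.
#'
#' @param paths character vector of metrics JSON paths, or a directory to
#'   scan for \code{*metrics*.json}.
#' @return (invisibly) list of parsed reports.
#' @export
cmd_report <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "metrics.*\\.json$", full.names = TRUE)
  if (length(paths) == 0) stop("no reports found")
  reports <- lapply(paths, function(p) {
    r <- jsonlite::read_json(p, simplifyVector = TRUE)
    if (is.null(r$per_class)) stop("malformed metrics report: ", p)
    r$source <- p
    r
  })
  for (r in reports) {
    cat("== ", basename(r$source), " ==\n", sep = "")
    print(as.data.frame(r$per_class), row.names = FALSE)
    cat(sprintf("macro P/R/F1: %.2f / %.2f / %.2f; overall accuracy %.2f%%\n\n",
                r$macro$precision, r$macro$recall, r$macro$f1,
                r$overall_accuracy))
  }
  if (length(reports) > 1) {
    cmp <- do.call(rbind, lapply(reports, function(r)
      data.frame(report = basename(r$source),
                 overall_accuracy = r$overall_accuracy,
                 macro_f1 = r$macro$f1)))
    cat("Comparison:\n"); print(cmp, row.names = FALSE)
  }
  invisible(reports)
}
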