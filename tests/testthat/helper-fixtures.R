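# Shared fixtures, all built in code at test time.

# Reference one-vs-rest confusion proportions (percent of all test windows)
# for the four affect quadrants, with the metric values they imply.
table_confusion <- function() {
  data.frame(
    class = c("HV_HA", "HV_LA", "LV_HA", "LV_LA"),
    tp = c(17.7, 18.9, 23.7, 21.4),
    tn = c(1.6, 1.3, 1.3, 1.3),
    fp = c(0.9, 1.8, 1.7, 1.9),
    fn = c(1.3, 1.3, 1.5, 2.4),
    accuracy = c(89.77, 86.70, 88.65, 84.07),
    precision = c(95.16, 91.30, 93.31, 91.85),
    recall = c(93.16, 93.56, 94.05, 89.92),
    f1 = c(94.15, 92.42, 93.68, 90.87),
    stringsAsFactors = FALSE
  )
}

reference_macro <- function() c(precision = 92.90, recall = 92.67, f1 = 92.78)

# n-channel sinusoid recording
sine_recording <- function(freq_hz, rate = 256, dur_s = 4, channels = 2,
                           labels = NULL, amp = 1) {
  t <- seq_len(rate * dur_s) / rate
  x <- amp * sin(2 * pi * freq_hz * t)
  if (is.null(labels)) labels <- DEFAULT_MONTAGE_32[seq_len(channels)]
  eeg_recording(matrix(rep(x, channels), channels, byrow = TRUE), rate, labels)
}

noise_recording <- function(rate = 256, dur_s = 4, channels = 4, seed = 1,
                            labels = NULL) {
  set.seed(seed)
  if (is.null(labels)) labels <- DEFAULT_MONTAGE_32[seq_len(channels)]
  eeg_recording(matrix(rnorm(channels * rate * dur_s) * 10, channels),
                rate, labels)
}

# Small, fully featured dataset shared by orchestration tests (built once).
mini_dataset_env <- new.env()
mini_dataset <- function() {
  if (is.null(mini_dataset_env$dir)) {
    dir <- file.path(tempdir(), "eegaffect-mini-ds")
    unlink(dir, recursive = TRUE)
    cfg <- synth_config(n_subjects_per_group = 2, n_images = 6,
                        include_video = FALSE, seed = 5)
    suppressMessages(cmd_simulate(dir, cfg = cfg))
    mini_dataset_env$dir <- dir
  }
  mini_dataset_env$dir
}

mini_run_config <- function(seed = 9, ...) {
  run_config(overrides = utils::modifyList(
    list(model = list(epochs = 25L, lstm_epochs = 8L)), list(...)), seed = seed)
}

quiet_run <- function(...) suppressWarnings(suppressMessages(cmd_run(...)))
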