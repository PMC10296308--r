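test_that("downsampling halves the sample count and preserves spectral peaks", {
  rec <- noise_recording(rate = 256, dur_s = 4, channels = 2)
  ds <- downsample(rec, 128)
  expect_equal(ncol(ds$data), 512)
  expect_equal(ds$rate, 128)
  expect_equal(ds$channel_labels, rec$channel_labels)

  expect_identical(downsample(rec, 256)$data, rec$data)
  expect_error(downsample(rec, 512), "exceeds")

  # dominant DFT peak of a 10 Hz tone stays at 10 Hz after decimation
  tone <- sine_recording(10, rate = 256, dur_s = 4)
  dst <- downsample(tone, 128)
  x <- dst$data[1, ]
  spec <- Mod(fft(x))[1:(length(x) / 2)]
  peak_hz <- (which.max(spec) - 1) * 128 / length(x)
  expect_equal(peak_hz, 10, tolerance = 0.5)
})

test_that("downsampling rescales event onsets by the rate ratio", {
  ev <- stimulus_events(c(256L, 513L), c(512L, 256L), c("happy", "sad"),
                        c("image", "image"), c(5, 2), c(6, 2))
  rec <- eeg_recording(matrix(rnorm(2 * 2048), 2), 256, c("C3", "C4"),
                       events = ev)
  ds <- downsample(rec, 128)
  expect_identical(ds$events$onset_sample, c(128L, 256L))  # 513/2 rounds to 256
  expect_identical(ds$events$duration_samples, c(256L, 128L))
})

test_that("band-pass keeps the passband flat and removes DC", {
  # DC is in the stop band
  dc <- eeg_recording(matrix(5, 1, 2048), 128, "Cz")
  out <- bandpass(dc)
  expect_lt(max(abs(out$data[1, 500:1500])), 0.05 * 5)

  # forward-backward order-2 Butterworth: unit passband gain within 5%
  tone <- sine_recording(10, rate = 128, dur_s = 8, channels = 1)
  bp <- bandpass(tone)
  gain <- sd(bp$data[1, 300:700]) / sd(tone$data[1, 300:700])
  expect_gt(gain, 0.95); expect_lt(gain, 1.05)

  z <- eeg_recording(matrix(0, 1, 1024), 128, "Cz")
  expect_equal(max(abs(bandpass(z)$data)), 0)
  expect_error(bandpass(tone, high_hz = 64), "Nyquist")
})

test_that("notch suppresses the line frequency and spares neighbours", {
  line <- sine_recording(50, rate = 256, dur_s = 4, channels = 1)
  nt <- notch(line)
  expect_lt(sd(nt$data[1, 300:700]) / sd(line$data[1, 300:700]), 0.10)

  tone <- sine_recording(10, rate = 256, dur_s = 4, channels = 1)
  nt10 <- notch(tone)
  ratio <- sd(nt10$data[1, 300:700]) / sd(tone$data[1, 300:700])
  expect_lt(abs(ratio - 1), 0.02)

  z <- eeg_recording(matrix(0, 1, 1024), 256, "Cz")
  expect_equal(max(abs(notch(z)$data)), 0)
  expect_error(notch(sine_recording(10, rate = 64, dur_s = 4), 50), "Nyquist")
})

test_that("filtering is linear", {
  set.seed(21)
  a <- 2.5; b <- -1.25
  x <- noise_recording(rate = 128, dur_s = 4, channels = 1, seed = 1)
  y <- noise_recording(rate = 128, dur_s = 4, channels = 1, seed = 2)
  mix <- x; mix$data <- a * x$data + b * y$data
  lhs <- bandpass(mix)$data
  rhs <- a * bandpass(x)$data + b * bandpass(y)$data
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("ICA removes an injected blink component and reports it", {
  set.seed(7)
  n <- 6000
  blink <- rep(0, n)
  tpl <- eegaffect:::blink_template(256) * 70
  for (s in seq(300, n - 300, by = 500)) blink[s:(s + length(tpl) - 1)] <-
    blink[s:(s + length(tpl) - 1)] + tpl
  X <- matrix(rnorm(8 * n) * 5, 8, n)
  X[1, ] <- X[1, ] + blink
  X[2, ] <- X[2, ] + 0.8 * blink
  rec <- eeg_recording(X, 256, c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "O1", "O2"))

  out <- remove_artifacts_ica(rec, reject_threshold = 0.7, seed = 3)
  expect_gte(sum(out$report$removed), 1)
  pre <- abs(cor(X[1, ], blink))
  post <- abs(cor(out$recording$data[1, ], blink))
  expect_lt(post, 0.5 * pre)

  # artifact-free recording with a high threshold: nothing removed
  clean <- noise_recording(rate = 256, dur_s = 20, channels = 6, seed = 9)
  out2 <- remove_artifacts_ica(clean, reject_threshold = 0.9, seed = 3)
  expect_equal(sum(out2$report$removed), 0)

  # seeded decomposition is reproducible
  out3 <- remove_artifacts_ica(rec, reject_threshold = 0.7, seed = 3)
  expect_equal(out$report, out3$report)

  short <- noise_recording(rate = 256, dur_s = 0.25, channels = 8)
  expect_error(remove_artifacts_ica(short), "too few samples")
})

test_that("window segmentation enumerates every valid start offset", {
  mk <- function(n) eeg_recording(matrix(rnorm(2 * n), 2), 128, c("C3", "C4"))
  expect_length(segment_windows(mk(256)), 1)
  expect_length(segment_windows(mk(255)), 0)
  w9 <- segment_windows(mk(1280))
  expect_length(w9, 9)
  expect_equal(vapply(w9, `[[`, numeric(1), "start_sample"),
               seq(0, 1024, by = 128))

  # exhaustive-enumeration oracle over random lengths
  set.seed(5)
  for (n in sample(200:4000, 25)) {
    expected <- if (n >= 256) length(seq(0, n - 256, by = 128)) else 0
    expect_length(segment_windows(mk(n)), expected)
    expect_equal(expected, if (n >= 256) floor((n - 256) / 128) + 1 else 0)
  }
})

test_that("windows are tagged with the event covering their start sample", {
  ev <- stimulus_events(c(0L, 512L), c(512L, 512L), c("happy", "sad"),
                        c("image", "image"), c(6, 2), c(6, 2))
  rec <- eeg_recording(matrix(rnorm(1 * 1152), 1), 128, "Cz", events = ev)
  wins <- segment_windows(rec)
  cats <- vapply(wins, function(w)
    if (is.null(w$stimulus)) NA_character_ else w$stimulus$category, character(1))
  starts <- vapply(wins, `[[`, numeric(1), "start_sample")
  expect_equal(cats[starts < 512], rep("happy", sum(starts < 512)))
  expect_equal(cats[starts >= 512], rep("sad", sum(starts >= 512)))
  expect_equal(wins[[1]]$emotion_label, "HV_HA")
  expect_equal(cats[starts >= 512][1], "sad")
})

test_that("baseline adjustment subtracts the first-200-ms mean and is idempotent", {
  rec <- eeg_recording(matrix(5, 2, 256), 128, c("C3", "C4"))
  w <- segment_windows(rec)[[1]]
  adj <- baseline_adjust(w)
  expect_equal(max(abs(adj$data)), 0)

  # 200 ms at 128 Hz rounds to 26 samples
  x <- c(rep(3.25, 26), rep(0, 230))
  w2 <- segment_windows(eeg_recording(matrix(x, 1), 128, "Cz"))[[1]]
  adj2 <- baseline_adjust(w2)
  expect_equal(adj2$data[1, 27], -3.25)
  expect_equal(mean(adj2$data[1, 1:26]), 0, tolerance = 1e-12)

  again <- baseline_adjust(adj2)
  expect_equal(again$data, adj2$data, tolerance = 1e-12)
})

test_that("the full chain preserves channel count and labels", {
  ev <- stimulus_events(0L, 2048L, "happy", "image", 6, 6)
  rec <- noise_recording(rate = 256, dur_s = 10, channels = 4, seed = 2)
  rec$events <- ev
  wins <- preprocess_chain(rec, list(ica = list(enabled = TRUE, threshold = 0.8,
                                                seed = 1L, maxit = 30)))
  expect_gt(length(wins), 0)
  for (w in wins[c(1, length(wins))]) {
    expect_equal(nrow(w$data), 4)
    expect_equal(w$channel_labels, rec$channel_labels)
    expect_equal(ncol(w$data), 256)
  }
})
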