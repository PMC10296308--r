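test_that("personality sampling is seeded, truncation-aware and group-shifted", {
  p1 <- sample_personality("normal", seed = 4)
  p2 <- sample_personality("normal", seed = 4)
  expect_identical(p1, p2)

  p0 <- sample_personality("unstable_introvert", seed = 1,
                           sds = c(E = 0, A = 0, C = 0, N = 0, O = 0))
  expect_equal(unname(unclass(p0)["E"]), 2.33 - 0.9)
  expect_equal(unname(unclass(p0)["N"]), 2.32 + 1.2)
  expect_error(sample_personality("stable"), "unknown group")

  # law of large numbers against the analytic truncated-normal mean
  trunc_mean <- function(mu, sd, a, b) {
    al <- (a - mu) / sd; be <- (b - mu) / sd
    mu + sd * (dnorm(al) - dnorm(be)) / (pnorm(be) - pnorm(al))
  }
  n <- 3000
  draws <- vapply(seq_len(n), function(i)
    unclass(sample_personality("normal", seed = 100000 + i)), numeric(5))
  means <- rowMeans(draws)
  sds_emp <- apply(draws, 1, sd)
  mu <- c(E = 2.33, A = 2.155, C = 2.18, N = 2.32, O = 2.54)
  sdv <- c(E = 1.10, A = 1.65, C = 1.735, N = 1.37, O = 1.295)
  for (tr in TRAIT_NAMES) {
    expected <- trunc_mean(mu[tr], sdv[tr], 1, 5)
    expect_lt(abs(means[tr] - expected), 3 * sds_emp[tr] / sqrt(n))
  }
})

test_that("stimulus sequences follow the block protocol and sorting rule", {
  ev <- generate_stimulus_sequence(seed = 2)
  expect_equal(sum(ev$modality == "image"), 90)
  expect_equal(sum(ev$modality == "video"), 3)
  expect_setequal(unique(ev$category), EMOTION_CATEGORIES)

  # within each block the image arousal+valence score is non-decreasing,
  # and the video closes the block
  for (cat in EMOTION_CATEGORIES) {
    block <- ev[ev$category == cat, ]
    block <- block[order(block$onset_sample), ]
    expect_equal(block$modality[nrow(block)], "video")
    score <- block$arousal[-nrow(block)] + block$valence[-nrow(block)]
    expect_true(all(diff(score) >= -1e-12))
  }
  expect_true(all(ev$arousal >= 1 & ev$arousal <= 7))
  expect_true(all(ev$valence >= 1 & ev$valence <= 7))

  # seeded block-order randomization: two seeds differ in about 2/3 of pairs
  orders <- vapply(1:40, function(s) {
    e <- generate_stimulus_sequence(seed = s, n_images = 2, image_s = 1,
                                    include_video = FALSE)
    paste(unique(e$category), collapse = "-")
  }, character(1))
  frac_diff <- mean(orders[-1] != orders[-40])
  expect_gt(frac_diff, 0.35)
  expect_gt(length(unique(orders)), 1)
})

test_that("synthetic EEG is deterministic and carries the configured beta effect", {
  cfg <- synth_config(n_images = 6, image_s = 2, include_video = FALSE,
                      seed = 3)
  sp <- list(subject_id = "T1", group = "normal",
             profile = personality_profile(3, 3, 3, 3, 3))
  ev <- generate_stimulus_sequence(seed = 9, n_images = 6, image_s = 2,
                                   include_video = FALSE)
  r1 <- synthesize_eeg(sp, ev, cfg, seed = 21)
  r2 <- synthesize_eeg(sp, ev, cfg, seed = 21)
  expect_identical(r1$data, r2$data)
  expect_equal(nrow(r1$data), 32)
  expect_equal(r1$rate, 256)

  # beta band power during high-arousal events exceeds low-arousal by the
  # configured multiplier (power oracle on the generated data)
  pow <- function(span, ch) band_power(r1$data[ch, span], 256, c(13, 30))
  ha <- ev[ev$arousal >= 3.5, ]; la <- ev[ev$arousal < 3.5, ]
  span_of <- function(e) unlist(lapply(seq_len(nrow(e)), function(i)
    (e$onset_sample[i] + 1):(e$onset_sample[i] + e$duration_samples[i])))
  if (nrow(ha) > 0 && nrow(la) > 0) {
    ratio <- mean(vapply(1:32, function(ch) pow(span_of(ha), ch), numeric(1))) /
      mean(vapply(1:32, function(ch) pow(span_of(la), ch), numeric(1)))
    expect_gt(ratio, 1.5)
  }

  over <- ev; over$onset_sample[2] <- over$onset_sample[1]
  expect_error(synthesize_eeg(sp, over, cfg), "overlapping")
})

test_that("alpha asymmetry flips with valence in the generated signal", {
  cfg <- synth_config(seed = 5)
  sp <- list(subject_id = "T2", group = "normal",
             profile = personality_profile(3, 3, 3, 3, 3))
  ev <- stimulus_events(c(512L, 5632L), c(5120L, 5120L), c("happy", "sad"),
                        c("image", "image"), c(5, 5), c(6.5, 1.5))
  rec <- synthesize_eeg(sp, ev, cfg, seed = 8)
  hemi <- hemisphere_of(rec$channel_labels)
  apow <- function(span, chs) mean(vapply(chs, function(ch)
    band_power(rec$data[ch, span], 256, c(8, 12)), numeric(1)))
  hv_span <- 513:5632; lv_span <- 5633:10752
  asym_hv <- log(apow(hv_span, which(hemi == "left")) /
                   apow(hv_span, which(hemi == "right")))
  asym_lv <- log(apow(lv_span, which(hemi == "left")) /
                   apow(lv_span, which(hemi == "right")))
  expect_gt(asym_hv, 0)
  expect_lt(asym_lv, 0)
})

test_that("trait coupling into alpha power is recoverable by regression", {
  cfg <- synth_config(seed = 6)
  Evals <- seq(1.2, 4.8, length.out = 30)
  apow <- vapply(seq_along(Evals), function(i) {
    sp <- list(subject_id = sprintf("R%02d", i), group = "normal",
               profile = personality_profile(Evals[i], 3, 3, 3, 3))
    ev <- stimulus_events(0L, 2560L, "neutral", "image", 3.5, 4)
    rec <- synthesize_eeg(sp, ev, cfg, seed = 500 + i)
    mean(vapply(1:8, function(ch) band_power(rec$data[ch, ], 256, c(8, 12)),
                numeric(1)))
  }, numeric(1))
  expect_gt(cor(apow, Evals), 0.5)
})

test_that("make_dataset produces one EDF per subject plus loadable sidecars", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_subjects_per_group = 2, n_images = 2, image_s = 1,
                      include_video = FALSE, seed = 12)
  ds <- make_dataset(cfg, out_dir = dir, write = TRUE)
  expect_length(ds$paths$edf, 6)
  expect_true(all(file.exists(ds$paths$edf)))
  expect_true(file.exists(ds$paths$manifest))

  expect_warning(tr <- load_traits(ds$paths$traits), NA)
  expect_length(tr, 6)
  expect_setequal(unique(ds$traits$group), SUBJECT_GROUPS)

  stim <- read.csv(ds$paths$stimuli)
  expect_equal(nrow(stim), 6 * 6)   # 6 subjects x (3 blocks x 2 images)

  # writing over an existing dataset is refused
  expect_error(make_dataset(cfg, out_dir = dir, write = TRUE), "overwrite")

  # the generator is a pure function of (cfg, seed)
  dir2 <- withr::local_tempdir()
  ds2 <- make_dataset(cfg, out_dir = dir2, write = TRUE)
  expect_identical(ds$recordings[["S01"]]$data, ds2$recordings[["S01"]]$data)
  expect_identical(ds$traits, ds2$traits)
})
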