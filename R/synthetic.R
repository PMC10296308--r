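# Synthetic EEG generator. Emulates the three-group cohort (Unstable
# Introvert / Unstable Extrovert / Normal) viewing per-category blocks of 30
# images plus one terminal video, with a signal model that gives the
# pipeline learnable structure:
#   - 1/f (pink) background per channel,
#   - band-limited theta/alpha/beta oscillations,
#   - arousal expressed as beta band-power modulation,
#   - valence expressed as the sign of a left/right alpha asymmetry,
#   - extroversion (by default) coupled into global alpha power,
#   - blink templates on frontal channels, white sensor noise.
# The emotion-to-physiology mapping is a modeling choice (a widely used
# heuristic), not a physiological claim; every effect size is configurable
# and can be nulled.

# Cohort trait statistics (questionnaire scale 1-5): means are the average
# of the female/male cohort rows, SDs likewise.
TRAIT_MEANS_DEFAULT <- c(E = 2.33, A = 2.155, C = 2.18, N = 2.32, O = 2.54)
TRAIT_SDS_DEFAULT <- c(E = 1.10, A = 1.65, C = 1.735, N = 1.37, O = 1.295)
GROUP_TRAIT_SHIFTS <- list(
  unstable_introvert = c(E = -0.9, N = 1.2),
  unstable_extrovert = c(E = 0.9, N = 1.2),
  normal = c()
)

# Stimulus rating distributions (PANAS-style 1-7 scale): per-category
# arousal mean/SD for images and videos; category-shifted valence means.
IMAGE_AROUSAL <- list(happy = c(3.74, 1.05), neutral = c(3.31, 0.94),
                      sad = c(3.52, 1.17))
VIDEO_AROUSAL <- list(happy = c(3.38, 0.82), neutral = c(3.66, 0.91),
                      sad = c(2.72, 1.08))
VALENCE_MEANS <- c(happy = 5.4, neutral = 4.0, sad = 2.6)

#' Synthetic dataset configuration
#'
#' @param n_subjects_per_group subjects per group (full cohort scale: 20).
#' @param rate sampling rate in Hz.
#' @param n_channels channel count (first \code{n_channels} labels of the
#'   default 32-channel 10-20 montage).
#' @param emotion_effect list: \code{beta_mult} (high-arousal beta power
#'   multiplier; low arousal uses its reciprocal) and \code{alpha_asym}
#'   (left/right alpha power ratio for high valence; inverted for low).
#'   Both 1.0 nulls the emotion structure.
#' @param trait_effect list: \code{trait} (which Big Five score couples into
#'   alpha power) and \code{coef} (0 nulls the coupling).
#' @param noise list: \code{pink_exponent}, \code{sensor_sd} (microvolts).
#' @param artifacts list: \code{blink_rate} (per second), \code{blink_amp}
#'   (microvolts).
#' @param band_amps RMS amplitudes (microvolts) of the theta/alpha/beta
#'   oscillations.
#' @param n_images,image_s,video_s,include_video stimulus protocol: images
#'   per category block, image/video durations in seconds.
#' @param seed master seed; all per-subject seeds derive from it.
#' @return list of class \code{synth_config}.
#' @export
synth_config <- function(n_subjects_per_group = 2, rate = 256, n_channels = 32,
                         emotion_effect = list(beta_mult = 2.0, alpha_asym = 1.5),
                         trait_effect = list(trait = "E", coef = 0.8),
                         noise = list(pink_exponent = 1.0, sensor_sd = 2.0),
                         artifacts = list(blink_rate = 0.1, blink_amp = 80),
                         band_amps = c(theta = 5, alpha = 8, beta = 4),
                         n_images = 30, image_s = 4, video_s = 60,
                         include_video = TRUE, seed = 1L) {
  if (rate <= 0) stop("rate must be > 0")
  if (emotion_effect$beta_mult <= 0 || emotion_effect$alpha_asym <= 0)
    stop("effect multipliers must be > 0")
  structure(list(n_subjects_per_group = n_subjects_per_group, rate = rate,
                 n_channels = n_channels, emotion_effect = emotion_effect,
                 trait_effect = trait_effect, noise = noise,
                 artifacts = artifacts, band_amps = band_amps,
                 n_images = n_images, image_s = image_s, video_s = video_s,
                 include_video = include_video, seed = as.integer(seed)),
            class = "synth_config")
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  u <- runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd))
  qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12), mean, sd)
}

#' Sample a Big Five profile for a subject group
#'
#' Trait scores are drawn from truncated normal distributions on the 1-5
#' item scale, centred on the cohort means with group shifts: both unstable
#' groups score high on neuroticism, the extrovert (introvert) group high
#' (low) on extroversion.
#'
#' @param group one of the three subject groups.
#' @param seed integer seed.
#' @param means,sds per-trait normal parameters before truncation.
#' @param bounds item scale bounds.
#' @return a \code{\link{personality_profile}}.
#' @export
sample_personality <- function(group, seed = 1L, means = TRAIT_MEANS_DEFAULT,
                               sds = TRAIT_SDS_DEFAULT, bounds = c(1, 5)) {
  if (!group %in% SUBJECT_GROUPS)
    stop("unknown group '", group, "'")
  shift <- GROUP_TRAIT_SHIFTS[[group]]
  m <- means
  if (length(shift) > 0) m[names(shift)] <- m[names(shift)] + shift
  sc <- with_seed(seed, {
    vapply(TRAIT_NAMES, function(tr)
      rtruncnorm1(1, m[tr], sds[tr], bounds[1], bounds[2]), numeric(1))
  })
  personality_profile(sc["E"], sc["A"], sc["C"], sc["N"], sc["O"])
}

#' Generate one subject's stimulus sequence
#'
#' Three category blocks (happy/sad/neutral) in seeded-random order; each
#' block holds \code{n_images} image events sorted ascending by their
#' arousal+valence score, optionally followed by one video event. Arousal
#' scores are drawn from the per-category image/video rating distributions;
#' valence from category-shifted normals; all on the 1-7 rating scale.
#'
#' @param seed integer seed.
#' @param rate sampling rate used to convert seconds to samples.
#' @param n_images images per block.
#' @param image_s,video_s stimulus durations in seconds.
#' @param include_video append the terminal video event to each block.
#' @param lead_s silence before the first block (seconds).
#' @param gap_s silence between blocks (seconds).
#' @return event data.frame as from \code{\link{stimulus_events}}.
#' @export
generate_stimulus_sequence <- function(seed = 1L, rate = 256, n_images = 30,
                                       image_s = 4, video_s = 60,
                                       include_video = TRUE, lead_s = 2,
                                       gap_s = 2) {
  with_seed(seed, {
    cats <- sample(EMOTION_CATEGORIES)
    onset <- lead_s * rate
    rows <- list()
    for (cat in cats) {
      ar <- rtruncnorm1(n_images, IMAGE_AROUSAL[[cat]][1],
                        IMAGE_AROUSAL[[cat]][2], 1, 7)
      va <- rtruncnorm1(n_images, VALENCE_MEANS[[cat]], 0.7, 1, 7)
      ord <- order(ar + va)
      ar <- ar[ord]; va <- va[ord]
      for (i in seq_len(n_images)) {
        rows[[length(rows) + 1]] <- data.frame(
          onset_sample = as.integer(round(onset)),
          duration_samples = as.integer(round(image_s * rate)),
          category = cat, modality = "image", arousal = ar[i], valence = va[i],
          stringsAsFactors = FALSE)
        onset <- onset + image_s * rate
      }
      if (include_video) {
        ar_v <- rtruncnorm1(1, VIDEO_AROUSAL[[cat]][1], VIDEO_AROUSAL[[cat]][2], 1, 7)
        va_v <- rtruncnorm1(1, VALENCE_MEANS[[cat]], 0.7, 1, 7)
        rows[[length(rows) + 1]] <- data.frame(
          onset_sample = as.integer(round(onset)),
          duration_samples = as.integer(round(video_s * rate)),
          category = cat, modality = "video", arousal = ar_v, valence = va_v,
          stringsAsFactors = FALSE)
        onset <- onset + video_s * rate
      }
      onset <- onset + gap_s * rate
    }
    ev <- do.call(rbind, rows)
    stimulus_events(ev$onset_sample, ev$duration_samples, ev$category,
                    ev$modality, ev$arousal, ev$valence)
  })
}

# 1/f^a noise of length n, unit variance, via spectral shaping.
pink_noise <- function(n, exponent = 1) {
  nf <- 2^ceiling(log2(max(n, 2)))
  w <- rnorm(nf)
  W <- fft(w)
  f <- c(1, seq_len(nf - 1))                # avoid DC blow-up
  f <- pmin(f, nf - f + 1)                  # symmetric frequency index
  W <- W * (1 / f^(exponent / 2))
  x <- Re(fft(W, inverse = TRUE)) / nf
  x <- x[seq_len(n)]
  x / sd(x)
}

band_noise <- function(n, rate, band) {
  flt <- signal::butter(4, band / (rate / 2), type = "pass")
  x <- as.numeric(signal::filter(flt, rnorm(n + 2 * rate)))
  x <- x[(2 * rate + 1):(2 * rate + n)]     # drop warm-up transient
  x / sd(x)
}

blink_template <- function(rate, dur_s = 0.4) {
  t <- seq(0, dur_s, by = 1 / rate)
  0.5 * (1 - cos(2 * pi * t / dur_s))       # raised cosine, unit peak
}

#' Synthesize one subject's EEG recording
#'
#' See the module description for the signal model. The recording is a pure
#' function of \code{(subject, events, cfg, seed)}.
#'
#' @param subject list with \code{subject_id}, \code{group} and
#'   \code{profile} (a \code{\link{personality_profile}}), as produced by
#'   \code{\link{make_dataset}}; a bare subject id string is also accepted
#'   (traits then default to the scale midpoint).
#' @param events stimulus event table (non-overlapping).
#' @param cfg a \code{\link{synth_config}}.
#' @param seed integer seed for this recording.
#' @return an \code{\link{eeg_recording}} at \code{cfg$rate} with
#'   \code{cfg$n_channels} channels.
#' @export
synthesize_eeg <- function(subject, events, cfg = synth_config(), seed = 1L) {
  if (is.character(subject))
    subject <- list(subject_id = subject, group = NA_character_,
                    profile = personality_profile(3, 3, 3, 3, 3))
  if (nrow(events) > 1) {
    ev_sorted <- events[order(events$onset_sample), ]
    if (any(ev_sorted$onset_sample[-1] <
            head(ev_sorted$onset_sample + ev_sorted$duration_samples, -1)))
      stop("overlapping events are not supported")
  }
  rate <- cfg$rate
  labels <- DEFAULT_MONTAGE_32[seq_len(cfg$n_channels)]
  n <- max(events$onset_sample + events$duration_samples, 0) + 2L * rate
  hemi <- hemisphere_of(labels)
  frontal <- grepl("^(Fp|AF)", labels)

  # Band-power envelopes (amplitude domain = sqrt of power multipliers).
  beta_env <- rep(1, n)
  alpha_env_l <- rep(1, n)
  alpha_env_r <- rep(1, n)
  bm <- sqrt(cfg$emotion_effect$beta_mult)
  as_ <- sqrt(cfg$emotion_effect$alpha_asym)
  for (k in seq_len(nrow(events))) {
    span <- (events$onset_sample[k] + 1):(events$onset_sample[k] +
                                            events$duration_samples[k])
    ha <- events$arousal[k] >= AROUSAL_SPLIT
    hv <- events$valence[k] >= VALENCE_SPLIT
    beta_env[span] <- if (ha) bm else 1 / bm
    alpha_env_l[span] <- if (hv) as_ else 1 / as_
    alpha_env_r[span] <- if (hv) 1 / as_ else as_
  }

  # Trait coupling into global alpha amplitude.
  tr_name <- cfg$trait_effect$trait
  tr_val <- unclass(subject$profile)[tr_name]
  alpha_gain <- sqrt(max(1 + cfg$trait_effect$coef * (tr_val - 3) / 2, 0.05))

  amps <- cfg$band_amps
  bands <- list(theta = c(4, 8), alpha = c(8, 12), beta = c(13, 30))
  data <- with_seed(seed, {
    m <- matrix(0, cfg$n_channels, n)
    for (ch in seq_len(cfg$n_channels)) {
      x <- 10 * pink_noise(n, cfg$noise$pink_exponent)
      x <- x + amps["theta"] * band_noise(n, rate, bands$theta)
      a_env <- if (hemi[ch] == "left") alpha_env_l
               else if (hemi[ch] == "right") alpha_env_r else rep(1, n)
      x <- x + amps["alpha"] * alpha_gain * a_env * band_noise(n, rate, bands$alpha)
      x <- x + amps["beta"] * beta_env * band_noise(n, rate, bands$beta)
      x <- x + cfg$noise$sensor_sd * rnorm(n)
      m[ch, ] <- x
    }
    if (cfg$artifacts$blink_rate > 0 && any(frontal)) {
      tpl <- blink_template(rate) * cfg$artifacts$blink_amp
      n_blinks <- rpois(1, cfg$artifacts$blink_rate * n / rate)
      if (n_blinks > 0) {
        starts <- sort(sample.int(n - length(tpl), n_blinks))
        for (s0 in starts) {
          span <- s0:(s0 + length(tpl) - 1)
          for (ch in which(frontal)) m[ch, span] <- m[ch, span] + tpl
        }
      }
    }
    m
  })
  eeg_recording(data, rate, labels, subject_id = subject$subject_id,
                group = subject$group, events = events)
}

#' Generate a full synthetic dataset
#'
#' One recording per subject across the three groups, with sidecar trait and
#' stimulus tables. With \code{write = TRUE} the recordings are stored as
#' EDF files plus \code{traits.csv}, \code{stimuli.csv} and a
#' \code{manifest.json} recording the configuration and seeds.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param out_dir output directory (created if needed) when writing.
#' @param write write EDF + CSV artifacts to \code{out_dir}.
#' @return list with \code{subjects} (specs), \code{recordings} (in-memory
#'   list, kept also when writing), \code{traits} (data.frame),
#'   \code{stimuli} (data.frame) and \code{paths} when written.
#' @export
make_dataset <- function(cfg = synth_config(), out_dir = NULL, write = !is.null(out_dir)) {
  if (write) {
    if (is.null(out_dir)) stop("out_dir required when write = TRUE")
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  }
  subjects <- list()
  k <- 0
  for (g in SUBJECT_GROUPS) {
    for (i in seq_len(cfg$n_subjects_per_group)) {
      k <- k + 1
      sid <- sprintf("S%02d", k)
      subjects[[sid]] <- list(
        subject_id = sid, group = g,
        profile = sample_personality(g, seed = cfg$seed * 131L + k),
        seed_events = cfg$seed * 977L + k,
        seed_signal = cfg$seed * 389L + k)
    }
  }
  recordings <- list()
  stim_rows <- list()
  for (sid in names(subjects)) {
    sp <- subjects[[sid]]
    ev <- generate_stimulus_sequence(sp$seed_events, rate = cfg$rate,
                                     n_images = cfg$n_images,
                                     image_s = cfg$image_s,
                                     video_s = cfg$video_s,
                                     include_video = cfg$include_video)
    recordings[[sid]] <- synthesize_eeg(sp, ev, cfg, seed = sp$seed_signal)
    stim_rows[[sid]] <- data.frame(
      subject_id = sid,
      stimulus_id = sprintf("%s_%03d", sid, seq_len(nrow(ev))),
      category = ev$category, modality = ev$modality,
      arousal = ev$arousal, valence = ev$valence,
      onset_s = ev$onset_sample / cfg$rate,
      duration_s = ev$duration_samples / cfg$rate,
      stringsAsFactors = FALSE)
  }
  traits <- do.call(rbind, lapply(subjects, function(sp) {
    p <- unclass(sp$profile)
    data.frame(subject_id = sp$subject_id, E = p["E"], A = p["A"], C = p["C"],
               N = p["N"], O = p["O"], group = sp$group,
               stringsAsFactors = FALSE)
  }))
  rownames(traits) <- NULL
  stimuli <- do.call(rbind, stim_rows)
  rownames(stimuli) <- NULL

  out <- list(subjects = subjects, recordings = recordings, traits = traits,
              stimuli = stimuli)
  if (write) {
    edf_paths <- character()
    for (sid in names(recordings)) {
      p <- file.path(out_dir, paste0(sid, ".edf"))
      if (file.exists(p)) stop("refusing to overwrite existing file: ", p)
      write_edf(recordings[[sid]], p)
      edf_paths[sid] <- p
    }
    tp <- file.path(out_dir, "traits.csv")
    sp_ <- file.path(out_dir, "stimuli.csv")
    mp <- file.path(out_dir, "manifest.json")
    write.csv(traits, tp, row.names = FALSE)
    write.csv(stimuli, sp_, row.names = FALSE)
    jsonlite::write_json(
      list(config = unclass(cfg),
           subjects = lapply(subjects, function(s)
             list(subject_id = s$subject_id, group = s$group,
                  seed_events = s$seed_events, seed_signal = s$seed_signal))),
      mp, auto_unbox = TRUE, digits = NA)
    out$paths <- list(edf = edf_paths, traits = tp, stimuli = sp_, manifest = mp)
  }
  out
}
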