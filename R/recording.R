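#' @importFrom stats fft rnorm runif sd cor median pnorm qnorm rpois predict
#' @importFrom utils read.csv write.csv head modifyList
NULL

#' Extended 10-20 electrode label vocabulary
#'
#' Electrode names accepted by \code{\link{validate_recording}}.
#' @export
TEN_TWENTY_LABELS <- c(
  "Fp1", "Fp2", "Fpz", "AF3", "AF4", "AF7", "AF8", "AFz",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT7", "FT8", "FT9", "FT10", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
  "T7", "T8", "T3", "T4", "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
  "TP7", "TP8", "TP9", "TP10", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "T5", "T6",
  "PO3", "PO4", "PO7", "PO8", "PO9", "PO10", "POz", "O1", "Oz", "O2"
)

#' Default 32-channel 10-20 montage of the recording protocol
#' @export
DEFAULT_MONTAGE_32 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
  "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
  "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
  "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10"
)

#' Subject screening groups
#' @export
SUBJECT_GROUPS <- c("unstable_introvert", "unstable_extrovert", "normal")

#' Stimulus emotion categories
#' @export
EMOTION_CATEGORIES <- c("happy", "sad", "neutral")

STIMULUS_MODALITIES <- c("image", "video")

#' Arousal-valence quadrant labels
#' @export
EMOTION_QUADRANTS <- c("HV_HA", "HV_LA", "LV_HA", "LV_LA")

#' Construct a stimulus event table
#'
#' Events mark stimulus presentations inside a recording. Sample indices are
#' 0-based; an event covers the half-open interval
#' \code{[onset_sample, onset_sample + duration_samples)}.
#'
#' @param onset_sample integer vector of 0-based onset samples.
#' @param duration_samples integer vector of durations in samples (> 0).
#' @param category character vector, one of \code{"happy"}, \code{"sad"},
#'   \code{"neutral"}.
#' @param modality character vector, \code{"image"} or \code{"video"}.
#' @param arousal,valence numeric affect scores on the stimulus rating scale.
#' @return a \code{data.frame} with one row per event.
#' @export
stimulus_events <- function(onset_sample = integer(), duration_samples = integer(),
                            category = character(), modality = character(),
                            arousal = numeric(), valence = numeric()) {
  ev <- data.frame(
    onset_sample = as.integer(onset_sample),
    duration_samples = as.integer(duration_samples),
    category = as.character(category),
    modality = as.character(modality),
    arousal = as.numeric(arousal),
    valence = as.numeric(valence),
    stringsAsFactors = FALSE
  )
  if (nrow(ev) > 0) {
    if (any(ev$onset_sample < 0)) stop("event onset_sample must be >= 0")
    if (any(ev$duration_samples <= 0)) stop("event duration_samples must be > 0")
    if (!all(ev$category %in% EMOTION_CATEGORIES))
      stop("unknown event category; expected one of ",
           paste(EMOTION_CATEGORIES, collapse = ", "))
    if (!all(ev$modality %in% STIMULUS_MODALITIES))
      stop("unknown event modality")
    if (!all(is.finite(ev$arousal)) || !all(is.finite(ev$valence)))
      stop("arousal/valence scores must be finite")
  }
  ev
}

#' Construct an EEG recording
#'
#' The core container of the package: a channels-by-samples matrix in
#' microvolts plus sampling rate, 10-20 montage labels, subject identity and
#' stimulus events.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param rate sampling rate in Hz (> 0).
#' @param channel_labels character vector of unique electrode names, one per
#'   row of \code{data}.
#' @param subject_id opaque subject identifier string.
#' @param group one of \code{"unstable_introvert"}, \code{"unstable_extrovert"},
#'   \code{"normal"}, or \code{NA} when unknown.
#' @param events event table from \code{\link{stimulus_events}}.
#' @return an object of class \code{eeg_recording}.
#' @export
eeg_recording <- function(data, rate, channel_labels,
                          subject_id = "anonymous", group = NA_character_,
                          events = stimulus_events()) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be a numeric matrix")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length (", length(channel_labels),
         ") must equal channel count (", nrow(data), ")")
  if (anyDuplicated(channel_labels))
    stop("channel_labels must be unique")
  if (!is.na(group) && !group %in% SUBJECT_GROUPS)
    stop("group must be one of ", paste(SUBJECT_GROUPS, collapse = ", "))
  if (nrow(events) > 0) {
    ends <- events$onset_sample + events$duration_samples
    if (any(ends > ncol(data)))
      stop("event extends past end of recording (", max(ends), " > ",
           ncol(data), " samples)")
  }
  structure(
    list(data = data, rate = rate, channel_labels = channel_labels,
         subject_id = subject_id, group = group, events = events),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  cat(sprintf("  subject: %s  group: %s  events: %d\n",
              x$subject_id, x$group, nrow(x$events)))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)

#' Validate a recording against the extended 10-20 montage
#'
#' Checks recording invariants and reports channel labels outside the extended
#' 10-20 vocabulary. Unknown labels produce a warning, not an error: research
#' montages routinely include reference or peripheral channels.
#'
#' @param rec an \code{eeg_recording}.
#' @return (invisibly) a list with \code{ok}, \code{unknown_labels} and
#'   \code{messages}; suitable for serialization as a JSON validation report.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  unknown <- setdiff(rec$channel_labels, TEN_TWENTY_LABELS)
  msgs <- character()
  if (length(unknown) > 0) {
    msg <- paste0("channel labels outside extended 10-20 set: ",
                  paste(unknown, collapse = ", "))
    warning(msg, call. = FALSE)
    msgs <- c(msgs, msg)
  }
  out <- list(ok = length(msgs) == 0, unknown_labels = unknown, messages = msgs)
  invisible(out)
}

#' Hemisphere membership of 10-20 electrode labels
#'
#' Follows the 10-20 naming convention: odd trailing digit = left
#' hemisphere, even = right, letter suffix (z) = midline.
#'
#' @param labels character vector of electrode names.
#' @return character vector of \code{"left"}, \code{"right"},
#'   \code{"midline"}.
#' @export
hemisphere_of <- function(labels) {
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", labels)))
  out <- rep("midline", length(labels))
  out[!is.na(num) & num %% 2L == 1L] <- "left"
  out[!is.na(num) & num %% 2L == 0L] <- "right"
  out
}

# Median-split thresholds on the 1-7 rating scale. The arousal split sits at
# the median of the category rating mixture (the published distributions
# centre near 3.3-3.7), the valence split at 4 (happy/sad valence means are
# symmetric about it); this keeps the four quadrants near-balanced so that
# 4-class chance is 25%.
AROUSAL_SPLIT <- 3.5
VALENCE_SPLIT <- 4

# Map arousal/valence scores to a quadrant label.
quadrant_label <- function(arousal, valence, arousal_mid = AROUSAL_SPLIT,
                           valence_mid = VALENCE_SPLIT) {
  hv <- valence >= valence_mid
  ha <- arousal >= arousal_mid
  ifelse(hv & ha, "HV_HA",
         ifelse(hv & !ha, "HV_LA",
                ifelse(!hv & ha, "LV_HA", "LV_LA")))
}
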