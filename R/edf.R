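# EDF (European Data Format) reading and writing.
#
# Implements the 16-bit EDF encoding with an EDF+ style "EDF Annotations"
# signal carrying stimulus events as time-stamped annotation lists (TALs).
# Only the subset needed as an interchange carrier is supported: one
# continuous recording, identical record structure for all signals.
# Constraint: the true sample count is stored in the reserved header field
# ("EEGNS=<n>") because the final data record is zero-padded to a whole
# record; readers unaware of the tag see trailing zeros, our reader trims.

EDF_HEADER_BYTES <- 256L

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

num_field <- function(x, width) {
  s <- format(x, trim = TRUE, scientific = FALSE)
  if (nchar(s) > width) s <- substr(s, 1, width)
  pad_field(s, width)
}

# Render seconds so that round(x * rate) is recovered exactly on re-read.
fmt_seconds <- function(x) {
  s <- formatC(x, format = "f", digits = 7, drop0trailing = TRUE)
  sub("\\.$", "", s)
}

# Render a physical range bound into <= 8 ASCII chars and return both the
# string and the value it parses back to, so quantization can use the
# as-written value (header truncation must not corrupt the scale).
fmt_phys <- function(v) {
  for (digs in 7:1) {
    s <- formatC(signif(v, digs), format = "fg", digits = digs, flag = "-")
    s <- trimws(s)
    if (nchar(s) <= 8) return(list(str = s, val = as.numeric(s)))
  }
  s <- formatC(v, format = "g", digits = 2)
  list(str = substr(trimws(s), 1, 8), val = as.numeric(substr(trimws(s), 1, 8)))
}

#' Write a recording to an EDF file
#'
#' One EDF signal per channel (physical dimension microvolts, 16-bit digital
#' range) plus an annotations signal holding each stimulus event as
#' \code{"category/modality/arousal/valence"}. Event onsets and durations are
#' stored in seconds and recovered exactly (integer samples) on re-read.
#'
#' @param rec an \code{\link{eeg_recording}} with finite samples.
#' @param path output file path.
#' @return (invisibly) \code{path}.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!all(is.finite(rec$data)))
    stop("recording contains non-finite samples; cannot encode to EDF")
  nchan <- n_channels(rec)
  nsamp <- n_samples(rec)
  if (nchan == 0 || nsamp == 0) stop("cannot write an empty recording")

  if (rec$rate == round(rec$rate) && nsamp > rec$rate) {
    rec_dur <- 1
    spr <- as.integer(rec$rate)            # samples per record per channel
  } else {
    rec_dur <- nsamp / rec$rate            # single-record fallback
    spr <- nsamp
  }
  n_rec <- as.integer(ceiling(nsamp / spr))

  # Per-channel linear 16-bit quantization over the observed physical range.
  dig_min <- -32768L; dig_max <- 32767L
  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  flat <- phys_max - phys_min < .Machine$double.eps
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  pmin_f <- lapply(phys_min, fmt_phys)
  pmax_f <- lapply(phys_max, fmt_phys)
  # widen as-written bounds so every sample stays inside the written range
  for (i in seq_len(nchan)) {
    if (pmin_f[[i]]$val > phys_min[i]) pmin_f[[i]] <- fmt_phys(phys_min[i] - abs(phys_min[i]) * 1e-5 - 1e-4)
    if (pmax_f[[i]]$val < phys_max[i]) pmax_f[[i]] <- fmt_phys(phys_max[i] + abs(phys_max[i]) * 1e-5 + 1e-4)
  }
  phys_min <- vapply(pmin_f, function(z) z$val, numeric(1))
  phys_max <- vapply(pmax_f, function(z) z$val, numeric(1))

  # Annotation payload: one timestamp TAL per record, event TALs in record 1.
  # TALs are NUL-terminated; NUL cannot live in an R string, so payloads are
  # raw vectors.
  NUL <- as.raw(0)
  tal_events <- if (nrow(rec$events) > 0) {
    do.call(c, lapply(seq_len(nrow(rec$events)), function(i) c(charToRaw(
      paste0("+", fmt_seconds(rec$events$onset_sample[i] / rec$rate),
             "\x15", fmt_seconds(rec$events$duration_samples[i] / rec$rate),
             "\x14",
             rec$events$category[i], "/", rec$events$modality[i], "/",
             format(rec$events$arousal[i], trim = TRUE, scientific = FALSE), "/",
             format(rec$events$valence[i], trim = TRUE, scientific = FALSE),
             "\x14")), NUL)))
  } else raw(0)
  tal_stamp <- function(r)
    c(charToRaw(paste0("+", fmt_seconds((r - 1) * rec_dur), "\x14\x14")), NUL)
  ann_payloads <- lapply(seq_len(n_rec), function(r) {
    if (r == 1) c(tal_stamp(r), tal_events) else tal_stamp(r)
  })
  ann_bytes <- max(lengths(ann_payloads))
  ann_spr <- as.integer(ceiling(ann_bytes / 2))  # 2 bytes per "sample"

  ns_total <- nchan + 1L
  header_bytes <- EDF_HEADER_BYTES * (1L + ns_total)

  con <- file(path, "wb")
  on.exit(close(con))
  wtext <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)

  wtext(pad_field("0", 8))                             # version
  wtext(pad_field(rec$subject_id, 80))                 # patient id
  wtext(pad_field("Startdate 01-JAN-2000", 80))        # recording id
  wtext(pad_field("01.01.00", 8))                      # start date
  wtext(pad_field("00.00.00", 8))                      # start time
  wtext(num_field(header_bytes, 8))
  wtext(pad_field(paste0("EDF+C EEGNS=", nsamp), 44))  # reserved + true count
  wtext(num_field(n_rec, 8))
  wtext(num_field(rec_dur, 8))
  wtext(num_field(ns_total, 4))

  labels <- c(rec$channel_labels, "EDF Annotations")
  for (l in labels) wtext(pad_field(l, 16))
  for (i in seq_len(ns_total)) wtext(pad_field("", 80))          # transducer
  wtext(paste(vapply(seq_len(nchan), function(i) pad_field("uV", 8),
                     character(1)), collapse = ""))
  wtext(pad_field("", 8))                                        # ann phys dim
  for (s in c(vapply(pmin_f, function(z) z$str, character(1)), "-1"))
    wtext(pad_field(s, 8))
  for (s in c(vapply(pmax_f, function(z) z$str, character(1)), "1"))
    wtext(pad_field(s, 8))
  for (i in seq_len(ns_total)) wtext(num_field(dig_min, 8))
  for (i in seq_len(ns_total)) wtext(num_field(dig_max, 8))
  for (i in seq_len(ns_total)) wtext(pad_field("", 80))          # prefilter
  for (v in c(rep(spr, nchan), ann_spr)) wtext(num_field(v, 8))
  for (i in seq_len(ns_total)) wtext(pad_field("", 32))          # reserved

  # Quantize once; pad the tail record with digital zeros.
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  total <- n_rec * spr
  dig <- matrix(0L, nchan, total)
  for (i in seq_len(nchan)) {
    d <- round((rec$data[i, ] - phys_min[i]) * scale[i]) + dig_min
    dig[i, seq_len(nsamp)] <- as.integer(pmin(pmax(d, dig_min), dig_max))
  }

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
    # annotations channel, zero-padded to ann_spr * 2 bytes
    raw_pay <- ann_payloads[[r]]
    raw_pay <- c(raw_pay, raw(ann_spr * 2 - length(raw_pay)))
    writeBin(raw_pay, con)
  }
  invisible(path)
}

parse_tals <- function(raw_bytes, rate) {
  # TALs are NUL-terminated; split the raw stream on 0x00, then split each
  # TAL on \x14 into onset[\x15duration] and annotation texts.
  nul <- which(raw_bytes == as.raw(0))
  starts <- c(1L, nul + 1L)
  ends <- c(nul - 1L, length(raw_bytes))
  chunks <- vapply(seq_along(starts), function(i) {
    if (starts[i] > ends[i]) "" else rawToChar(raw_bytes[starts[i]:ends[i]])
  }, character(1))
  ev <- list()
  for (ch in chunks) {
    if (ch == "") next
    parts <- strsplit(ch, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2 || all(parts[-1] == "")) next  # bare timestamp TAL
    od <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    onset_s <- as.numeric(od[1])
    dur_s <- if (length(od) > 1) as.numeric(od[2]) else 0
    for (text in parts[-1]) {
      if (text == "") next
      f <- strsplit(text, "/", fixed = TRUE)[[1]]
      if (length(f) != 4) next  # not one of our event annotations
      ev[[length(ev) + 1]] <- data.frame(
        onset_sample = as.integer(round(onset_s * rate)),
        duration_samples = as.integer(round(dur_s * rate)),
        category = f[1], modality = f[2],
        arousal = as.numeric(f[3]), valence = as.numeric(f[4]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(ev) == 0) stimulus_events() else do.call(rbind, ev)
}

#' Read an EDF file into a recording
#'
#' Reads the 16-bit EDF encoding written by \code{\link{write_edf}} (and plain
#' EDF from other writers with a uniform record layout). Stimulus events are
#' recovered from an "EDF Annotations" signal when present. Channel labels
#' outside the extended 10-20 vocabulary trigger a validation warning but the
#' load succeeds.
#'
#' @param path path to an EDF file.
#' @param group optional subject group to attach (EDF has no field for it;
#'   group membership travels in a sidecar table).
#' @return an \code{\link{eeg_recording}}.
#' @export
read_edf <- function(path, group = NA_character_) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < EDF_HEADER_BYTES) stop("not a valid EDF file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rfield <- function(width) {
    trimws(readChar(con, width, useBytes = TRUE))
  }
  version <- rfield(8)
  if (version != "0") stop("not a valid EDF file (bad version field): ", path)
  patient <- rfield(80)
  rfield(80); rfield(8); rfield(8)
  header_bytes <- as.integer(rfield(8))
  reserved <- rfield(44)
  n_rec <- as.integer(rfield(8))
  rec_dur <- as.numeric(rfield(8))
  ns <- as.integer(rfield(4))
  if (is.na(ns) || ns < 1) stop("EDF file declares zero signals: ", path)

  sig_field <- function(width, type = c("chr", "num")) {
    type <- match.arg(type)
    out <- vapply(seq_len(ns), function(i) rfield(width), character(1))
    if (type == "num") as.numeric(out) else out
  }
  labels <- sig_field(16)
  sig_field(80)
  phys_dim <- sig_field(8)
  phys_min <- sig_field(8, "num")
  phys_max <- sig_field(8, "num")
  dig_min <- sig_field(8, "num")
  dig_max <- sig_field(8, "num")
  sig_field(80)
  spr <- as.integer(sig_field(8))
  sig_field(32)

  is_ann <- labels == "EDF Annotations"
  chan_idx <- which(!is_ann)
  if (length(chan_idx) == 0) stop("EDF file contains no data channels: ", path)
  if (rec_dur <= 0) stop("invalid record duration in EDF header")
  rate <- spr[chan_idx[1]] / rec_dur
  if (any(spr[chan_idx] != spr[chan_idx[1]]))
    stop("per-channel sampling rates differ; not supported")

  total <- n_rec * spr[chan_idx[1]]
  data <- matrix(0, length(chan_idx), total)
  ann_raw <- raw(0)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      if (is_ann[s]) {
        ann_raw <- c(ann_raw, readBin(con, "raw", n = spr[s] * 2))
      } else {
        v <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
        if (length(v) < spr[s]) stop("EDF file truncated: ", path)
        k <- which(chan_idx == s)
        g <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
        data[k, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
          (v - dig_min[s]) * g + phys_min[s]
      }
    }
  }

  true_n <- regmatches(reserved, regexpr("EEGNS=[0-9]+", reserved))
  if (length(true_n) == 1) {
    n_keep <- as.integer(sub("EEGNS=", "", true_n))
    data <- data[, seq_len(min(n_keep, total)), drop = FALSE]
  }

  events <- if (any(is_ann)) parse_tals(ann_raw, rate) else stimulus_events()
  rec <- eeg_recording(data, rate, labels[chan_idx],
                       subject_id = patient, group = group, events = events)
  validate_recording(rec)
  rec
}
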