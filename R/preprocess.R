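# Preprocessing chain: decimation, zero-phase Butterworth band-pass,
# power-line notch, ICA blink removal, overlapping windows, baseline
# adjustment. All filters are applied forward-backward (zero phase) so event
# latencies are preserved.

filtfilt_rows <- function(data, flt) {
  out <- data
  for (i in seq_len(nrow(data))) out[i, ] <- signal::filtfilt(flt, data[i, ])
  out
}

#' Downsample a recording
#'
#' Anti-alias filters and decimates each channel; event onsets and durations
#' are rescaled by the rate ratio and rounded to the nearest sample.
#'
#' @param rec an \code{\link{eeg_recording}}.
#' @param target_rate new sampling rate in Hz; must not exceed \code{rec$rate}
#'   and must divide it to an integer factor.
#' @return the downsampled \code{eeg_recording}.
#' @export
downsample <- function(rec, target_rate = 128) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_rate > rec$rate)
    stop("target_rate (", target_rate, ") exceeds recording rate (", rec$rate, ")")
  if (target_rate == rec$rate) return(rec)
  q <- rec$rate / target_rate
  if (abs(q - round(q)) > 1e-9)
    stop("target_rate must divide the recording rate (factor ", q, " not integer)")
  q <- as.integer(round(q))
  # 8th-order low-pass at 80% of the new Nyquist, zero-phase, then decimate.
  aa <- signal::butter(8, 0.8 / q, type = "low")
  filt <- filtfilt_rows(rec$data, aa)
  keep <- seq(1, ncol(filt), by = q)
  ev <- rec$events
  if (nrow(ev) > 0) {
    ev$onset_sample <- as.integer(round(ev$onset_sample / q))
    ev$duration_samples <- pmax(1L, as.integer(round(ev$duration_samples / q)))
    over <- ev$onset_sample + ev$duration_samples > length(keep)
    ev$duration_samples[over] <- length(keep) - ev$onset_sample[over]
  }
  eeg_recording(filt[, keep, drop = FALSE], target_rate, rec$channel_labels,
                rec$subject_id, rec$group, ev)
}

#' Band-pass filter a recording
#'
#' Butterworth band-pass (default order 2, 0.4-60 Hz), applied forward and
#' backward for zero phase distortion.
#'
#' @param rec an \code{\link{eeg_recording}}.
#' @param low_hz,high_hz band edges in Hz; both must lie inside the Nyquist
#'   interval.
#' @param order Butterworth order of the one-way prototype.
#' @return the filtered \code{eeg_recording}.
#' @export
bandpass <- function(rec, low_hz = 0.4, high_hz = 60, order = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$rate / 2
  if (low_hz <= 0 || high_hz <= low_hz) stop("need 0 < low_hz < high_hz")
  if (high_hz >= nyq)
    stop("high band edge (", high_hz, " Hz) must be below Nyquist (", nyq, " Hz)")
  flt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- rec
  out$data <- filtfilt_rows(rec$data, flt)
  out
}

#' Notch filter for power-line noise
#'
#' Zero-phase Butterworth band-stop around \code{center_hz} (default 50 Hz
#' mains), stop band \code{center_hz +- width_hz}.
#'
#' @param rec an \code{\link{eeg_recording}}.
#' @param center_hz line frequency to suppress; must be below Nyquist.
#' @param width_hz half-width of the stop band in Hz.
#' @param order Butterworth order of the one-way prototype.
#' @return the filtered \code{eeg_recording}.
#' @export
notch <- function(rec, center_hz = 50, width_hz = 2, order = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$rate / 2
  if (center_hz >= nyq)
    stop("notch center (", center_hz, " Hz) must be below Nyquist (", nyq, " Hz)")
  edges <- c(center_hz - width_hz, center_hz + width_hz) / nyq
  flt <- signal::butter(order, pmin(pmax(edges, 1e-4), 1 - 1e-4), type = "stop")
  out <- rec
  out$data <- filtfilt_rows(rec$data, flt)
  out
}

# Symmetric FastICA with the logcosh contrast, seeded and deterministic.
# Returns unmixing W (comp x chan, applied to whitened data), whitening K and
# sources S = W K X.
fastica_decompose <- function(X, n_comp = nrow(X), maxit = 200, tol = 1e-6,
                              seed = 1L) {
  Xc <- X - rowMeans(X)
  cv <- tcrossprod(Xc) / ncol(Xc)
  eg <- eigen(cv, symmetric = TRUE)
  d <- pmax(eg$values[seq_len(n_comp)], .Machine$double.eps)
  K <- diag(1 / sqrt(d), n_comp) %*% t(eg$vectors[, seq_len(n_comp), drop = FALSE])
  Z <- K %*% Xc
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  W <- matrix(rnorm(n_comp * n_comp), n_comp)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  orth <- function(W) {
    sv <- svd(W)
    sv$u %*% t(sv$v)
  }
  W <- orth(W)
  for (it in seq_len(maxit)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime <- rowMeans(1 - G^2)
    W1 <- (G %*% t(Z)) / ncol(Z) - diag(gprime, n_comp) %*% W
    W1 <- orth(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  list(W = W, K = K, S = W %*% Z, means = rowMeans(X), iterations = it)
}

#' Remove artifact components with ICA
#'
#' Decomposes the recording with a seeded symmetric FastICA and zeroes every
#' component whose time course correlates (absolutely) with a frontal blink
#' proxy above \code{reject_threshold} before back-projection. The proxy is
#' the mean of the frontal (Fp*/AF*) channels, falling back to the first two
#' channels when no frontal labels are present.
#'
#' @param rec an \code{\link{eeg_recording}} with at least 20 samples per
#'   channel component.
#' @param reject_threshold absolute correlation above which a component is
#'   considered a blink component (default 0.8).
#' @param seed integer seed for the decomposition (deterministic reports).
#' @param maxit FastICA iteration cap.
#' @return list with the cleaned \code{recording} and a \code{report}
#'   data.frame of component index, correlation and removal flag.
#' @export
remove_artifacts_ica <- function(rec, reject_threshold = 0.8, seed = 1L,
                                 maxit = 200) {
  stopifnot(inherits(rec, "eeg_recording"))
  nc <- n_channels(rec)
  if (n_samples(rec) < 20 * nc)
    stop("too few samples for a stable decomposition (need >= 20 x channels)")
  frontal <- grepl("^(Fp|AF)", rec$channel_labels)
  if (!any(frontal)) frontal <- seq_len(nc) <= 2
  proxy <- colMeans(rec$data[frontal, , drop = FALSE])

  dec <- fastica_decompose(rec$data, n_comp = nc, maxit = maxit, seed = seed)
  cors <- as.numeric(cor(t(dec$S), proxy))
  cors[is.na(cors)] <- 0
  removed <- abs(cors) > reject_threshold
  report <- data.frame(component = seq_len(nc), correlation = cors,
                       removed = removed)

  S <- dec$S
  S[removed, ] <- 0
  # back-project: X = A S + mean, A = pinv(W K)
  WK <- dec$W %*% dec$K
  A <- MASS_ginv(WK)
  cleaned <- A %*% S + dec$means
  out <- rec
  out$data <- cleaned
  list(recording = out, report = report)
}

# Moore-Penrose pseudoinverse via SVD (square, well-conditioned here).
MASS_ginv <- function(M, tol = sqrt(.Machine$double.eps)) {
  sv <- svd(M)
  pos <- sv$d > tol * sv$d[1]
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' Segment a recording into overlapping windows
#'
#' Cuts 2-second windows with 50\% overlap (at 128 Hz: 256-sample windows,
#' 128-sample hop). Each window is tagged with the stimulus event covering its
#' start sample; windows starting outside every event carry no label. A
#' trailing partial segment is discarded.
#'
#' @param rec an \code{\link{eeg_recording}} (rate expected 128 Hz after
#'   \code{\link{downsample}}, but any rate is accepted).
#' @param win_s window length in seconds.
#' @param overlap fractional overlap in [0, 1).
#' @return list of \code{eeg_window} objects (possibly empty).
#' @export
segment_windows <- function(rec, win_s = 2.0, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  win <- as.integer(round(win_s * rec$rate))
  hop <- as.integer(round(win * (1 - overlap)))
  if (hop < 1) stop("overlap too large: hop would be < 1 sample")
  n <- n_samples(rec)
  if (n < win) return(list())
  starts <- seq(0L, n - win, by = hop)      # 0-based
  ev <- rec$events
  lapply(starts, function(s0) {
    stim <- NULL
    if (nrow(ev) > 0) {
      hit <- which(ev$onset_sample <= s0 &
                     s0 < ev$onset_sample + ev$duration_samples)
      if (length(hit) > 0) stim <- ev[hit[1], , drop = FALSE]
    }
    structure(
      list(data = rec$data[, (s0 + 1):(s0 + win), drop = FALSE],
           rate = rec$rate, start_sample = s0,
           channel_labels = rec$channel_labels,
           subject_id = rec$subject_id, group = rec$group,
           stimulus = stim,
           emotion_label = if (is.null(stim)) NA_character_ else
             quadrant_label(stim$arousal, stim$valence)),
      class = "eeg_window"
    )
  })
}

#' @export
print.eeg_window <- function(x, ...) {
  cat(sprintf("<eeg_window> %d ch x %d samples @ %g Hz, start %d, label %s\n",
              nrow(x$data), ncol(x$data), x$rate, x$start_sample,
              x$emotion_label))
  invisible(x)
}

#' Baseline-adjust a window
#'
#' Subtracts, per channel, the mean of the first \code{baseline_ms}
#' milliseconds (200 ms at 128 Hz = 26 samples, rounded to nearest). The
#' operation is idempotent.
#'
#' @param w an \code{eeg_window} from \code{\link{segment_windows}}.
#' @param baseline_ms baseline span in milliseconds.
#' @return the adjusted \code{eeg_window}.
#' @export
baseline_adjust <- function(w, baseline_ms = 200) {
  stopifnot(inherits(w, "eeg_window"))
  nb <- as.integer(round(baseline_ms / 1000 * w$rate))
  if (nb < 1 || nb > ncol(w$data))
    stop("baseline span (", nb, " samples) outside window length")
  mu <- rowMeans(w$data[, seq_len(nb), drop = FALSE])
  w$data <- w$data - mu
  w
}

#' Run the full preprocessing chain
#'
#' Downsample, band-pass, notch, optional ICA blink removal, segmentation and
#' baseline adjustment, in that order.
#'
#' @param rec raw \code{\link{eeg_recording}}.
#' @param cfg list of stage parameters; see Details. Missing entries take the
#'   defaults of the individual stage functions.
#' @details Config keys: \code{target_rate}, \code{bandpass} (list
#'   \code{low, high, order}), \code{notch_hz}, \code{ica} (list
#'   \code{enabled, threshold, seed}), \code{window} (list
#'   \code{seconds, overlap, baseline_ms}).
#' @param verbose print stage shapes.
#' @return list of baseline-adjusted windows.
#' @export
preprocess_chain <- function(rec, cfg = list(), verbose = FALSE) {
  defaults <- list(target_rate = 128,
                   bandpass = list(low = 0.4, high = 60, order = 2),
                   notch_hz = 50,
                   ica = list(enabled = TRUE, threshold = 0.8, seed = 1L,
                              maxit = 200),
                   window = list(seconds = 2.0, overlap = 0.5, baseline_ms = 200))
  cfg <- utils::modifyList(defaults, cfg)
  say <- function(stage, r) if (verbose)
    message(sprintf("[preprocess] %-12s %d x %d @ %g Hz", stage,
                    nrow(r$data), ncol(r$data), r$rate))
  say("input", rec)
  rec <- downsample(rec, cfg$target_rate); say("downsample", rec)
  rec <- bandpass(rec, cfg$bandpass$low, cfg$bandpass$high, cfg$bandpass$order)
  say("bandpass", rec)
  rec <- notch(rec, cfg$notch_hz); say("notch", rec)
  if (isTRUE(cfg$ica$enabled)) {
    ica <- remove_artifacts_ica(rec, cfg$ica$threshold, cfg$ica$seed,
                                maxit = cfg$ica$maxit)
    rec <- ica$recording
    say("ica", rec)
  }
  wins <- segment_windows(rec, cfg$window$seconds, cfg$window$overlap)
  lapply(wins, baseline_adjust, baseline_ms = cfg$window$baseline_ms)
}
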