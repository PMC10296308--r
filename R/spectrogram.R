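# Time-frequency featurization: short-time Fourier magnitude spectrograms of
# 2-second windows, cropped to the analysis band and rendered as unit-scaled
# images for the convolutional branch.

#' STFT parameters
#'
#' @param win_size analysis window length in samples.
#' @param step hop between consecutive frames in samples (0 < step <= win_size).
#' @param window_fn taper: \code{"hamming"} or \code{"rectangular"}.
#' @param rate sampling rate of the signal in Hz.
#' @param zero_pad pad the signal with zeros up to \code{win_size} when it is
#'   shorter (the default preset analyses a 256-sample segment with a
#'   512-sample window; see Details).
#' @details Two presets are natural for 2-s segments at 128 Hz: the wide
#' preset (\code{win_size = 512, step = 256}) zero-pads each segment and
#' yields a single finely resolved spectral frame; the dense preset
#' (\code{win_size = 128, step = 16}) yields a 9-frame time-frequency image.
#' Both are supported; the pipeline default is the dense preset because it
#' retains within-window temporal structure.
#' @return an object of class \code{stft_params}.
#' @export
stft_params <- function(win_size = 512, step = 256, window_fn = "hamming",
                        rate = 128, zero_pad = TRUE) {
  if (step <= 0 || step > win_size) stop("need 0 < step <= win_size")
  if (!window_fn %in% c("hamming", "rectangular"))
    stop("window_fn must be 'hamming' or 'rectangular'")
  structure(list(win_size = as.integer(win_size), step = as.integer(step),
                 window_fn = window_fn, rate = rate, zero_pad = zero_pad),
            class = "stft_params")
}

taper_of <- function(p) {
  if (p$window_fn == "hamming")
    0.54 - 0.46 * cos(2 * pi * (0:(p$win_size - 1)) / (p$win_size - 1))
  else rep(1, p$win_size)
}

#' Short-time Fourier magnitude spectrogram
#'
#' Frames the signal at each window position, multiplies by the taper,
#' transforms and takes the magnitude. With \code{onesided = TRUE} (default)
#' only bins 0..rate/2 are returned.
#'
#' @param x numeric vector, a single-channel signal.
#' @param p \code{\link{stft_params}}.
#' @param onesided return non-negative-frequency bins only.
#' @return object of class \code{spectrogram}: list with magnitude matrix
#'   \code{mag} (frequency bins x time frames), bin centers \code{freqs_hz}
#'   and frame centers \code{times_s}.
#' @export
stft <- function(x, p = stft_params(), onesided = TRUE) {
  if (length(x) == 0) stop("empty signal")
  if (length(x) < p$win_size) {
    if (!p$zero_pad)
      stop("signal shorter than win_size and zero_pad = FALSE")
    x <- c(x, rep(0, p$win_size - length(x)))
  }
  h <- taper_of(p)
  starts <- seq(1L, length(x) - p$win_size + 1L, by = p$step)
  frames <- vapply(starts, function(s) x[s:(s + p$win_size - 1L)] * h,
                   numeric(p$win_size))
  F <- stats::mvfft(frames)
  if (onesided) {
    nb <- p$win_size %/% 2L + 1L
    F <- F[seq_len(nb), , drop = FALSE]
    freqs <- (0:(nb - 1L)) * p$rate / p$win_size
  } else {
    freqs <- (0:(p$win_size - 1L)) * p$rate / p$win_size
  }
  structure(list(mag = abs(F),
                 freqs_hz = freqs,
                 times_s = (starts - 1 + p$win_size / 2) / p$rate),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d bins (%.2f-%.2f Hz) x %d frames\n",
              nrow(x$mag), min(x$freqs_hz), max(x$freqs_hz), ncol(x$mag)))
  invisible(x)
}

#' Crop a spectrogram to a frequency band
#'
#' Keeps bins with \code{low <= f <= high}; the time axis is untouched. A
#' \code{high} above the top bin is clipped with a warning.
#'
#' @param s a \code{spectrogram}.
#' @param low,high band edges in Hz.
#' @return the cropped \code{spectrogram}.
#' @export
crop_band <- function(s, low = 0.4, high = 60) {
  stopifnot(inherits(s, "spectrogram"))
  if (low >= high) stop("need low < high")
  top <- max(s$freqs_hz)
  if (high > top) {
    warning("band edge ", high, " Hz above top bin ", top, " Hz; clipped",
            call. = FALSE)
    high <- top
  }
  keep <- which(s$freqs_hz >= low & s$freqs_hz <= high)
  if (length(keep) == 0) stop("no frequency bins inside [", low, ", ", high, "] Hz")
  s$mag <- s$mag[keep, , drop = FALSE]
  s$freqs_hz <- s$freqs_hz[keep]
  s
}

# Bilinear resize of a matrix to out_h x out_w (edge-clamped sampling).
resize_bilinear <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  ry <- if (out_h == 1) rep(1, 1) else seq(1, in_h, length.out = out_h)
  rx <- if (out_w == 1) rep(1, 1) else seq(1, in_w, length.out = out_w)
  y0 <- pmin(floor(ry), in_h); y1 <- pmin(y0 + 1, in_h); wy <- ry - y0
  x0 <- pmin(floor(rx), in_w); x1 <- pmin(x0 + 1, in_w); wx <- rx - x0
  a <- m[y0, x0, drop = FALSE] * ((1 - wy) %o% (1 - wx))
  b <- m[y1, x0, drop = FALSE] * (wy %o% (1 - wx))
  cc <- m[y0, x1, drop = FALSE] * ((1 - wy) %o% wx)
  d <- m[y1, x1, drop = FALSE] * (wy %o% wx)
  a + b + cc + d
}

#' Convert a spectrogram to a unit-scaled image
#'
#' Applies \code{log(1 + mag)}, min-max normalizes to [0, 1], resizes
#' bilinearly to \code{out_h x out_w} and replicates across \code{channels}
#' planes. An all-zero spectrogram maps to an all-zero image (no division by
#' zero).
#'
#' @param s a \code{spectrogram}.
#' @param out_h,out_w output image size.
#' @param channels number of replicated planes.
#' @return object of class \code{spectro_image}: array
#'   \code{out_h x out_w x channels} with values in [0, 1].
#' @export
to_image <- function(s, out_h = 32, out_w = 32, channels = 1) {
  stopifnot(inherits(s, "spectrogram"))
  m <- log1p(s$mag)
  rng <- range(m)
  m <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  r <- resize_bilinear(m, out_h, out_w)
  r <- pmin(pmax(r, 0), 1)
  px <- array(r, dim = c(out_h, out_w, channels))
  structure(list(pixels = px), class = "spectro_image")
}

#' Spectrogram images for a multichannel window
#'
#' Computes one spectrogram per channel of a preprocessed window and
#' aggregates: \code{"mean"} averages the magnitude matrices into a single
#' image, \code{"per_channel"} returns one image per channel, and
#' \code{"hemisphere"} returns one image whose two planes are the left- and
#' right-hemisphere channel means (midline channels contribute to both) -
#' this retains lateralized structure such as frontal alpha asymmetry that a
#' whole-head channel mean cancels.
#'
#' @param w an \code{eeg_window}.
#' @param p \code{\link{stft_params}}.
#' @param agg aggregation: \code{"mean"} (default), \code{"per_channel"} or
#'   \code{"hemisphere"}.
#' @param band analysis band passed to \code{\link{crop_band}}.
#' @param out_h,out_w image size.
#' @return list of \code{spectro_image} objects.
#' @export
window_to_images <- function(w, p = stft_params(), agg = "mean",
                             band = c(0.4, 60), out_h = 32, out_w = 32) {
  stopifnot(inherits(w, "eeg_window"))
  if (nrow(w$data) < 1) stop("window has no channels")
  if (!agg %in% c("mean", "per_channel", "hemisphere"))
    stop("unknown aggregation '", agg, "'")
  specs <- lapply(seq_len(nrow(w$data)), function(i)
    crop_band(stft(w$data[i, ], p), band[1], band[2]))
  if (agg == "per_channel") {
    return(lapply(specs, to_image, out_h = out_h, out_w = out_w, channels = 1))
  }
  mean_spec <- function(idx) {
    s <- specs[[idx[1]]]
    s$mag <- Reduce(`+`, lapply(specs[idx], `[[`, "mag")) / length(idx)
    s
  }
  if (agg == "mean") {
    return(list(to_image(mean_spec(seq_along(specs)), out_h, out_w, 1)))
  }
  hemi <- hemisphere_of(w$channel_labels)
  left <- which(hemi != "right"); right <- which(hemi != "left")
  img_l <- to_image(mean_spec(left), out_h, out_w, 1)
  img_r <- to_image(mean_spec(right), out_h, out_w, 1)
  px <- array(0, dim = c(out_h, out_w, 2))
  px[, , 1] <- img_l$pixels[, , 1]
  px[, , 2] <- img_r$pixels[, , 1]
  list(structure(list(pixels = px), class = "spectro_image"))
}
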