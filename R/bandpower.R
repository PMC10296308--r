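# Band-power summaries: a lightweight, interpretable feature path used for
# diagnostics and for personality-branch experiments where the full
# convolutional featurization is unnecessarily heavy.

#' Mean band power of a signal
#'
#' Periodogram power (squared DFT magnitude, normalized by length) averaged
#' over the bins inside \code{band}.
#'
#' @param x numeric signal vector.
#' @param rate sampling rate in Hz.
#' @param band length-2 frequency band in Hz.
#' @return mean power in the band.
#' @export
band_power <- function(x, rate, band) {
  n <- length(x)
  X <- fft(x)
  p <- Mod(X)^2 / n
  f <- (0:(n - 1)) * rate / n
  keep <- f >= band[1] & f <= band[2]
  if (!any(keep)) stop("no DFT bins inside band [", band[1], ", ", band[2], "] Hz")
  mean(p[keep])
}

EEG_BANDS <- list(theta = c(4, 8), alpha = c(8, 12), beta = c(13, 30))

#' Hemisphere band-power features for windows
#'
#' For each window: theta/alpha/beta power averaged over left- and
#' right-hemisphere channels (6 features per window). Keeps lateralized
#' structure and is orders of magnitude cheaper than the convolutional path.
#'
#' @param windows list of \code{eeg_window} objects.
#' @param bands named list of frequency bands.
#' @return numeric matrix, windows x (2 * number of bands), with named
#'   columns like \code{alpha_left}.
#' @export
window_band_features <- function(windows, bands = EEG_BANDS) {
  feat <- t(vapply(windows, function(w) {
    hemi <- hemisphere_of(w$channel_labels)
    left <- which(hemi != "right"); right <- which(hemi != "left")
    n <- ncol(w$data)
    P <- Mod(stats::mvfft(t(w$data)))^2 / n      # one periodogram per channel
    f <- (0:(n - 1)) * w$rate / n
    unlist(lapply(names(bands), function(b) {
      keep <- f >= bands[[b]][1] & f <= bands[[b]][2]
      bp <- colMeans(P[keep, , drop = FALSE])
      c(mean(bp[left]), mean(bp[right]))
    }))
  }, numeric(2 * length(bands))))
  colnames(feat) <- as.vector(t(outer(names(bands), c("left", "right"),
                                      paste, sep = "_")))
  feat
}
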