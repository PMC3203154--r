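# Welch-averaged magnitude-squared coherence, the classical pairwise
# cross-check for ensemble synchronization: two channels that share a
# source show coherence near 1 in the band the source occupies, and
# decoupling them lowers it.

welch_window <- function(name, n) {
  u <- seq(0, n - 1) / (n - 1)
  switch(name,
         hann = 0.5 - 0.5 * cos(2 * pi * u),
         hamming = 0.54 - 0.46 * cos(2 * pi * u),
         rect = rep(1, n),
         mdfa_stop(sprintf("unknown window '%s'", name), "mdfa_validation_error"))
}

#' Magnitude-squared coherence of two channels
#'
#' Welch's method: both series are cut into overlapping segments, each
#' segment mean-removed and windowed, and the auto- and cross-spectra
#' averaged across segments; the coherence is
#' `|S_xy|^2 / (S_xx * S_yy)` per frequency, clipped into `[0, 1]` against
#' rounding.  With L averaged segments, the coherence of two independent
#' signals is biased upward by about 1/L, so use enough segments (>= 8; a
#' warning is given below that).
#'
#' @param x,y [time_series()] objects of equal length and sampling rate.
#' @param segment_length Samples per segment; default the power of two
#'   closest to 2 seconds of samples (resolves the sub-10 Hz band where
#'   CDP-like events live).
#' @param overlap_fraction Fractional overlap between segments (default 0.5).
#' @param window `"hann"` (default), `"hamming"`, or `"rect"`.
#' @return An object of class `coherence_spectrum`: `frequencies` (Hz, up
#'   to Nyquist), `coherence` in `[0, 1]`, `segment_params`.
#' @examples
#' x <- gen_white_noise(2^14, seed = 1, sampling_rate = 100)
#' spec <- msc(x, x, segment_length = 512)
#' all(spec$coherence > 1 - 1e-9)
#' @export
msc <- function(x, y, segment_length = NULL, overlap_fraction = 0.5,
                window = "hann") {
  stopifnot(inherits(x, "mdfa_ts"), inherits(y, "mdfa_ts"))
  if (length(x$values) != length(y$values)) {
    mdfa_stop("'x' and 'y' must have equal length", "mdfa_validation_error")
  }
  if (abs(x$sampling_rate - y$sampling_rate) > 1e-9 * x$sampling_rate) {
    mdfa_stop("'x' and 'y' must share one sampling rate", "mdfa_validation_error")
  }
  fs <- x$sampling_rate
  n <- length(x$values)
  if (is.null(segment_length)) {
    segment_length <- 2^round(log2(max(8, 2 * fs)))
  }
  L <- as.integer(segment_length)
  if (L < 8L || L > n) {
    mdfa_stop("'segment_length' must lie in [8, series length]",
              "mdfa_validation_error")
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    mdfa_stop("'overlap_fraction' must lie in [0, 1)", "mdfa_validation_error")
  }
  step <- max(1L, as.integer(round(L * (1 - overlap_fraction))))
  starts <- seq.int(1L, n - L + 1L, by = step)
  if (length(starts) < 2L) {
    mdfa_stop("fewer than 2 Welch segments; shorten 'segment_length'",
              "mdfa_segment_error")
  }
  if (length(starts) < 8L) {
    warning(sprintf("only %d Welch segments; coherence estimates are noisy",
                    length(starts)))
  }
  win <- welch_window(window, L)
  nfreq <- L %/% 2L + 1L
  pxx <- pyy <- numeric(nfreq)
  pxy <- complex(length.out = nfreq)
  for (s in starts) {
    idx <- s:(s + L - 1L)
    fx <- stats::fft((x$values[idx] - mean(x$values[idx])) * win)[seq_len(nfreq)]
    fy <- stats::fft((y$values[idx] - mean(y$values[idx])) * win)[seq_len(nfreq)]
    pxx <- pxx + Re(fx * Conj(fx))
    pyy <- pyy + Re(fy * Conj(fy))
    pxy <- pxy + fx * Conj(fy)
  }
  coh <- Mod(pxy)^2 / (pxx * pyy)
  coh[!is.finite(coh)] <- 0
  structure(list(frequencies = (seq_len(nfreq) - 1) * fs / L,
                 coherence = pmin(pmax(coh, 0), 1),
                 segment_params = list(segment_length = L,
                                       overlap_fraction = overlap_fraction,
                                       window = window,
                                       n_segments = length(starts)),
                 labels = c(x$label, y$label)),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf(
    "<coherence_spectrum> %s vs %s: %d freqs to %.4g Hz, %d segments of %d (%s, %.0f%% overlap)\n",
    x$labels[1], x$labels[2], length(x$frequencies), max(x$frequencies),
    x$segment_params$n_segments, x$segment_params$segment_length,
    x$segment_params$window, 100 * x$segment_params$overlap_fraction))
  invisible(x)
}

#' Mean coherence over a frequency band
#'
#' @param spec A [msc()] spectrum.
#' @param band `c(f_lo, f_hi)` in Hz; must contain at least one grid
#'   frequency.
#' @return Scalar mean coherence in `[0, 1]`.
#' @export
band_mean_coherence <- function(spec, band) {
  stopifnot(inherits(spec, "coherence_spectrum"))
  if (length(band) != 2L || band[1] > band[2]) {
    mdfa_stop("'band' must be c(f_lo, f_hi) with f_lo <= f_hi",
              "mdfa_validation_error")
  }
  keep <- spec$frequencies >= band[1] & spec$frequencies <= band[2]
  if (!any(keep)) {
    mdfa_stop("no grid frequencies inside the requested band", "mdfa_band_error")
  }
  mean(spec$coherence[keep])
}
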