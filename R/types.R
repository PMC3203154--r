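#' Construct a single-channel time series
#'
#' A light container for one uniformly sampled channel: numeric values
#' (arbitrary units, typically microvolts), a sampling rate in samples per
#' second, and a channel label.
#'
#' @param values Numeric vector of finite samples, length >= 1.
#' @param sampling_rate Positive finite sampling rate (samples/second).
#' @param label Channel name.
#' @return An object of class `mdfa_ts` with fields `values`,
#'   `sampling_rate`, `label`.
#' @examples
#' ts <- time_series(rnorm(1000), sampling_rate = 250, label = "L5L")
#' length(ts$values)
#' @export
time_series <- function(values, sampling_rate = 1, label = "ch1") {
  check_finite_values(values)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    mdfa_stop("'sampling_rate' must be a single positive finite number",
              "mdfa_validation_error")
  }
  structure(list(values = as.numeric(values),
                 sampling_rate = as.numeric(sampling_rate),
                 label = as.character(label)[1L]),
            class = "mdfa_ts")
}

#' @export
print.mdfa_ts <- function(x, ...) {
  cat(sprintf("<mdfa_ts> channel '%s': %d samples @ %.6g Hz (%.3g s)\n",
              x$label, length(x$values), x$sampling_rate,
              length(x$values) / x$sampling_rate))
  invisible(x)
}

as_ts_values <- function(x, what = "series") {
  if (inherits(x, "mdfa_ts")) return(x$values)
  if (is.numeric(x)) {
    check_finite_values(x, what)
    return(as.numeric(x))
  }
  mdfa_stop(sprintf("'%s' must be an mdfa_ts or a numeric vector", what),
            "mdfa_validation_error")
}

#' Construct an aligned multichannel series
#'
#' Bundles k simultaneously recorded channels of equal length and sampling
#' rate.  Values are stored as an N x k numeric matrix with one column per
#' channel.
#'
#' @param channels A numeric matrix (N x k), a list of [time_series()]
#'   objects, or a list of equal-length numeric vectors.
#' @param sampling_rate Sampling rate shared by all channels; taken from the
#'   channels when they are `mdfa_ts` objects.
#' @param labels Unique channel names; defaults to matrix column names or
#'   the labels of the supplied series.
#' @return An object of class `mdfa_mc` with fields `values` (N x k matrix),
#'   `sampling_rate`, `labels`.
#' @examples
#' mc <- multichannel_series(matrix(rnorm(400), ncol = 4),
#'                           sampling_rate = 100,
#'                           labels = c("L5L", "L5R", "L6L", "L6R"))
#' mc$labels
#' @export
multichannel_series <- function(channels, sampling_rate = NULL, labels = NULL) {
  if (is.list(channels) && !is.data.frame(channels)) {
    is_ts <- vapply(channels, inherits, TRUE, what = "mdfa_ts")
    if (all(is_ts)) {
      lens <- vapply(channels, function(ch) length(ch$values), 1L)
      if (length(unique(lens)) != 1L) {
        mdfa_stop("all channels must have equal length", "mdfa_validation_error")
      }
      rates <- vapply(channels, function(ch) ch$sampling_rate, 1.0)
      if (diff(range(rates)) > 1e-9 * max(rates)) {
        mdfa_stop("all channels must share one sampling rate",
                  "mdfa_validation_error")
      }
      if (is.null(labels)) labels <- vapply(channels, function(ch) ch$label, "")
      if (is.null(sampling_rate)) sampling_rate <- rates[1L]
      channels <- vapply(channels, function(ch) ch$values, numeric(lens[1L]))
    } else {
      lens <- lengths(channels)
      if (length(unique(lens)) != 1L) {
        mdfa_stop("all channels must have equal length", "mdfa_validation_error")
      }
      channels <- do.call(cbind, lapply(channels, as.numeric))
    }
  }
  if (!is.matrix(channels) || !is.numeric(channels)) {
    mdfa_stop("'channels' must reduce to a numeric matrix", "mdfa_validation_error")
  }
  check_finite_values(channels, "channels")
  if (is.null(labels)) {
    labels <- colnames(channels)
    if (is.null(labels)) labels <- sprintf("ch%d", seq_len(ncol(channels)))
  }
  if (length(labels) != ncol(channels) || anyDuplicated(labels)) {
    mdfa_stop("'labels' must be unique and match the channel count",
              "mdfa_validation_error")
  }
  if (is.null(sampling_rate)) sampling_rate <- 1
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    mdfa_stop("'sampling_rate' must be a single positive finite number",
              "mdfa_validation_error")
  }
  dimnames(channels) <- list(NULL, as.character(labels))
  structure(list(values = channels,
                 sampling_rate = as.numeric(sampling_rate),
                 labels = as.character(labels)),
            class = "mdfa_mc")
}

#' @export
print.mdfa_mc <- function(x, ...) {
  cat(sprintf("<mdfa_mc> %d channels x %d samples @ %.6g Hz: %s\n",
              ncol(x$values), nrow(x$values), x$sampling_rate,
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Extract one channel of a multichannel series
#'
#' @param mc An [multichannel_series()] object.
#' @param channel Channel label or column index.
#' @return A [time_series()] for that channel.
#' @export
get_channel <- function(mc, channel) {
  stopifnot(inherits(mc, "mdfa_mc"))
  idx <- if (is.character(channel)) match(channel, mc$labels) else as.integer(channel)
  if (is.na(idx) || idx < 1L || idx > ncol(mc$values)) {
    mdfa_stop(sprintf("unknown channel '%s'", channel), "mdfa_validation_error")
  }
  time_series(mc$values[, idx], mc$sampling_rate, mc$labels[idx])
}
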