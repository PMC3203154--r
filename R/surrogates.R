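# Shuffle surrogates: random permutations that keep the amplitude
# distribution of a recording but destroy its temporal ordering, the
# standard randomization control for scaling analyses.  A series with any
# long-range structure collapses to alpha ~ 0.5 after shuffling.

#' Shuffle surrogate of a single channel
#'
#' Returns a uniformly random permutation of the sample values; the value
#' multiset is preserved exactly.
#'
#' @param series A [time_series()] or numeric vector.
#' @param seed Integer seed for reproducibility.  Unseeded use is allowed
#'   but warns, since surrogate tests should be reproducible.
#' @return A [time_series()] with permuted values (label suffixed
#'   `"_shuf"` when the input carried a label).
#' @examples
#' s <- shuffle_series(time_series(1:10), seed = 42)
#' sort(s$values)   # 1..10 exactly
#' @export
shuffle_series <- function(series, seed = NULL) {
  if (is.null(seed)) {
    warning("shuffle_series() called without a seed; result is not reproducible")
  }
  if (inherits(series, "mdfa_ts")) {
    n <- length(series$values)
    if (n < 2L) mdfa_stop("need at least 2 samples to shuffle", "mdfa_validation_error")
    perm <- with_seed(seed, sample.int(n))
    time_series(series$values[perm], series$sampling_rate,
                paste0(series$label, "_shuf"))
  } else {
    x <- as_ts_values(series)
    if (length(x) < 2L) mdfa_stop("need at least 2 samples to shuffle", "mdfa_validation_error")
    perm <- with_seed(seed, sample.int(length(x)))
    time_series(x[perm], 1, "shuf")
  }
}

#' Shuffle surrogate of a multichannel series
#'
#' Two randomization schemes: `"independent"` (default) permutes each
#' channel with its own stream, destroying both temporal ordering and
#' cross-channel synchrony — the full null for ensemble statistics;
#' `"joint"` applies one permutation to all channels, destroying temporal
#' ordering while preserving every zero-lag cross-channel relation.
#'
#' @param mc A [multichannel_series()].
#' @param seed Integer seed; unseeded use warns.
#' @param mode `"independent"` or `"joint"`.
#' @return A shuffled [multichannel_series()] with the same labels.
#' @export
shuffle_multichannel <- function(mc, seed = NULL,
                                 mode = c("independent", "joint")) {
  stopifnot(inherits(mc, "mdfa_mc"))
  if (length(mode) == 1L && !mode %in% c("independent", "joint")) {
    mdfa_stop(sprintf("unknown shuffle mode '%s'", mode), "mdfa_mode_error")
  }
  mode <- match.arg(mode)
  if (is.null(seed)) {
    warning("shuffle_multichannel() called without a seed; result is not reproducible")
  }
  n <- nrow(mc$values)
  if (n < 2L) mdfa_stop("need at least 2 samples to shuffle", "mdfa_validation_error")
  vals <- with_seed(seed, {
    if (mode == "joint") {
      mc$values[sample.int(n), , drop = FALSE]
    } else {
      apply(mc$values, 2L, function(col) col[sample.int(n)])
    }
  })
  multichannel_series(vals, mc$sampling_rate, mc$labels)
}
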