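# Multichannel DFA: each channel is integrated and detrended on its own,
# and the squared residuals are pooled across channels into one ensemble
# fluctuation function, so an ensemble of k channels yields a single
# scaling exponent.  All channels share one box partition (they are
# simultaneously recorded and aligned), and the pooled fluctuation is
# normalized by 1/(N'*k): duplicating every channel, or permuting them,
# leaves F(n) unchanged, and k = 1 reduces exactly to classical DFA.

#' Componentwise profile integration of a multichannel series
#'
#' Applies [integrate_profile()] to each channel independently; no
#' cross-channel mixing happens at this stage.
#'
#' @param mc A [multichannel_series()].
#' @return N x k numeric matrix of per-channel profiles (columns keep the
#'   channel labels).
#' @export
integrate_profile_mc <- function(mc) {
  stopifnot(inherits(mc, "mdfa_mc"))
  apply(mc$values, 2L, function(x) cumsum(x - mean(x)))
}

#' Pooled multichannel fluctuation at one box size
#'
#' `F(n) = sqrt( (1/(N'*k)) * sum over channels of per-box squared
#' residuals )`: per-channel local polynomial trends, residuals pooled over
#' channels.  Equivalently, pooled `F(n)^2` is the mean over channels of
#' the per-channel `F(n)^2` at the same partition.
#'
#' @param profiles N x k profile matrix from [integrate_profile_mc()] (a
#'   single profile vector is accepted as k = 1).
#' @param box_size Box length n.
#' @param order Polynomial detrending degree m >= 1.
#' @param two_sided As in [fluctuation()].
#' @return Nonnegative scalar F(n).
#' @export
fluctuation_mc <- function(profiles, box_size, order = 1, two_sided = FALSE) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, ncol = 1L)
  check_finite_values(profiles, "profiles")
  order <- as.integer(order)
  if (is.na(order) || order < 1L) {
    mdfa_stop("'order' must be an integer >= 1", "mdfa_validation_error")
  }
  part <- partition_boxes(nrow(profiles), box_size, order = order)
  ssr <- sum(vapply(seq_len(ncol(profiles)), function(c) {
    s <- box_ssr(profiles[, c], part$box_size, order)
    if (two_sided) s <- (s + box_ssr(rev(profiles[, c]), part$box_size, order)) / 2
    s
  }, numeric(1)))
  sqrt(ssr / (part$covered_length * ncol(profiles)))
}

#' Multichannel detrended fluctuation analysis
#'
#' The ensemble statistic: componentwise integration, per-channel
#' polynomial detrending on a shared box partition, root-mean-square
#' pooling of residuals across channels, and one log-log scaling fit for
#' the whole ensemble.
#'
#' @param mc A [multichannel_series()].
#' @param order Polynomial detrending degree m >= 1.
#' @param schedule Box sizes; default [default_box_schedule()].
#' @param n_range Optional fit range.
#' @param normalize If `TRUE`, z-score each channel first so channels with
#'   different amplifier gains weight the pooled fluctuation equally.
#'   Off by default: raw fluctuations keep physical units.
#' @param two_sided As in [fluctuation()].
#' @return A `dfa_result` (kind `"mdfa"`) with the pooled
#'   [fluctuation_curve()] and its [fit_scaling()].
#' @examples
#' mc <- multichannel_series(matrix(rnorm(4 * 20000), ncol = 4))
#' mdfa(mc)$fit$alpha   # close to 0.5
#' @export
mdfa <- function(mc, order = 1, schedule = NULL, n_range = NULL,
                 normalize = FALSE, two_sided = FALSE) {
  stopifnot(inherits(mc, "mdfa_mc"))
  vals <- mc$values
  if (normalize) vals <- scale(vals)
  if (is.null(schedule)) schedule <- default_box_schedule(nrow(vals), order)
  if (length(schedule) < 1L) {
    mdfa_stop("'schedule' must contain at least one box size",
              "mdfa_schedule_error")
  }
  if (is.unsorted(schedule, strictly = TRUE)) {
    mdfa_stop("'schedule' must be strictly increasing", "mdfa_schedule_error")
  }
  profiles <- apply(vals, 2L, function(x) cumsum(x - mean(x)))
  fl <- vapply(schedule, function(n) fluctuation_mc(profiles, n, order, two_sided),
               numeric(1))
  curve <- structure(list(box_sizes = as.integer(schedule), fluctuations = fl,
                          order = as.integer(order), n_samples = nrow(vals),
                          two_sided = isTRUE(two_sided)),
                     class = "fluctuation_curve")
  fit <- fit_scaling(curve, n_range)
  structure(list(curve = curve, fit = fit,
                 config = list(kind = "mdfa", order = as.integer(order),
                               schedule = curve$box_sizes, n_range = n_range,
                               normalize = isTRUE(normalize),
                               two_sided = isTRUE(two_sided),
                               channels = mc$labels)),
            class = "dfa_result")
}

#' Per-channel scaling exponents of a multichannel series
#'
#' Convenience companion to [mdfa()]: runs classical [dfa()] on each channel
#' separately and collects the fitted exponents.  The pooled mDFA exponent,
#' not this vector, is the ensemble statistic.
#'
#' @inheritParams mdfa
#' @return Data frame with one row per channel: `label`, `alpha`,
#'   `r_squared`.
#' @export
channel_alphas <- function(mc, order = 1, schedule = NULL, n_range = NULL) {
  stopifnot(inherits(mc, "mdfa_mc"))
  rows <- lapply(seq_along(mc$labels), function(i) {
    fit <- dfa(mc$values[, i], order, schedule, n_range)$fit
    data.frame(label = mc$labels[i], alpha = fit$alpha,
               r_squared = fit$r_squared, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
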