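# Classical detrended fluctuation analysis (DFA / DFAm).
#
# The method integrates the mean-removed series into a profile, splits the
# profile into non-overlapping boxes of size n, removes a per-box
# least-squares polynomial trend of degree m, and summarizes the residuals
# as the fluctuation function F(n).  The Hurst-type scaling exponent alpha
# is the slope of log10 F(n) versus log10 n.

#' Integrate a series into its fluctuation profile
#'
#' Computes the cumulative sum of the mean-removed series,
#' `y(k) = sum_{i<=k} (x(i) - mean(x))`.  The profile always ends at zero
#' (the telescoping sum), which later detrending exploits.
#'
#' @param series A [time_series()] or numeric vector of finite values.
#' @return Numeric profile of the same length as the input.
#' @examples
#' integrate_profile(c(1, 2, 3))   # -1 -1 0
#' @export
integrate_profile <- function(series) {
  x <- as_ts_values(series)
  cumsum(x - mean(x))
}

#' Partition a series into non-overlapping boxes
#'
#' Divides indices `1..length` into `floor(length/box_size)` contiguous,
#' disjoint boxes of exactly `box_size` samples, starting at the first
#' sample.  The remainder at the tail is excluded (see [fluctuation()] for
#' the two-sided variant that also partitions from the end).
#'
#' @param length Total number of samples.
#' @param box_size Box length n, `1 <= n <= length`.
#' @param order Optional detrending order m; when given, boxes must hold at
#'   least `m + 2` samples so the polynomial fit is overdetermined.
#' @return A list of class `box_partition`: `box_size`, `box_starts`
#'   (1-based), `n_boxes`, `covered_length`.
#' @examples
#' partition_boxes(10, 3)  # 3 boxes covering 9 samples
#' @export
partition_boxes <- function(length, box_size, order = NULL) {
  length <- as.integer(length); box_size <- as.integer(box_size)
  if (is.na(box_size) || box_size < 1L || box_size > length) {
    mdfa_stop(sprintf("box_size %d must lie in [1, %d]", box_size, length),
              "mdfa_box_error")
  }
  if (!is.null(order) && box_size < order + 2L) {
    mdfa_stop(sprintf("box_size %d too small for detrend order %d (need >= %d)",
                      box_size, order, order + 2L),
              "mdfa_box_error")
  }
  n_boxes <- length %/% box_size
  structure(list(box_size = box_size,
                 box_starts = seq.int(1L, by = box_size, length.out = n_boxes),
                 n_boxes = n_boxes,
                 covered_length = n_boxes * box_size),
            class = "box_partition")
}

# Sum of squared residuals after per-box polynomial detrending, over the
# first covered_length points of `profile`.  The per-box design matrix is
# shared, so all boxes are detrended in one QR solve on an n x n_boxes
# matrix.  Box abscissae are rescaled to [-1, 1] for conditioning.
box_ssr <- function(profile, box_size, order) {
  n_boxes <- length(profile) %/% box_size
  covered <- n_boxes * box_size
  Y <- matrix(profile[seq_len(covered)], nrow = box_size)
  t_scaled <- seq_len(box_size)
  t_scaled <- (t_scaled - mean(t_scaled)) / max(1, (box_size - 1) / 2)
  X <- outer(t_scaled, 0:order, `^`)
  sum(qr.resid(qr(X), Y)^2)
}

#' Detrended fluctuation at one box size
#'
#' `F(n) = sqrt( (1/N') * sum of squared residuals )` where the residuals
#' are taken against per-box least-squares polynomials of degree `order`
#' and `N'` is the number of covered samples (tail remainder excluded, so a
#' perfectly box-wise-polynomial profile gives exactly 0).
#'
#' @param profile Numeric profile from [integrate_profile()].
#' @param box_size Box length n; must satisfy `n >= order + 2`.
#' @param order Polynomial detrending degree m >= 1 (1 = classical DFA).
#' @param two_sided If `TRUE`, average squared residuals over the forward
#'   partition and the partition anchored at the series end, so tail samples
#'   also contribute when `length %% n != 0`.
#' @return Nonnegative scalar F(n).
#' @export
fluctuation <- function(profile, box_size, order = 1, two_sided = FALSE) {
  check_finite_values(profile, "profile")
  order <- as.integer(order)
  if (is.na(order) || order < 1L) {
    mdfa_stop("'order' must be an integer >= 1", "mdfa_validation_error")
  }
  part <- partition_boxes(length(profile), box_size, order = order)
  ssr <- box_ssr(profile, part$box_size, order)
  if (two_sided) {
    ssr <- (ssr + box_ssr(rev(profile), part$box_size, order)) / 2
  }
  sqrt(ssr / part$covered_length)
}

#' Default log-spaced box-size schedule
#'
#' About four sizes per octave between `n_min = max(2 * (order + 2), 4)`
#' and `n_max = floor(N/4)`, rounded to integers and deduplicated.  The
#' upper bound keeps at least four boxes per size so each F(n) averages
#' several independent trend fits.
#'
#' @param n_samples Series length N.
#' @param order Detrending order (sets the minimum admissible box).
#' @param n_min,n_max Optional overrides of the range.
#' @param per_octave Target number of sizes per factor-of-two.
#' @return Strictly increasing integer vector of box sizes.
#' @export
default_box_schedule <- function(n_samples, order = 1, n_min = NULL,
                                 n_max = NULL, per_octave = 4) {
  if (is.null(n_min)) n_min <- max(2L * (as.integer(order) + 2L), 4L)
  if (is.null(n_max)) n_max <- n_samples %/% 4L
  if (n_max < n_min) {
    mdfa_stop(sprintf("series too short for a schedule (n_min %d > n_max %d)",
                      n_min, n_max), "mdfa_schedule_error")
  }
  grid <- 2^seq(log2(n_min), log2(n_max), by = 1 / per_octave)
  sched <- unique(pmin(as.integer(round(grid)), as.integer(n_max)))
  if (length(sched) < 4L) {
    mdfa_stop("schedule has fewer than 4 box sizes; series too short",
              "mdfa_schedule_error")
  }
  sched
}

#' Fluctuation function over a schedule of box sizes
#'
#' @param series A [time_series()] or numeric vector.
#' @param schedule Strictly increasing box sizes; default
#'   [default_box_schedule()].
#' @param order Polynomial detrending degree m >= 1.
#' @param two_sided Passed to [fluctuation()].
#' @return An object of class `fluctuation_curve`: `box_sizes`,
#'   `fluctuations`, `order`, `n_samples`, `two_sided`.
#' @examples
#' curve <- fluctuation_curve(rnorm(4096))
#' head(cbind(n = curve$box_sizes, F = curve$fluctuations))
#' @export
fluctuation_curve <- function(series, schedule = NULL, order = 1,
                              two_sided = FALSE) {
  x <- as_ts_values(series)
  if (is.null(schedule)) schedule <- default_box_schedule(length(x), order)
  if (length(schedule) < 1L) {
    mdfa_stop("'schedule' must contain at least one box size",
              "mdfa_schedule_error")
  }
  if (is.unsorted(schedule, strictly = TRUE)) {
    mdfa_stop("'schedule' must be strictly increasing", "mdfa_schedule_error")
  }
  profile <- integrate_profile(x)
  fl <- vapply(schedule, function(n) fluctuation(profile, n, order, two_sided),
               numeric(1))
  structure(list(box_sizes = as.integer(schedule), fluctuations = fl,
                 order = as.integer(order), n_samples = length(x),
                 two_sided = isTRUE(two_sided)),
            class = "fluctuation_curve")
}

#' @export
print.fluctuation_curve <- function(x, ...) {
  cat(sprintf("<fluctuation_curve> order m=%d, %d box sizes in [%d, %d], N=%d\n",
              x$order, length(x$box_sizes), min(x$box_sizes), max(x$box_sizes),
              x$n_samples))
  invisible(x)
}

#' Fit the scaling exponent of a fluctuation curve
#'
#' Ordinary least squares of `log10 F(n)` on `log10 n` over the requested
#' box-size range.  The slope is the Hurst-type scaling exponent alpha:
#' 0.5 for uncorrelated noise, > 0.5 for persistent long-range correlation,
#' about 1.0 for 1/f noise.  Points with F(n) = 0 (log undefined; only
#' degenerate inputs produce them) are dropped with a warning.
#'
#' @param curve A [fluctuation_curve()].
#' @param n_range Optional `c(n_min, n_max)` bounds for the fit.
#' @return An object of class `scaling_fit`: `alpha`, `intercept` (log10
#'   scale), `r_squared`, `n_range` (range actually used), `n_points`.
#' @examples
#' curve <- fluctuation_curve(cumsum(rnorm(8192)))
#' fit_scaling(curve)
#' @export
fit_scaling <- function(curve, n_range = NULL) {
  stopifnot(inherits(curve, "fluctuation_curve"))
  n <- curve$box_sizes; fl <- curve$fluctuations
  if (!is.null(n_range)) {
    keep <- n >= n_range[1] & n <= n_range[2]
    n <- n[keep]; fl <- fl[keep]
  }
  pos <- fl > 0
  if (any(!pos)) {
    warning(sprintf("dropping %d box size(s) with F(n) = 0 from the log-log fit",
                    sum(!pos)))
    n <- n[pos]; fl <- fl[pos]
  }
  if (length(n) < 4L) {
    mdfa_stop("fewer than 4 usable (n, F(n)) points for the scaling fit",
              "mdfa_fit_error")
  }
  lx <- log10(n); ly <- log10(fl)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(alpha = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 r_squared = min(max(r2, 0), 1),
                 n_range = c(min(n), max(n)),
                 n_points = length(n)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> alpha = %.4f  (R^2 = %.4f, %d points, n in [%d, %d])\n",
              x$alpha, x$r_squared, x$n_points, x$n_range[1], x$n_range[2]))
  invisible(x)
}

#' Detrended fluctuation analysis of one channel
#'
#' Runs the full pipeline: profile integration, per-box polynomial
#' detrending over a log-spaced schedule of box sizes, and a straight-line
#' fit of `log10 F(n)` on `log10 n`.
#'
#' @inheritParams fluctuation_curve
#' @param n_range Optional fit range passed to [fit_scaling()].
#' @return An object of class `dfa_result` with elements `curve`
#'   ([fluctuation_curve()]), `fit` ([fit_scaling()]), and `config`.
#' @examples
#' res <- dfa(gen_white_noise(20000, seed = 1))
#' res$fit$alpha   # close to 0.5
#' @export
dfa <- function(series, order = 1, schedule = NULL, n_range = NULL,
                two_sided = FALSE) {
  x <- as_ts_values(series)
  if (is.null(schedule)) schedule <- default_box_schedule(length(x), order)
  curve <- fluctuation_curve(x, schedule, order, two_sided)
  fit <- fit_scaling(curve, n_range)
  structure(list(curve = curve, fit = fit,
                 config = list(kind = "dfa", order = as.integer(order),
                               schedule = curve$box_sizes, n_range = n_range,
                               two_sided = isTRUE(two_sided))),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<%s result> alpha = %.4f, R^2 = %.4f over n in [%d, %d] (m = %d)\n",
              x$config$kind, x$fit$alpha, x$fit$r_squared,
              x$fit$n_range[1], x$fit$n_range[2], x$config$order))
  invisible(x)
}
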