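# Statistical comparison of fluctuation curves across conditions, as used
# to test whether a lesion reduced the detrended fluctuations: a paired
# Student t-test on log10 F(n) differences across the box sizes shared by
# the two curves.  The one-sided "reduction" tail tests whether the second
# curve's fluctuations are lower than the first's.
#
# Caveat (documented in the methods vignette): log F(n) estimation errors
# are correlated across box sizes within one recording, so these p-values
# treat window sizes as independent observations the way the original
# tabulations do; under a seed-level resampling null they are
# anticonservative.

#' Paired comparison of two fluctuation curves
#'
#' @param a,b [fluctuation_curve()] objects (`a` = reference/control,
#'   `b` = comparison/lesioned condition).
#' @param tail `"two_sided"`, or `"reduction"` to test one-sidedly that
#'   `b`'s fluctuations are lower than `a`'s.
#' @param per_size If `TRUE`, also return the per-box-size log10 ratio
#'   table (useful for "largest window sizes" inspections).
#' @return An object of class `fluctuation_comparison`:
#'   `shared_box_sizes`, `t_statistic`, `p_value`, `tail`, `n_points`,
#'   `mean_log10_ratio` (mean of `log10(F_b/F_a)`), and optionally
#'   `per_size`.  Degenerate zero-variance differences are resolved
#'   exactly: identical curves give `t = 0`, `p = 1`; a constant nonzero
#'   log-ratio is an exact rejection (p at the smallest positive double).
#' @examples
#' a <- fluctuation_curve(gen_white_noise(8192, seed = 1))
#' compare_fluctuations(a, a)$p_value   # 1
#' @export
compare_fluctuations <- function(a, b, tail = c("two_sided", "reduction"),
                                 per_size = FALSE) {
  stopifnot(inherits(a, "fluctuation_curve"), inherits(b, "fluctuation_curve"))
  tail <- match.arg(tail)
  shared <- intersect(a$box_sizes, b$box_sizes)
  fa <- a$fluctuations[match(shared, a$box_sizes)]
  fb <- b$fluctuations[match(shared, b$box_sizes)]
  ok <- fa > 0 & fb > 0
  shared <- shared[ok]; fa <- fa[ok]; fb <- fb[ok]
  if (length(shared) < 4L) {
    mdfa_stop("fewer than 4 shared box sizes with positive fluctuations",
              "mdfa_compare_error")
  }
  d <- log10(fb) - log10(fa)
  m <- mean(d); s <- stats::sd(d); k <- length(d)
  eps <- 1e-13 * max(1, abs(m))
  if (s <= eps) {
    # zero-variance differences: exact outcome
    t_stat <- if (abs(m) <= eps) 0 else sign(m) * Inf
    p <- if (abs(m) <= eps) 1
         else if (tail == "two_sided") .Machine$double.xmin
         else if (m < 0) .Machine$double.xmin else 1
  } else {
    t_stat <- m / (s / sqrt(k))
    p <- switch(tail,
                two_sided = 2 * stats::pt(-abs(t_stat), df = k - 1),
                reduction = stats::pt(t_stat, df = k - 1))
    p <- max(p, .Machine$double.xmin)
  }
  out <- list(shared_box_sizes = shared, t_statistic = t_stat,
              p_value = p, tail = tail, n_points = k, mean_log10_ratio = m)
  if (per_size) {
    out$per_size <- data.frame(box_size = shared, f_a = fa, f_b = fb,
                               log10_ratio = d)
  }
  structure(out, class = "fluctuation_comparison")
}

#' @export
print.fluctuation_comparison <- function(x, ...) {
  cat(sprintf(
    "<fluctuation_comparison> t = %.3f, p = %.3g (%s tail, %d shared sizes, mean log10 F-ratio %.4f)\n",
    x$t_statistic, x$p_value, x$tail, x$n_points, x$mean_log10_ratio))
  invisible(x)
}
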