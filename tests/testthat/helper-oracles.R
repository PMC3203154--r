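# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals: explicit
# per-box loops, lm() polynomial fits on raw box indices, direct residual
# sums.

oracle_profile <- function(x) cumsum(x - mean(x))

# F(n) by looping over boxes and fitting each trend with lm().
oracle_fluctuation <- function(x, n, m = 1) {
  y <- oracle_profile(x)
  n_boxes <- length(y) %/% n
  ssr <- 0
  for (b in seq_len(n_boxes)) {
    idx <- ((b - 1) * n + 1):(b * n)
    fit <- stats::lm(y[idx] ~ stats::poly(seq_len(n), degree = m, raw = TRUE))
    ssr <- ssr + sum(stats::residuals(fit)^2)
  }
  sqrt(ssr / (n_boxes * n))
}

# Pooled multichannel F(n): per-channel oracle fluctuations combined as a
# root mean square over channels (same shared partition).
oracle_fluctuation_mc <- function(mat, n, m = 1) {
  f2 <- vapply(seq_len(ncol(mat)), function(c) oracle_fluctuation(mat[, c], n, m)^2,
               numeric(1))
  sqrt(mean(f2))
}

# Least-squares slope of log10 F on log10 n, via lm().
oracle_alpha <- function(ns, fs) {
  unname(coef(stats::lm(log10(fs) ~ log10(ns)))[2])
}

# fGn autocovariance at lag j (unit variance).
fgn_gamma <- function(j, H) {
  0.5 * (abs(j + 1)^(2 * H) - 2 * abs(j)^(2 * H) + abs(j - 1)^(2 * H))
}

make_mc <- function(mat, fs = 100, labels = NULL) {
  multichannel_series(mat, fs, labels)
}
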