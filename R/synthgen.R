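# Synthetic signal generators.
#
# The cat cord-dorsum recordings that motivate this package are not
# publicly deposited, so calibration and workflow tests run on synthetic
# inputs: Gaussian white noise (alpha = 0.5 null), exact fractional
# Gaussian noise with prescribed Hurst parameter H (alpha ~ H), 1/f noise
# (alpha ~ 1.0), and a multichannel generator of coupled cord dorsum
# potential (CDP)-like activity whose inter-channel coupling can be
# "lesioned" to emulate a partial spinal transection between segments.
#
# Default record geometry mirrors the study's acquisition: 10-minute
# records of about one million samples per channel, i.e. a sampling rate
# of 1e6/600 ~ 1666.67 samples/s.

DEFAULT_RATE <- 1e6 / 600

#' Gaussian white noise
#'
#' @param n Number of samples.
#' @param seed Integer seed (optional).
#' @param sd Standard deviation.
#' @param sampling_rate Samples per second.
#' @param label Channel label.
#' @return A [time_series()] of i.i.d. `N(0, sd^2)` samples.
#' @export
gen_white_noise <- function(n, seed = NULL, sd = 1,
                            sampling_rate = DEFAULT_RATE, label = "white") {
  x <- with_seed(seed, stats::rnorm(n, sd = sd))
  time_series(x, sampling_rate, label)
}

#' Fractional Gaussian noise by exact circulant embedding
#'
#' Synthesizes a stationary Gaussian sequence with the fGn autocovariance
#' `gamma(j) = 0.5 * (|j+1|^(2H) - 2|j|^(2H) + |j-1|^(2H))` (unit variance)
#' by the Davies-Harte method: the covariance is embedded in a circulant of
#' size 2n, its eigenvalues obtained by FFT, and one exact sample drawn with
#' correctly weighted real and complex Gaussian spectral coefficients.  DFA
#' on the output recovers alpha ~ H.
#'
#' @param H Hurst parameter in (0, 1); 0.5 gives white noise.
#' @param n Number of samples.
#' @param seed Integer seed (optional).
#' @param sampling_rate Samples per second.
#' @param label Channel label.
#' @return A [time_series()] of length `n`.
#' @export
gen_fgn <- function(H, n, seed = NULL, sampling_rate = DEFAULT_RATE,
                    label = sprintf("fgn_H%g", H)) {
  if (!is.numeric(H) || length(H) != 1L || !is.finite(H) || H <= 0 || H >= 1) {
    mdfa_stop("'H' must lie strictly between 0 and 1", "mdfa_validation_error")
  }
  n <- as.integer(n)
  if (n < 2L) mdfa_stop("'n' must be >= 2", "mdfa_validation_error")
  j <- 0:n
  gam <- 0.5 * ((j + 1)^(2 * H) - 2 * j^(2 * H) + abs(j - 1)^(2 * H))
  first_row <- c(gam, gam[n:2])               # circulant of size M = 2n
  lambda <- Re(stats::fft(first_row))
  if (min(lambda) < -1e-8 * max(lambda)) {
    mdfa_stop(sprintf(
      "circulant embedding is not nonnegative definite for n = %d; try a different (e.g. power-of-two) n",
      n), "mdfa_embedding_error")
  }
  lambda <- pmax(lambda, 0)
  M <- 2L * n
  x <- with_seed(seed, {
    z <- stats::rnorm(M)
    a <- complex(length.out = M)
    a[1L] <- sqrt(lambda[1L]) * z[1L]
    a[n + 1L] <- sqrt(lambda[n + 1L]) * z[2L]
    k <- 2:n
    re <- z[2L * k - 1L]; im <- z[2L * k]
    a[k] <- sqrt(lambda[k] / 2) * complex(real = re, imaginary = im)
    a[M + 2L - k] <- Conj(a[k])
    Re(stats::fft(a))[seq_len(n)] / sqrt(M)
  })
  time_series(x, sampling_rate, label)
}

#' 1/f (pink) noise by random-phase spectral synthesis
#'
#' Builds a Hermitian spectrum with amplitude proportional to `f^(-1/2)`
#' (power spectral density proportional to 1/f), uniform random phases and
#' zero DC, inverse-transforms to a real series, and rescales to unit
#' standard deviation.  DFA on the output gives alpha ~ 1.0.
#'
#' @param n Number of samples (>= 16; powers of two transform fastest).
#' @param seed Integer seed (optional).
#' @param sampling_rate Samples per second.
#' @param label Channel label.
#' @return A zero-mean, unit-sd [time_series()] of length `n`.
#' @export
gen_one_over_f <- function(n, seed = NULL, sampling_rate = DEFAULT_RATE,
                           label = "one_over_f") {
  n <- as.integer(n)
  if (n < 16L) mdfa_stop("'n' must be >= 16", "mdfa_validation_error")
  nf <- n %/% 2L
  x <- with_seed(seed, {
    amp <- seq_len(nf)^(-0.5)
    phase <- stats::runif(nf, 0, 2 * pi)
    h <- complex(length.out = n)
    h[2:(nf + 1L)] <- complex(modulus = amp, argument = phase)
    pos <- if (n %% 2L == 0L) 2:nf else 2:(nf + 1L)
    if (n %% 2L == 0L) h[nf + 1L] <- amp[nf]   # Nyquist bin must be real
    h[n + 2L - pos] <- Conj(h[pos])
    Re(stats::fft(h, inverse = TRUE)) / n
  })
  x <- x - mean(x)
  x <- x / stats::sd(x)
  time_series(x, sampling_rate, label)
}

#' Event specification for CDP-like activity
#'
#' Describes the discrete biphasic events superposed on background noise by
#' [gen_cdp_train()].  Defaults follow the physiology of spontaneous cord
#' dorsum potentials: event durations of 100-300 ms.
#'
#' @param rate Events per second (Poisson intensity), >= 0.
#' @param duration_range Two positive durations (seconds), `lo <= hi`;
#'   each event's duration is uniform in this interval.
#' @param amplitude_scale Peak amplitude multiplier (arbitrary units).
#' @param shape Waveform identifier; `"biphasic_hann"` (one sine cycle
#'   under a Hann window, zero-mean) is currently implemented.
#' @return An object of class `cdp_event_spec`.
#' @export
cdp_event_spec <- function(rate = 1, duration_range = c(0.1, 0.3),
                           amplitude_scale = 1, shape = "biphasic_hann") {
  if (!is.numeric(rate) || rate < 0) {
    mdfa_stop("'rate' must be >= 0", "mdfa_validation_error")
  }
  if (length(duration_range) != 2L || duration_range[1] <= 0 ||
      duration_range[1] > duration_range[2]) {
    mdfa_stop("'duration_range' must satisfy 0 < lo <= hi", "mdfa_validation_error")
  }
  if (!identical(shape, "biphasic_hann")) {
    mdfa_stop(sprintf("unknown event shape '%s'", shape), "mdfa_validation_error")
  }
  structure(list(rate = rate, duration_range = as.numeric(duration_range),
                 amplitude_scale = amplitude_scale, shape = shape),
            class = "cdp_event_spec")
}

# One sine cycle under a Hann window: biphasic, smooth, exactly zero-mean,
# so event trains add no baseline drift.
biphasic_hann <- function(n_samples) {
  u <- seq(0, 1, length.out = n_samples)
  sin(2 * pi * u) * 0.5 * (1 - cos(2 * pi * u))
}

#' Train of biphasic CDP-like events on a noise floor
#'
#' Event onsets follow a Poisson process; each event is a biphasic
#' waveform with duration drawn uniformly from the spec's range, added to
#' Gaussian background noise.
#'
#' @param spec A [cdp_event_spec()].
#' @param duration_s Record length in seconds (default 600, a 10-minute
#'   record).
#' @param sampling_rate Samples per second.
#' @param seed Integer seed (optional).
#' @param noise_sd Standard deviation of the background noise floor.
#' @param label Channel label.
#' @return A [time_series()] with the realized event onset times (s) and
#'   durations (s) attached as attribute `"events"`.
#' @export
gen_cdp_train <- function(spec = cdp_event_spec(), duration_s = 600,
                          sampling_rate = DEFAULT_RATE, seed = NULL,
                          noise_sd = 0.1, label = "cdp") {
  stopifnot(inherits(spec, "cdp_event_spec"))
  if (sampling_rate * spec$duration_range[1] < 8) {
    mdfa_stop("sampling_rate too low: shortest event would span < 8 samples",
              "mdfa_validation_error")
  }
  n <- as.integer(round(duration_s * sampling_rate))
  out <- with_seed(seed, {
    x <- stats::rnorm(n, sd = noise_sd)
    n_events <- stats::rpois(1L, spec$rate * duration_s)
    onsets <- sort(stats::runif(n_events, 0, duration_s))
    durations <- stats::runif(n_events, spec$duration_range[1],
                              spec$duration_range[2])
    for (e in seq_len(n_events)) {
      i0 <- as.integer(floor(onsets[e] * sampling_rate)) + 1L
      len <- as.integer(round(durations[e] * sampling_rate))
      i1 <- min(i0 + len - 1L, n)
      if (i1 >= i0) {
        w <- biphasic_hann(len)[seq_len(i1 - i0 + 1L)]
        x[i0:i1] <- x[i0:i1] + spec$amplitude_scale * w
      }
    }
    list(x = x, onsets = onsets, durations = durations)
  })
  ts <- time_series(out$x, sampling_rate, label)
  attr(ts, "events") <- data.frame(onset_s = out$onsets,
                                   duration_s = out$durations)
  ts
}

#' Inter-channel coupling specification
#'
#' Ground truth for the coupled multichannel generator: a symmetric k x k
#' coupling matrix with unit diagonal and off-diagonal entries in `[0, 1]`
#' (the target zero-lag correlation between channel pairs), plus an
#' additive per-channel white-noise floor.  Lesions act on this object via
#' [apply_lesion()].
#'
#' @param k Number of channels.
#' @param coupling Either a single off-diagonal level in `[0, 1]` or a full
#'   symmetric k x k matrix with unit diagonal.
#' @param noise_floor Standard deviation of additional per-channel white
#'   measurement noise (0 disables it).
#' @param labels Channel labels; default `"ch1" ... "chk"`.
#' @return An object of class `coupling_spec`.
#' @examples
#' coupling_spec(4, 0.9, labels = c("L5L", "L5R", "L6L", "L6R"))
#' @export
coupling_spec <- function(k = 4, coupling = 0.9, noise_floor = 0,
                          labels = NULL) {
  k <- as.integer(k)
  if (k < 1L) mdfa_stop("'k' must be >= 1", "mdfa_validation_error")
  if (is.matrix(coupling)) {
    C <- coupling
    if (nrow(C) != k || ncol(C) != k) {
      mdfa_stop("coupling matrix must be k x k", "mdfa_validation_error")
    }
  } else {
    if (length(coupling) != 1L) {
      mdfa_stop("'coupling' must be a scalar or a k x k matrix",
                "mdfa_validation_error")
    }
    C <- matrix(coupling, k, k)
    diag(C) <- 1
  }
  if (max(abs(C - t(C))) > 1e-12) {
    mdfa_stop("coupling matrix must be symmetric", "mdfa_validation_error")
  }
  if (any(C < 0) || any(C > 1)) {
    mdfa_stop("coupling entries must lie in [0, 1]", "mdfa_validation_error")
  }
  if (any(abs(diag(C) - 1) > 1e-12)) {
    mdfa_stop("coupling matrix must have unit diagonal", "mdfa_validation_error")
  }
  if (!is.numeric(noise_floor) || noise_floor < 0) {
    mdfa_stop("'noise_floor' must be >= 0", "mdfa_validation_error")
  }
  if (is.null(labels)) labels <- sprintf("ch%d", seq_len(k))
  if (length(labels) != k || anyDuplicated(labels)) {
    mdfa_stop("'labels' must be unique and of length k", "mdfa_validation_error")
  }
  dimnames(C) <- list(labels, labels)
  structure(list(k = k, coupling = C, noise_floor = as.numeric(noise_floor),
                 labels = as.character(labels)),
            class = "coupling_spec")
}

#' Attenuate selected coupling edges (simulated lesion)
#'
#' Multiplies the listed off-diagonal coupling entries by
#' `(1 - attenuation)`, symmetrically — the synthetic analogue of a partial
#' spinal lesion interrupting the pathway between two recording sites.
#' Sequential lesions compose multiplicatively on shared edges.
#'
#' @param spec A [coupling_spec()] (the ground truth to lesion).
#' @param attenuation Fraction removed, in `[0, 1]`; 1 severs the edge.
#' @param edges List of length-2 vectors of channel labels (or indices)
#'   naming the pairs to attenuate.
#' @return A new [coupling_spec()] with the lesioned matrix.
#' @examples
#' cs <- coupling_spec(4, 0.9, labels = c("L5L", "L5R", "L6L", "L6R"))
#' apply_lesion(cs, 0.8, list(c("L5L", "L6L"), c("L5L", "L6R")))
#' @export
apply_lesion <- function(spec, attenuation, edges) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (!is.numeric(attenuation) || attenuation < 0 || attenuation > 1) {
    mdfa_stop("'attenuation' must lie in [0, 1]", "mdfa_validation_error")
  }
  C <- spec$coupling
  for (e in edges) {
    if (length(e) != 2L) {
      mdfa_stop("each edge must name exactly two channels", "mdfa_validation_error")
    }
    idx <- if (is.character(e)) match(e, spec$labels) else as.integer(e)
    if (anyNA(idx) || any(idx < 1L) || any(idx > spec$k) || idx[1] == idx[2]) {
      mdfa_stop(sprintf("unknown or degenerate edge (%s, %s)", e[1], e[2]),
                "mdfa_validation_error")
    }
    C[idx[1], idx[2]] <- C[idx[1], idx[2]] * (1 - attenuation)
    C[idx[2], idx[1]] <- C[idx[1], idx[2]]
  }
  coupling_spec(spec$k, C, spec$noise_floor, spec$labels)
}

# Rank-1 least-squares factorization of the off-diagonal coupling:
# find w in [0,1]^k minimizing sum_{i != j} (C_ij - w_i w_j)^2 by
# coordinate fixed-point iteration.  For a uniform off-diagonal rho this
# converges to w = sqrt(rho) exactly.
coupling_weights <- function(C) {
  k <- nrow(C)
  if (k == 1L) return(0)
  off <- (rowSums(C) - diag(C)) / (k - 1)
  w <- sqrt(pmin(1, pmax(0, off)))
  if (all(w == 0)) return(w)
  for (iter in 1:200) {
    w_old <- w
    for (i in seq_len(k)) {
      den <- sum(w[-i]^2)
      w[i] <- if (den > 0) min(1, max(0, sum(C[i, -i] * w[-i]) / den)) else 0
    }
    if (max(abs(w - w_old)) < 1e-12) break
  }
  w
}

#' Coupled multichannel series with lesionable ground truth
#'
#' Generates k channels as mixtures of one shared source and independent
#' private white noise:
#' `channel_c = w_c * shared + sqrt(1 - w_c^2) * private_c + noise_floor * eps_c`.
#' The per-channel weights `w` are the rank-1 least-squares factorization
#' of the coupling matrix's off-diagonals, so with a uniform coupling `rho`
#' and no noise floor the zero-lag correlation of every pair is exactly
#' `rho` in expectation (`w = sqrt(rho)`).  With a long-range-correlated
#' shared source (1/f, fGn, or a CDP event train) and white private
#' sources, stronger coupling shifts every channel's spectrum toward the
#' shared source, raising the ensemble mDFA exponent; attenuating edges
#' with [apply_lesion()] lowers it — the synthetic analogue of
#' decoupling adjacent spinal segments.
#'
#' @param coupling A [coupling_spec()].
#' @param source Shared-source family: `"one_over_f"`, `"fgn"`, or
#'   `"cdp_train"`.
#' @param n Samples per channel.
#' @param seed Integer seed (optional).
#' @param H Hurst parameter of the shared source when `source = "fgn"`.
#' @param event_spec [cdp_event_spec()] for `source = "cdp_train"`.
#' @param sampling_rate Samples per second.
#' @return A [multichannel_series()]; attribute `"ground_truth"` records
#'   the coupling spec, mixing weights, source family, and seed.
#' @examples
#' cs <- coupling_spec(4, 0.9, labels = c("L5L", "L5R", "L6L", "L6R"))
#' mc <- gen_coupled_multichannel(cs, "one_over_f", n = 2^14, seed = 7)
#' round(cor(mc$values), 2)
#' @export
gen_coupled_multichannel <- function(coupling, source = c("one_over_f", "fgn",
                                                          "cdp_train"),
                                     n, seed = NULL, H = 0.9,
                                     event_spec = cdp_event_spec(),
                                     sampling_rate = DEFAULT_RATE) {
  stopifnot(inherits(coupling, "coupling_spec"))
  source <- match.arg(source)
  n <- as.integer(n)
  w <- coupling_weights(coupling$coupling)
  vals <- with_seed(seed, {
    shared <- switch(source,
      one_over_f = gen_one_over_f(n, seed = NULL, sampling_rate = sampling_rate)$values,
      fgn = gen_fgn(H, n, seed = NULL, sampling_rate = sampling_rate)$values,
      cdp_train = {
        ts <- gen_cdp_train(event_spec, duration_s = n / sampling_rate,
                            sampling_rate = sampling_rate, seed = NULL)
        v <- ts$values[seq_len(n)]
        (v - mean(v)) / stats::sd(v)
      })
    out <- matrix(0, n, coupling$k)
    for (c in seq_len(coupling$k)) {
      priv <- stats::rnorm(n)
      ch <- w[c] * shared + sqrt(max(0, 1 - w[c]^2)) * priv
      if (coupling$noise_floor > 0) {
        ch <- ch + coupling$noise_floor * stats::rnorm(n)
      }
      out[, c] <- ch
    }
    out
  })
  mc <- multichannel_series(vals, sampling_rate, coupling$labels)
  attr(mc, "ground_truth") <- list(coupling = coupling, weights = w,
                                   source = source,
                                   H = if (source == "fgn") H else NULL,
                                   seed = seed)
  mc
}
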