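test_that("white noise generator is seeded, centered, and uncorrelated", {
  x <- gen_white_noise(1e5, seed = 1)
  y <- gen_white_noise(1e5, seed = 1)
  z <- gen_white_noise(1e5, seed = 2)
  expect_identical(x$values, y$values)
  expect_false(identical(x$values, z$values))
  n <- length(x$values)
  expect_lt(abs(mean(x$values)), 3 / sqrt(n))
  r1 <- cor(x$values[-1], x$values[-n])
  expect_lt(abs(r1), 3 / sqrt(n))
})

test_that("fGn matches its closed-form autocovariance and unit variance", {
  H <- 0.8
  x <- gen_fgn(H, 2^17, seed = 4)$values
  expect_lt(abs(var(x) - 1), 0.02)
  emp <- acf(x, lag.max = 5, plot = FALSE, demean = TRUE)$acf[2:6]
  expect_lt(max(abs(emp - fgn_gamma(1:5, H))), 0.02)
  # H = 0.5 reduces to white noise: lags 1..10 all near zero
  w <- gen_fgn(0.5, 2^16, seed = 5)$values
  empw <- acf(w, lag.max = 10, plot = FALSE)$acf[2:11]
  expect_lt(max(abs(empw)), 3 / sqrt(length(w)))
  expect_error(gen_fgn(1.2, 100), class = "mdfa_validation_error")
})

test_that("1/f noise has periodogram slope ~ -1 and is seed-stable", {
  x <- gen_one_over_f(2^16, seed = 6)
  expect_identical(x$values, gen_one_over_f(2^16, seed = 6)$values)
  sp <- spec.pgram(ts(x$values), plot = FALSE, taper = 0)
  # central two decades of the frequency axis
  keep <- sp$freq > 1e-3 & sp$freq < 1e-1
  slope <- unname(coef(lm(log10(sp$spec[keep]) ~ log10(sp$freq[keep])))[2])
  expect_lt(abs(slope + 1), 0.1)
  # odd lengths keep the spectrum Hermitian (real output, finite values)
  xo <- gen_one_over_f(3333, seed = 7)
  expect_true(all(is.finite(xo$values)))
  expect_lt(abs(sd(xo$values) - 1), 1e-12)
})

test_that("CDP trains realize Poisson event counts and in-range durations", {
  spec <- cdp_event_spec(rate = 2)
  counts <- vapply(1:20, function(s) {
    ts <- gen_cdp_train(spec, duration_s = 60, sampling_rate = 200, seed = s)
    ev <- attr(ts, "events")
    expect_true(all(ev$duration_s >= 0.1 & ev$duration_s <= 0.3))
    nrow(ev)
  }, numeric(1))
  # z-test of the mean count against Poisson(120)
  z <- (mean(counts) - 120) / sqrt(120 / 20)
  expect_lt(abs(z), 3)
  # rate 0 leaves the pure noise floor
  quiet <- gen_cdp_train(cdp_event_spec(rate = 0), duration_s = 10,
                         sampling_rate = 200, seed = 1, noise_sd = 0.5)
  expect_equal(nrow(attr(quiet, "events")), 0)
  expect_lt(abs(sd(quiet$values) - 0.5), 0.05)
  # event waveform is biphasic and zero-mean so trains add no drift
  w <- mdfa:::biphasic_hann(256)
  expect_lt(abs(mean(w)), 1e-12)
  expect_lt(min(w), 0); expect_gt(max(w), 0)
})

test_that("coupling specs validate and lesions compose multiplicatively", {
  cs <- coupling_spec(4, 0.9, labels = c("L5L", "L5R", "L6L", "L6R"))
  expect_equal(unname(diag(cs$coupling)), rep(1, 4))
  expect_error(coupling_spec(3, 1.4), class = "mdfa_validation_error")
  bad <- matrix(0.5, 3, 3); diag(bad) <- 1; bad[1, 2] <- 0.7
  expect_error(coupling_spec(3, bad), class = "mdfa_validation_error")

  l0 <- apply_lesion(cs, 0, list(c("L5L", "L6L")))
  expect_equal(l0$coupling, cs$coupling)
  l1 <- apply_lesion(cs, 1, list(c("L5L", "L6L")))
  expect_equal(l1$coupling["L5L", "L6L"], 0)
  expect_equal(l1$coupling["L6L", "L5L"], 0)
  a <- apply_lesion(apply_lesion(cs, 0.5, list(c("L5L", "L6L"))),
                    0.5, list(c("L5L", "L6L")))
  expect_equal(a$coupling["L5L", "L6L"], 0.9 * 0.25)
  expect_equal(a$coupling, t(a$coupling))
  expect_error(apply_lesion(cs, 0.5, list(c("L5L", "nope"))),
               class = "mdfa_validation_error")
})

test_that("rank-1 weights reproduce uniform couplings exactly", {
  C <- matrix(0.64, 4, 4); diag(C) <- 1
  expect_equal(mdfa:::coupling_weights(C), rep(0.8, 4), tolerance = 1e-10)
  expect_equal(mdfa:::coupling_weights(diag(3)), rep(0, 3))
})

test_that("coupled channels hit their target pairwise correlations", {
  # full coupling, no noise: all channels identical
  cs1 <- coupling_spec(3, 1, noise_floor = 0)
  mc1 <- gen_coupled_multichannel(cs1, "one_over_f", 2^12, seed = 8)
  expect_equal(mc1$values[, 1], mc1$values[, 2], tolerance = 1e-12)
  expect_equal(min(cor(mc1$values)), 1, tolerance = 1e-12)
  # zero coupling: independent channels
  cs0 <- coupling_spec(3, 0)
  mc0 <- gen_coupled_multichannel(cs0, "one_over_f", 1e5, seed = 9)
  cc0 <- cor(mc0$values)
  expect_lt(max(abs(cc0[upper.tri(cc0)])), 0.02)
  # intermediate rho: correlation ~ rho
  for (rho in c(0.3, 0.7)) {
    cs <- coupling_spec(4, rho)
    mc <- gen_coupled_multichannel(cs, "fgn", 1e5, seed = 30 + 10 * rho, H = 0.7)
    cc <- cor(mc$values)
    expect_lt(max(abs(cc[upper.tri(cc)] - rho)), 0.03)
  }
})

test_that("ground truth rides along with generated ensembles", {
  cs <- coupling_spec(2, 0.5, labels = c("a", "b"))
  mc <- gen_coupled_multichannel(cs, "fgn", 2^10, seed = 3, H = 0.6)
  gt <- attr(mc, "ground_truth")
  expect_identical(gt$coupling$coupling, cs$coupling)
  expect_equal(gt$weights, rep(sqrt(0.5), 2), tolerance = 1e-10)
  expect_identical(gt$source, "fgn")
  expect_identical(gt$H, 0.6)
  expect_identical(gt$seed, 3)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_fgn(0.7, 256, seed = 1))
  invisible(gen_white_noise(256, seed = 2))
  invisible(gen_one_over_f(256, seed = 3))
  expect_identical(.Random.seed, before)
})
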