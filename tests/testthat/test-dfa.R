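test_that("profile integration removes the mean and telescopes to zero", {
  expect_equal(integrate_profile(c(1, 2, 3)), c(-1, -1, 0))
  expect_equal(integrate_profile(c(5, 5, 5, 5)), c(0, 0, 0, 0))
  set.seed(11)
  for (x in list(rnorm(1), rnorm(100), runif(1000, -5, 5))) {
    prof <- integrate_profile(x)
    expect_equal(length(prof), length(x))
    expect_lt(abs(prof[length(prof)]), 1e-9 * max(1, max(abs(prof))))
  }
  expect_error(integrate_profile(c(1, NA, 3)), class = "mdfa_validation_error")
  expect_error(integrate_profile(c(1, Inf)), class = "mdfa_validation_error")
})

test_that("box partitioning is disjoint, contiguous, and truncates the tail", {
  p <- partition_boxes(10, 3)
  expect_equal(p$n_boxes, 3L)
  expect_equal(p$covered_length, 9L)
  expect_equal(p$box_starts, c(1L, 4L, 7L))
  p <- partition_boxes(8, 4)
  expect_equal(p$n_boxes, 2L)
  expect_equal(p$covered_length, 8L)
  expect_error(partition_boxes(5, 6), class = "mdfa_box_error")
  expect_error(partition_boxes(100, 3, order = 2), class = "mdfa_box_error")
})

test_that("fluctuation vanishes on box-wise detrendable profiles", {
  # a profile that is exactly linear inside every box of size 8
  prof <- rep(seq_len(8), 4) * 2.5 - 3
  expect_equal(fluctuation(prof, 8, order = 1), 0)
  expect_equal(fluctuation(rep(1.3, 64), 16, order = 1), 0)
  expect_equal(fluctuation(rep(0, 64), 4, order = 1), 0)
})

test_that("fluctuation matches the brute-force per-box oracle", {
  set.seed(42)
  x <- rnorm(500)
  prof <- integrate_profile(x)
  for (m in 1:3) {
    for (n in c(8, 16, 25)) {
      expect_equal(fluctuation(prof, n, order = m),
                   oracle_fluctuation(x, n, m),
                   tolerance = 1e-10)
    }
  }
  expect_error(fluctuation(prof, 4, order = 3), class = "mdfa_box_error")
})

test_that("two-sided fluctuation averages forward and backward partitions", {
  set.seed(7)
  x <- rnorm(101)           # 101 %% 16 != 0, so the two partitions differ
  prof <- integrate_profile(x)
  fwd2 <- fluctuation(prof, 16)^2
  bwd2 <- fluctuation(rev(prof), 16)^2
  expect_equal(fluctuation(prof, 16, two_sided = TRUE)^2, (fwd2 + bwd2) / 2,
               tolerance = 1e-12)
})

test_that("fluctuation curves compose pointwise and validate the schedule", {
  set.seed(3)
  x <- rnorm(600)
  sched <- c(8, 16, 32, 64)
  curve <- fluctuation_curve(x, sched)
  prof <- integrate_profile(x)
  expect_equal(curve$fluctuations,
               vapply(sched, function(n) fluctuation(prof, n), numeric(1)))
  expect_equal(fluctuation_curve(rep(2, 600), sched)$fluctuations,
               c(0, 0, 0, 0))
  expect_error(fluctuation_curve(x, integer(0)), class = "mdfa_schedule_error")
  expect_error(fluctuation_curve(x, c(16, 8)), class = "mdfa_schedule_error")
})

test_that("default schedule is log-spaced with a bounded size count", {
  sched <- default_box_schedule(2^16)
  expect_gte(length(sched), 4)
  expect_lte(length(sched), 50)
  expect_true(!is.unsorted(sched, strictly = TRUE))
  expect_equal(min(sched), 6)                    # 2 * (m + 2) for m = 1
  expect_lte(max(sched), 2^16 / 4)
  # roughly uniform in log space over the later octaves
  ratios <- diff(log2(sched[sched > 64]))
  expect_lt(max(ratios), 0.5)
  expect_error(default_box_schedule(12), class = "mdfa_schedule_error")
})

test_that("scaling fit recovers exact power laws and flags degenerate input", {
  ns <- c(4, 8, 16, 32, 64)
  curve <- structure(list(box_sizes = ns, fluctuations = 2 * ns^0.7,
                          order = 1L, n_samples = 1000L, two_sided = FALSE),
                     class = "fluctuation_curve")
  fit <- fit_scaling(curve)
  expect_equal(fit$alpha, 0.7, tolerance = 1e-9)
  expect_equal(fit$intercept, log10(2), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$n_range, c(4, 64))

  flat <- curve; flat$fluctuations <- rep(3.2, 5)
  expect_equal(fit_scaling(flat)$alpha, 0, tolerance = 1e-12)

  withzero <- curve; withzero$fluctuations[2] <- 0
  expect_warning(fitz <- fit_scaling(withzero), "F\\(n\\) = 0")
  expect_equal(fitz$n_points, 4L)

  few <- curve
  few$box_sizes <- ns[1:3]; few$fluctuations <- (2 * ns^0.7)[1:3]
  expect_error(fit_scaling(few), class = "mdfa_fit_error")
})

test_that("n_range restricts the points used by the fit", {
  set.seed(5)
  curve <- fluctuation_curve(rnorm(4096))
  full <- fit_scaling(curve)
  sub <- fit_scaling(curve, n_range = c(16, 256))
  expect_gte(sub$n_range[1], 16)
  expect_lte(sub$n_range[2], 256)
  expect_lt(sub$n_points, full$n_points)
})

test_that("dfa is deterministic and respects scale/offset invariances", {
  x <- gen_white_noise(4096, seed = 99)$values
  r1 <- dfa(x); r2 <- dfa(x)
  expect_identical(r1, r2)

  # offset invariance: exact, by mean removal
  r_off <- dfa(x + 42)
  expect_equal(r_off$curve$fluctuations, r1$curve$fluctuations)
  expect_equal(r_off$fit$alpha, r1$fit$alpha)

  # scale equivariance: F scales by c, alpha and R^2 unchanged
  r_sc <- dfa(3 * x)
  expect_equal(r_sc$curve$fluctuations, 3 * r1$curve$fluctuations)
  expect_equal(r_sc$fit$alpha, r1$fit$alpha, tolerance = 1e-12)
  expect_equal(r_sc$fit$r_squared, r1$fit$r_squared, tolerance = 1e-12)
})

test_that("higher detrending order never increases F(n)", {
  set.seed(21)
  x <- cumsum(rnorm(2048))          # strongly trended input
  prof <- integrate_profile(x)
  for (n in c(16, 32, 64)) {
    f1 <- fluctuation(prof, n, order = 1)
    f2 <- fluctuation(prof, n, order = 2)
    f3 <- fluctuation(prof, n, order = 3)
    expect_lte(f2, f1 + 1e-12)
    expect_lte(f3, f2 + 1e-12)
  }
})

test_that("dfa recovers known exponents on calibrated noises", {
  # white noise -> alpha ~ 0.5 (3 seeds at moderate N for speed)
  a_white <- vapply(1:3, function(s) dfa(gen_white_noise(5e4, seed = s))$fit$alpha,
                    numeric(1))
  expect_lt(abs(mean(a_white) - 0.5), 0.03)
  # fGn H = 0.9 -> alpha ~ 0.9
  a_fgn <- dfa(gen_fgn(0.9, 2^16, seed = 8))$fit$alpha
  expect_lt(abs(a_fgn - 0.9), 0.05)
})
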