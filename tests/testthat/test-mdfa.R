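test_that("componentwise integration matches single-channel integration", {
  set.seed(10)
  mat <- matrix(rnorm(300), ncol = 3)
  mc <- make_mc(mat)
  profs <- integrate_profile_mc(mc)
  for (c in 1:3) {
    expect_equal(profs[, c], integrate_profile(mat[, c]))
    expect_lt(abs(profs[nrow(profs), c]), 1e-9)
  }
  # two identical channels give two identical profiles
  mc2 <- make_mc(cbind(mat[, 1], mat[, 1]))
  profs2 <- integrate_profile_mc(mc2)
  expect_identical(profs2[, 1], profs2[, 2])
  # ragged channel lists are rejected
  expect_error(multichannel_series(list(rnorm(10), rnorm(11))),
               class = "mdfa_validation_error")
})

test_that("pooled fluctuation reduces to single-channel DFA at k = 1", {
  set.seed(12)
  x <- rnorm(500)
  prof <- integrate_profile(x)
  for (n in c(8, 32)) {
    expect_identical(fluctuation_mc(matrix(prof, ncol = 1), n),
                     fluctuation(prof, n))
  }
})

test_that("k identical channels pool to the single-channel fluctuation", {
  set.seed(13)
  x <- rnorm(400)
  prof <- integrate_profile(x)
  mat <- matrix(rep(prof, 4), ncol = 4)
  for (n in c(8, 16, 50)) {
    expect_equal(fluctuation_mc(mat, n), fluctuation(prof, n),
                 tolerance = 1e-14)
  }
})

test_that("pooled F(n)^2 equals the mean of per-channel F(n)^2", {
  set.seed(14)
  mat <- matrix(rnorm(3 * 700), ncol = 3)
  profs <- apply(mat, 2, function(x) cumsum(x - mean(x)))
  for (n in c(8, 16, 32)) {
    pooled <- fluctuation_mc(profs, n)
    expect_equal(pooled, oracle_fluctuation_mc(mat, n), tolerance = 1e-10)
    perch <- vapply(1:3, function(c) fluctuation(profs[, c], n), numeric(1))
    expect_equal(pooled^2, mean(perch^2), tolerance = 1e-12)
  }
})

test_that("mdfa with one channel is identical to dfa on that channel", {
  x <- gen_white_noise(4096, seed = 77)
  mc <- multichannel_series(matrix(x$values, ncol = 1), x$sampling_rate, "only")
  r_m <- mdfa(mc)
  r_s <- dfa(x$values)
  expect_identical(r_m$curve$fluctuations, r_s$curve$fluctuations)
  expect_identical(r_m$fit$alpha, r_s$fit$alpha)
})

test_that("channel order and duplication leave the pooled result unchanged", {
  set.seed(15)
  mat <- matrix(rnorm(4 * 2048), ncol = 4)
  base <- mdfa(make_mc(mat, labels = c("a", "b", "c", "d")))
  perm <- mdfa(make_mc(mat[, c(3, 1, 4, 2)], labels = c("c", "a", "d", "b")))
  expect_equal(perm$curve$fluctuations, base$curve$fluctuations,
               tolerance = 1e-13)
  expect_equal(perm$fit$alpha, base$fit$alpha, tolerance = 1e-13)
  dup <- mdfa(make_mc(mat[, c(1:4, 1:4)],
                      labels = c(letters[1:4], LETTERS[1:4])))
  expect_equal(dup$curve$fluctuations, base$curve$fluctuations,
               tolerance = 1e-13)
  expect_equal(dup$fit$alpha, base$fit$alpha, tolerance = 1e-13)
})

test_that("mdfa of k copies of one series equals dfa of that series", {
  x <- gen_one_over_f(4096, seed = 31)$values
  mc <- make_mc(matrix(rep(x, 4), ncol = 4))
  expect_equal(mdfa(mc)$fit$alpha, dfa(x)$fit$alpha, tolerance = 1e-13)
})

test_that("per-channel z-scoring equalizes unequal gains", {
  set.seed(16)
  x <- rnorm(4096)
  mc_gain <- make_mc(cbind(x, 100 * x), labels = c("lo", "hi"))
  raw <- mdfa(mc_gain)
  norm <- mdfa(mc_gain, normalize = TRUE)
  # raw pooling is dominated by the high-gain channel
  expect_equal(raw$curve$fluctuations,
               fluctuation_curve(x)$fluctuations * sqrt((1 + 100^2) / 2),
               tolerance = 1e-10)
  # normalized pooling matches the unit-variance channel exactly
  expect_equal(norm$curve$fluctuations,
               fluctuation_curve(x / sd(x))$fluctuations,
               tolerance = 1e-10)
})

test_that("ensemble alpha increases with coupling to a 1/f shared source", {
  rhos <- c(0.1, 0.5, 0.9)
  mean_alpha <- vapply(rhos, function(rho) {
    mean(vapply(1:10, function(s) {
      cs <- coupling_spec(4, rho)
      mc <- gen_coupled_multichannel(cs, "one_over_f", 2^13,
                                     seed = 1000 * s + round(100 * rho))
      mdfa(mc)$fit$alpha
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_alpha) > 0))
})
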