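test_that("occurrence probability matches independent quadrature", {
  # adaptive quadrature of the stationary beta density, written from the
  # log-density (no incomplete-beta call), is the oracle
  N <- 1000; d <- 1 / N
  for (p in c(1e-4, 1e-3, 1e-2, 0.1, 0.5)) {
    for (m in c(1e-3, 0.01, 0.1, 0.5, 1)) {
      q <- integrate(betaDensity, d, 1, N = N, m = m, p = p,
                     rel.tol = 1e-12, subdivisions = 2000L)$value
      expect_lt(abs(occurrenceProbability(p, N, m, d) - q), 1e-8)
    }
  }
})

test_that("occurrence probability has the right limits and monotonicity", {
  # N m -> 0: the beta mass collapses onto {0, 1} with weight p at 1
  expect_equal(occurrenceProbability(0.3, 1000, 1e-9, 0.01), 0.3,
               tolerance = 1e-4)
  # N m -> infinity: the beta concentrates at p, so detection is a step
  expect_equal(occurrenceProbability(0.05, 1e6, 1, 0.01), 1)
  expect_equal(occurrenceProbability(0.005, 1e6, 1, 0.01), 0)
  # monotone increasing in p at fixed (N, m, d)
  p <- seq(1e-4, 0.999, length.out = 200)
  phi <- occurrenceProbability(p, 1000, 0.1, 1e-3)
  expect_true(all(diff(phi) >= 0))
  expect_true(all(phi >= 0 & phi <= 1))
  expect_error(occurrenceProbability(0, 1000, 0.1, 1e-3), "strictly inside")
  expect_error(occurrenceProbability(1, 1000, 0.1, 1e-3), "strictly inside")
})

test_that("binomial occurrence probability matches its closed form", {
  expect_equal(binomialOccurrenceProbability(0.001, 1000, 1 / 1000),
               1 - 0.999^1000)
  expect_equal(binomialOccurrenceProbability(1e-12, 1000, 1 / 1000), 0,
               tolerance = 1e-8)
  expect_equal(binomialOccurrenceProbability(1, 1000, 1 / 1000), 1)
  p <- seq(0, 1, length.out = 100)
  expect_true(all(diff(binomialOccurrenceProbability(p, 500, 0.01)) >= 0))
  # with a higher threshold it is a proper binomial tail, not 1-(1-p)^N
  expect_equal(binomialOccurrenceProbability(0.01, 100, 0.02),
               1 - dbinom(0, 100, 0.01) - dbinom(1, 100, 0.01))
})

test_that("the coefficient of determination follows its definition", {
  f <- c(0.2, 0.5, 0.9)
  expect_equal(rSquared(f, f), 1)
  expect_equal(rSquared(f, rep(mean(f), 3)), 0)
  # hand arithmetic: RSS = 0.02, TSS = 37/150, R^2 = 34/37
  expect_equal(rSquared(f, c(0.3, 0.5, 0.8)), 34 / 37)
  # invariant under joint permutation
  o <- c(3, 1, 2)
  expect_equal(rSquared(f[o], c(0.3, 0.5, 0.8)[o]), 34 / 37)
  expect_error(rSquared(c(0.5, 0.5), c(0.4, 0.6)), "constant")
  expect_error(rSquared(c(0.5), c(0.4)), "at least two")
  expect_error(rSquared(f, c(0.1, 0.2)), "equal length")
})
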