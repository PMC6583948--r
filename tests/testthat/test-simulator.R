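test_that("transition probabilities are complete and hit known edges", {
  for (N in c(5, 50)) {
    for (m in c(0, 0.3, 1)) {
      for (p in c(0, 0.2, 1)) {
        tp <- transitionProbabilities(0:N, N, m, p)
        expect_equal(tp$up + tp$down + tp$stay, rep(1, N + 1))
        expect_true(all(tp$up >= 0 & tp$down >= 0 & tp$stay >= -1e-15))
      }
    }
  }
  # a monomorphic community of the source's only taxon cannot lose it
  expect_equal(transitionProbabilities(50, 50, 0.3, 1)$down, 0)
  # with certain immigration from an empty start, growth is a source draw
  expect_equal(transitionProbabilities(0, 50, 1, 0.37)$up, 0.37)
})

test_that("without immigration communities drift to monodominance", {
  src <- rep(1 / 10, 10)
  cfg <- simulationConfig(S = 5, N = 50, m = 0, steps = 5e4, seed = 21)
  ens <- simulateEnsemble(cfg, src)
  expect_true(all(apply(ens@counts, 2, max) == 50))
})

test_that("community size is conserved at every checkpoint", {
  src <- sourceCommunity(20, seed = 31)
  cfg <- simulationConfig(S = 4, N = 100, m = 0.1, steps = 2e4, seed = 32)
  snaps <- simulateCheckpoints(cfg, src, checkpoints = c(0, 10, 123, 5e3, 2e4))
  for (e in snaps$ensembles)
    expect_true(all(colSums(e@counts) == 100))
  expect_equal(length(snaps$ensembles), 5L)
})

test_that("simulation is reproducible given the config seed", {
  src <- sourceCommunity(30, seed = 41)
  cfg <- simulationConfig(S = 3, N = 100, m = 0.2, steps = 1e4, seed = 42)
  e1 <- simulateEnsemble(cfg, src)
  e2 <- simulateEnsemble(cfg, src)
  expect_identical(e1@counts, e2@counts)
})

test_that("with certain immigration the community is a binomial sample", {
  # at m = 1 every replacement is an iid source draw, so the focal count
  # is Binomial(N, p) at stationarity
  emp <- focalCountDistribution(N = 100, m = 1, p = 0.3, events = 4e6,
                                seed = 51, thin = 400)
  expect_lt(totalVariation(emp, dbinom(0:100, 100, 0.3)), 0.02)
})

test_that("the stationary oracle is a proper symmetric distribution", {
  pi1 <- stationaryDistribution(50, m = 0.1, p = 0.2)
  expect_equal(sum(pi1), 1)
  expect_true(all(pi1 >= 0))
  pi2 <- stationaryDistribution(40, m = 0.25, p = 0.5)
  expect_equal(pi2, rev(pi2), tolerance = 1e-12)
})

test_that("the simulator agrees with the detailed-balance oracle", {
  emp <- focalCountDistribution(N = 50, m = 0.1, p = 0.2, events = 1e6,
                                seed = 61)
  oracle <- stationaryDistribution(50, m = 0.1, p = 0.2)
  expect_lt(totalVariation(emp, oracle), 0.03)
})

test_that("the beta approximation matches the exact chain at large N", {
  tv <- totalVariation(stationaryDistribution(200, 0.1, 0.1),
                       betaStationaryApproximation(200, 0.1, 0.1))
  expect_lt(tv, 0.05)
})

test_that("ensembles convert to OTU tables that feed the pipeline", {
  src <- sourceCommunity(40, seed = 71)
  cfg <- simulationConfig(S = 10, N = 1000, m = 0.3, steps = 1e5, seed = 72)
  ens <- simulateEnsemble(cfg, src)
  tab <- ensembleToOtuTable(ens)
  expect_true(all(colSums(otuCounts(tab)) == 1000))
  # multinomial read sampling at the rarefaction depth passes rarefy
  # unchanged
  seq_tab <- ensembleToOtuTable(ens, sequencingDepth = 1000, seed = 73)
  expect_true(all(colSums(otuCounts(seq_tab)) == 1000))
  rar <- rarefy(seq_tab, depth = 1000, seed = 74)
  expect_identical(otuCounts(rar), otuCounts(seq_tab))
})

test_that("stationary mean abundances track the source pool", {
  # at m = 1 each sample is a fresh multinomial draw, so pBar is an
  # average of S binomial proportions; check the abundant taxa against
  # the binomial standard error
  src <- sourceCommunity(30, seed = 81)
  S <- 30; N <- 1000
  cfg <- simulationConfig(S = S, N = N, m = 1, steps = 5e4, seed = 82)
  st <- taxonStats(ensembleToOtuTable(simulateEnsemble(cfg, src)))
  idx <- match(st@taxonId, paste0("taxon_", seq_along(src)))
  top <- order(src[idx], decreasing = TRUE)[1:10]
  se <- sqrt(src[idx][top] * (1 - src[idx][top]) / N / S)
  expect_true(all(abs(st@pBar[top] - src[idx][top]) < 4 * se))
})

test_that("transient communities neutralize over time", {
  src <- sourceCommunity(100, seed = 91)
  cfg <- simulationConfig(S = 20, N = 500, m = 0.1, steps = 2e5,
                          initMode = "colonizers", k = 5, seed = 92)
  tc <- timeCourseNeutrality(cfg, src,
                             checkpoints = c(0, 1e3, 1e4, 1e5, 2e5),
                             B = 20)
  expect_equal(nrow(tc), 5L)
  expect_equal(tc$events, c(0, 1e3, 1e4, 1e5, 2e5))
  # founder communities look non-neutral; equilibrated ones do not
  expect_lt(tc$r_squared[1], 0.5)
  expect_gt(tc$r_squared[5], tc$r_squared[1])
})
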