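test_that("bootstrap intervals are deterministic and well-formed", {
  tab <- neutralTable()
  b1 <- bootstrapFit(tab, B = 30, seed = 7)
  b2 <- bootstrapFit(tab, B = 30, seed = 7)
  expect_identical(b1$rSquared@replicates, b2$rSquared@replicates)
  expect_lte(b1$rSquared@lower, b1$rSquared@upper)
  expect_lte(b1$mHat@lower, b1$mHat@upper)
  expect_equal(b1$rSquared@B, 30L)
  # endpoints are order statistics of the replicate vector
  reps <- sort(b1$rSquared@replicates)
  expect_true(b1$rSquared@lower %in% reps)
  expect_true(b1$rSquared@upper %in% reps)
  # invariant to column order of the input table
  cts <- otuCounts(tab)
  perm <- otuExperiment(cts[, rev(seq_len(ncol(cts)))])
  b3 <- bootstrapFit(perm, B = 30, seed = 7)
  expect_equal(b3$rSquared@lower, b1$rSquared@lower)
  expect_equal(b3$rSquared@upper, b1$rSquared@upper)
})

test_that("degenerate bootstrap inputs are handled explicitly", {
  tab <- neutralTable()
  expect_warning(b <- bootstrapFit(tab, B = 1, seed = 1), "degenerate")
  expect_equal(b$rSquared@lower, b$rSquared@upper)
  expect_equal(b$rSquared@lower, b$rSquared@replicates[1])
  # identical duplicated samples leave every taxon at f = 1: the
  # occurrence frequencies are constant and the fit is undefined
  one <- matrix(c(100L, 300L, 600L), nrow = 3,
                dimnames = list(paste0("t", 1:3), "s1"))
  dup <- otuExperiment(one[, rep(1, 10)] |>
                         `colnames<-`(paste0("s", 1:10)))
  expect_error(bootstrapFit(dup, B = 5, seed = 1), "fit failed")
  tiny <- otuExperiment(one[, rep(1, 2)] |> `colnames<-`(c("a", "b")))
  expect_error(bootstrapFit(tiny, B = 5, seed = 1), "at least 3 samples")
})

test_that("the matched neutral benchmark reproduces the fitting regime", {
  tab <- neutralTable(S = 25, N = 500, D = 80, m = 0.1, steps = 2e5,
                      seed = 3)
  st <- taxonStats(tab)
  fit <- fitNeutral(st)
  bench <- matchedNeutralBenchmark(st, fit@mHat, steps = 2e5, B = 20,
                                   seed = 11)
  expect_s4_class(bench$fit, "NeutralFit")
  # even a perfectly neutral metacommunity does not fit perfectly at
  # finite S and D
  expect_lt(bench$fit@rSquared, 1)
  expect_gt(bench$fit@rSquared, 0.5)
  # on data that ARE neutral, the empirical fit quality is of the same
  # order as the benchmark point estimate
  expect_lt(abs(bench$fit@rSquared - fit@rSquared), 0.2)
  few <- makeTaxonStats(c(0.4, 0.6), c(0.5, 0.9), N = 500, S = 25)
  expect_error(matchedNeutralBenchmark(few, 0.1), "too few taxa")
})

test_that("goodness of fit degrades at very small host counts", {
  tab <- neutralTable(S = 30, N = 1000, D = 150, m = 0.05, steps = 5e5,
                      seed = 5)
  curve <- subsampleCurve(tab, sizes = c(3, 10, 30), reps = 30, seed = 13)
  expect_equal(curve$size, c(3, 10, 30))
  expect_true(all(curve$n_used > 0))
  expect_lt(curve$mean_r_squared[1], curve$mean_r_squared[3])
  # tiny sizes stay finite and produce a (wide) interval, not a crash
  tiny <- subsampleCurve(tab, sizes = 2, reps = 20, seed = 17)
  expect_true(is.finite(tiny$mean_r_squared) || tiny$n_used == 0)
  # determinism
  curve2 <- subsampleCurve(tab, sizes = c(3, 10, 30), reps = 30, seed = 13)
  expect_identical(curve, curve2)
})

test_that("read depth has little effect on neutral data", {
  # deeply sequenced neutral communities re-rarefied at several depths:
  # the goodness of fit should not move much
  src <- sourceCommunity(150, seed = 23)
  cfg <- simulationConfig(S = 30, N = 5000, m = 0.05, steps = 5e5,
                          seed = 24)
  tab <- ensembleToOtuTable(simulateEnsemble(cfg, src),
                            sequencingDepth = 50000, seed = 25)
  curve <- depthCurve(tab, depths = c(1000, 3000, 10000), reps = 3,
                      seed = 26)
  expect_equal(curve$n_samples, rep(30L, 3))
  expect_lt(max(curve$mean_r_squared) - min(curve$mean_r_squared), 0.1)
  expect_error(depthCurve(tab, depths = 1e6), "exceeds every sample")
})

test_that("core taxa are cross-tabulated against the band labels", {
  tab <- neutralTable()
  cl <- classifyTaxa(fitNeutral(taxonStats(tab)))
  all_taxa <- coreTaxa(cl, threshold = 0)
  expect_equal(nrow(all_taxa), length(cl@taxonId))
  omni <- coreTaxa(cl, threshold = 1)
  expect_true(all(omni$f == 1))
  core <- coreTaxa(cl, threshold = 0.9)
  expect_true(all(core$f >= 0.9))
  expect_equal(sum(attr(core, "table")), nrow(core))
})

test_that("taxon overlap is a set comparison on a lineage rank", {
  lin <- function(g) paste0("Bacteria;P;C;O;F;", g)
  t1 <- otuExperiment(matrix(1:4, 2, dimnames = list(c("a", "b"),
                                                     c("s1", "s2"))),
                      taxonomy = lin(c("G1", "G2")))
  t2 <- otuExperiment(matrix(1:4, 2, dimnames = list(c("x", "y"),
                                                     c("s1", "s2"))),
                      taxonomy = lin(c("G2", "G3")))
  ov <- taxonOverlap(t1, t2)
  expect_equal(ov$counts[["shared"]], 1L)
  expect_equal(ov$shared, "G2")
  same <- taxonOverlap(t1, t1)
  expect_equal(same$counts[["xOnly"]], 0L)
  expect_equal(same$counts[["shared"]], 2L)
  t3 <- otuExperiment(matrix(1:4, 2, dimnames = list(c("p", "q"),
                                                     c("s1", "s2"))),
                      taxonomy = lin(c("G8", "G9")))
  expect_equal(taxonOverlap(t1, t3)$counts[["shared"]], 0L)
  plain <- otuExperiment(matrix(1:4, 2, dimnames = list(c("p", "q"),
                                                        c("s1", "s2"))))
  expect_error(taxonOverlap(t1, plain), "taxonomy")
})
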