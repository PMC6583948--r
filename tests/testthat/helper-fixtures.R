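# Shared generators: all fixtures are built in code, no files needed
# beyond the bundled simulated ensemble under inst/extdata.

toyCounts <- function() {
  matrix(c(5L, 5L, 0L, 10L), nrow = 2,
         dimnames = list(c("OTU1", "OTU2"), c("s1", "s2")))
}

# A stationary neutral community table at moderate size; cached per
# parameter set so test files can reuse it cheaply.
.neutral_cache <- new.env(parent = emptyenv())
neutralTable <- function(S = 20, N = 500, D = 100, m = 0.1,
                         steps = 2e5, seed = 1) {
  key <- paste(S, N, D, m, steps, seed, sep = "_")
  if (is.null(.neutral_cache[[key]])) {
    src <- sourceCommunity(D, seed = seed)
    cfg <- simulationConfig(S = S, N = N, m = m, steps = steps,
                            seed = seed + 1)
    .neutral_cache[[key]] <- ensembleToOtuTable(simulateEnsemble(cfg, src))
  }
  .neutral_cache[[key]]
}

fixturePath <- function() {
  system.file("extdata", "simulated_neutral_ensemble.tsv",
              package = "SloanFit")
}

# Independent beta density for quadrature oracles (log-space, no pbeta).
betaDensity <- function(x, N, m, p) {
  a <- N * m * p
  b <- N * m * (1 - p)
  exp((a - 1) * log(x) + (b - 1) * log1p(-x) - lbeta(a, b))
}

totalVariation <- function(p, q) 0.5 * sum(abs(p - q))

# Empirical distribution of the focal-taxon count from thinned snapshots
# of a two-taxon simulation (one snapshot per expected generation).
focalCountDistribution <- function(N, m, p, events = 1e6, seed = 1,
                                   thin = N) {
  cfg <- simulationConfig(S = 1, N = N, m = m, steps = events, seed = seed)
  snaps <- simulateCheckpoints(cfg, c(p, 1 - p),
                               checkpoints = seq(thin, events, by = thin))
  counts <- vapply(snaps$ensembles, function(e) e@counts[1, 1], numeric(1))
  tabulate(counts + 1, nbins = N + 1) / length(counts)
}
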