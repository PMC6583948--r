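#' Transition probabilities of the neutral death-birth-immigration chain
#'
#' For a focal taxon at count n in a community of N individuals, with
#' immigration probability m and source abundance p, one death-birth event
#' changes the count by +1, -1 or 0 with probabilities
#' \deqn{P_{+} = \frac{N-n}{N}\Big(mp + (1-m)\frac{n}{N-1}\Big),}
#' \deqn{P_{-} = \frac{n}{N}\Big(m(1-p) + (1-m)\frac{N-n}{N-1}\Big),}
#' and \eqn{P_0 = 1 - P_{+} - P_{-}}: a uniformly chosen individual dies
#' and is replaced by an immigrant (probability m, source draw) or by the
#' offspring of one of the other N - 1 residents. Total community size is
#' conserved.
#'
#' @param n focal-taxon count, 0 <= n <= N; vectorized.
#' @param N community size. @param m immigration probability.
#' @param p focal-taxon source abundance.
#' @return a list with numeric vectors `up`, `down`, `stay` summing to 1.
#' @export
transitionProbabilities <- function(n, N, m, p) {
  stopifnot(all(n >= 0), all(n <= N), N >= 2, m >= 0, m <= 1,
            p >= 0, p <= 1)
  up <- (N - n) / N * (m * p + (1 - m) * n / (N - 1))
  down <- n / N * (m * (1 - p) + (1 - m) * (N - n) / (N - 1))
  stay <- n / N * (m * p + (1 - m) * (n - 1) / (N - 1)) +
    (N - n) / N * (m * (1 - p) + (1 - m) * (N - n - 1) / (N - 1))
  list(up = up, down = down, stay = stay)
}

#' Source-pool relative abundances
#'
#' The shared metacommunity the simulator immigrates from. Two shapes:
#' `"dirichlet"` draws a symmetric Dirichlet(alpha) vector over D taxa
#' (flat expected ranks, the default), `"geometric"` builds the
#' deterministic geometric rank-abundance series
#' \eqn{p_i \propto g^{i-1}} for a more realistic skew.
#'
#' @param D number of taxa in the pool.
#' @param distribution `"dirichlet"` or `"geometric"`.
#' @param alpha Dirichlet concentration (default 1).
#' @param g geometric decay per rank (default 0.98).
#' @param seed integer seed for the Dirichlet draw.
#' @return numeric vector of D positive abundances summing to 1.
#' @export
sourceCommunity <- function(D, distribution = c("dirichlet", "geometric"),
                            alpha = 1, g = 0.98, seed = NULL) {
  distribution <- match.arg(distribution)
  stopifnot(D >= 2)
  p <- switch(distribution,
    dirichlet = withSeed(seed, {
      x <- rgamma(D, shape = alpha, rate = 1)
      x <- pmax(x, .Machine$double.xmin)
      x / sum(x)
    }),
    geometric = {
      x <- g^(seq_len(D) - 1)
      x / sum(x)
    })
  p
}

#' Build a SimulationConfig
#'
#' @param S number of local communities (hosts).
#' @param N individuals per community.
#' @param m immigration probability.
#' @param steps death-birth events per community (one event = one time
#'   step).
#' @param initMode `"source"` (multinomial draw from the source pool,
#'   close to equilibrium) or `"colonizers"` (k founder taxa picked
#'   uniformly at equal abundance, a transient start).
#' @param k founder count for the colonizer start (default 5).
#' @param seed integer seed.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(S, N, m, steps, initMode = "source", k = 5L,
                             seed = NULL) {
  new("SimulationConfig", S = as.integer(S), N = as.integer(N),
      m = as.numeric(m), steps = as.numeric(steps),
      initMode = initMode, k = as.integer(k),
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: S = %d, N = %d, m = %.4g, steps = %.3g, init = %s",
    object@S, object@N, object@m, object@steps, object@initMode))
  if (object@initMode == "colonizers") cat(" (k =", object@k, ")")
  cat("\n")
})

# Initial D x S count matrix for an ensemble.
.initialCounts <- function(config, source) {
  D <- length(source)
  S <- config@S; N <- config@N
  if (config@initMode == "source") {
    matrix(rmultinom(S, size = N, prob = source), nrow = D)
  } else {
    k <- config@k
    if (k > D) stop("k colonizers exceed source-pool diversity D")
    # founders are picked uniformly over taxa (not by source abundance)
    # and arrive at random proportions (flat Dirichlet), so the initial
    # occurrence-abundance relation carries no neutral signal
    vapply(seq_len(S), function(s) {
      taxa <- sample.int(D, k)
      col <- integer(D)
      w <- rgamma(k, shape = 1)
      col[taxa] <- rmultinom(1L, size = N, prob = w / sum(w))[, 1L]
      col
    }, integer(D))
  }
}

#' Simulate an ensemble of neutral local communities
#'
#' Advances S independent communities by `config@steps` death-birth events
#' each (see [transitionProbabilities()] for the per-event rule; the
#' multi-taxon update draws the dying individual uniformly and its
#' replacement from the source with probability m or from the remaining
#' residents otherwise). Community size is conserved at every event.
#' Reproducible given `config@seed`.
#'
#' @param config a [SimulationConfig-class].
#' @param source source-pool abundances from [sourceCommunity()] (or any
#'   positive vector summing to 1).
#' @return a [CommunityEnsemble-class] at the final state.
#' @examples
#' src <- sourceCommunity(50, seed = 1)
#' cfg <- simulationConfig(S = 10, N = 200, m = 0.1, steps = 1e4, seed = 2)
#' simulateEnsemble(cfg, src)
#' @export
simulateEnsemble <- function(config, source) {
  snaps <- simulateCheckpoints(config, source,
                               checkpoints = config@steps)
  snaps$ensembles[[length(snaps$ensembles)]]
}

#' Simulate and record the ensemble at multiple checkpoints
#'
#' Runs one realization of the process and freezes the full ensemble state
#' at each requested event count, so transient trajectories can be fitted
#' without re-simulating.
#'
#' @inheritParams simulateEnsemble
#' @param checkpoints increasing per-community event counts; the last one
#'   is the total simulated length (checkpoint 0 records the initial
#'   state).
#' @return list with `checkpoints` and `ensembles`, a list of
#'   [CommunityEnsemble-class] objects of the same length.
#' @export
simulateCheckpoints <- function(config, source, checkpoints) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (abs(sum(source) - 1) > 1e-8) stop("source must sum to 1")
  checkpoints <- sort(unique(as.numeric(checkpoints)))
  if (any(checkpoints < 0)) stop("checkpoints must be >= 0")
  seed <- if (is.na(config@seed)) NULL else config@seed
  withSeed(seed, {
    init <- .initialCounts(config, source)
    # the C++ kernel needs strictly increasing targets; 0 means "record
    # the initial state before any event"
    arr <- .simulate_dbi(init, source, config@m, checkpoints + 0)
    D <- length(source)
    ens <- lapply(seq_along(checkpoints), function(ci) {
      cts <- matrix(arr[, , ci], nrow = D,
                    dimnames = list(paste0("taxon_", seq_len(D)),
                                    paste0("community_", seq_len(config@S))))
      new("CommunityEnsemble", counts = cts, source = source,
          config = config, events = checkpoints[ci])
    })
    list(checkpoints = checkpoints, ensembles = ens)
  })
}

setMethod("show", "CommunityEnsemble", function(object) {
  cat("CommunityEnsemble:", nrow(object@counts), "taxa x",
      ncol(object@counts), "communities of N =", object@config@N,
      "after", format(object@events, big.mark = ","), "events\n")
})

#' Convert a simulated ensemble to an OTU table
#'
#' Communities become samples, taxa become rows. Without
#' `sequencingDepth`, counts are the community states themselves (column
#' sums = N). With `sequencingDepth`, each community is multinomially
#' subsampled to that many reads, emulating sequencing before
#' rarefaction.
#'
#' @param ensemble a [CommunityEnsemble-class].
#' @param sequencingDepth optional reads per sample.
#' @param seed integer seed for the multinomial read draw.
#' @return an [OtuExperiment-class].
#' @export
ensembleToOtuTable <- function(ensemble, sequencingDepth = NULL,
                               seed = NULL) {
  cts <- ensemble@counts
  if (!is.null(sequencingDepth)) {
    stopifnot(sequencingDepth >= 1)
    cts <- withSeed(seed, {
      out <- vapply(seq_len(ncol(cts)), function(j)
        rmultinom(1L, size = sequencingDepth,
                  prob = cts[, j] / sum(cts[, j]))[, 1L],
        integer(nrow(cts)))
      dimnames(out) <- dimnames(ensemble@counts)
      out
    })
  }
  otuExperiment(cts)
}

#' R-squared of the neutral fit along a transient trajectory
#'
#' The in-silico neutralization experiment: communities start far from
#' equilibrium (a few random colonizers each), and at each checkpoint the
#' frozen ensemble is converted to an OTU table, the full neutral fit is
#' run, and the goodness of fit recorded with a bootstrap CI. Under purely
#' neutral dynamics the trend is increasing: transient communities look
#' non-neutral until drift and immigration wash out the founder
#' configuration.
#'
#' @param config a [SimulationConfig-class] with
#'   `initMode = "colonizers"`.
#' @param source source-pool abundances.
#' @param checkpoints event counts at which to fit (0 = initial state).
#' @param B bootstrap replicates per checkpoint (default 100).
#' @return data.frame with columns events, r_squared, lower, upper,
#'   m_hat, n_taxa (NA rows where a checkpoint had too few taxa to fit).
#' @export
timeCourseNeutrality <- function(config, source, checkpoints, B = 100L) {
  if (config@initMode != "colonizers")
    stop("time-course experiment requires initMode = 'colonizers'")
  snaps <- simulateCheckpoints(config, source, checkpoints)
  seed <- if (is.na(config@seed)) NULL else config@seed + 1
  boot_seeds <- substreamSeeds(seed, length(snaps$ensembles))
  rows <- lapply(seq_along(snaps$ensembles), function(i) {
    ens <- snaps$ensembles[[i]]
    tab <- ensembleToOtuTable(ens)
    res <- tryCatch({
      fit <- fitNeutral(taxonStats(tab))
      bs <- bootstrapFit(tab, B = B, seed = boot_seeds[i])
      data.frame(events = ens@events, r_squared = fit@rSquared,
                 lower = bs$rSquared@lower, upper = bs$rSquared@upper,
                 m_hat = fit@mHat, n_taxa = length(fit@phi))
    }, error = function(e)
      data.frame(events = ens@events, r_squared = NA_real_,
                 lower = NA_real_, upper = NA_real_, m_hat = NA_real_,
                 n_taxa = NA_integer_))
    res
  })
  do.call(rbind, rows)
}
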