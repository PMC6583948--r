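#' Exact stationary distribution of the two-taxon marginal chain
#'
#' The focal-taxon count under the death-birth-immigration process is a
#' one-dimensional birth-death chain on {0, ..., N}, so its stationary
#' distribution follows from detailed balance:
#' \deqn{\pi(n+1)/\pi(n) = P_{+}(n) / P_{-}(n+1),}
#' with the per-event rates of [transitionProbabilities()]. Computed in log
#' space and normalized. This is the brute-force oracle used to validate
#' both the stochastic simulator and the beta (diffusion) approximation of
#' the stationary state.
#'
#' @param N community size (exact computation is cheap for N up to a few
#'   thousand).
#' @param m immigration probability in (0, 1\].
#' @param p focal-taxon source abundance in (0, 1).
#' @return numeric vector of N + 1 stationary probabilities over counts
#'   0..N.
#' @examples
#' pi <- stationaryDistribution(50, m = 0.1, p = 0.2)
#' sum(pi)  # 1
#' @export
stationaryDistribution <- function(N, m, p) {
  stopifnot(N >= 2, m > 0, m <= 1, p > 0, p < 1)
  n <- 0:(N - 1)
  up <- transitionProbabilities(n, N, m, p)$up
  down <- transitionProbabilities(n + 1, N, m, p)$down
  logpi <- c(0, cumsum(log(up) - log(down)))
  logpi <- logpi - max(logpi)
  w <- exp(logpi)
  w / sum(w)
}

#' Discretized beta approximation of the stationary distribution
#'
#' Bins the continuous Beta(Nmp, Nm(1-p)) stationary density onto the
#' count grid {0, ..., N} (cell n covers relative abundances
#' \eqn{[(n-1/2)/N, (n+1/2)/N)}, with the boundary cells absorbing the
#' tails), for direct comparison against [stationaryDistribution()].
#'
#' @inheritParams stationaryDistribution
#' @return numeric vector of N + 1 probabilities.
#' @export
betaStationaryApproximation <- function(N, m, p) {
  stopifnot(N >= 2, m > 0, m <= 1, p > 0, p < 1)
  a <- N * m * p
  b <- N * m * (1 - p)
  edges <- (0:(N + 1) - 0.5) / N
  edges[1] <- 0
  edges[N + 2] <- 1
  diff(pbeta(edges, a, b))
}
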