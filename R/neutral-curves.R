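#' Neutral occurrence probability of a taxon
#'
#' Under the Sloan neutral model the stationary distribution of a taxon's
#' relative abundance x in a local community of N individuals with
#' immigration probability m from a source pool where the taxon has
#' relative abundance p is Beta(N m p, N m (1 - p)). The probability of
#' observing the taxon above a detection threshold d is the upper tail of
#' that beta distribution,
#' \deqn{\Phi = 1 - I_d(Nmp,\; Nm(1-p)),}
#' with I the regularized incomplete beta function. Computed via the upper
#' tail of `pbeta`, which is accurate in log space even for extreme shape
#' parameters.
#'
#' @param p source relative abundance, in (0, 1); vectorized. p = 0 or 1 is
#'   degenerate and rejected (callers clip boundary taxa).
#' @param N local community size (reads per sample), >= 2.
#' @param m immigration probability, in (0, 1].
#' @param d detection threshold, in (0, 1).
#' @return occurrence probabilities in \[0, 1\].
#' @examples
#' occurrenceProbability(p = 0.01, N = 1000, m = 0.1, d = 0.001)
#' @export
occurrenceProbability <- function(p, N, m, d) {
  stopifnot(N >= 2, m > 0, m <= 1, d > 0, d < 1)
  if (any(p <= 0 | p >= 1))
    stop("p must lie strictly inside (0, 1); clip or drop boundary taxa")
  a <- N * m * p
  b <- N * m * (1 - p)
  pbeta(d, a, b, lower.tail = FALSE)
}

#' Binomial (random-sampling) occurrence probability
#'
#' The parameter-free alternative model: a local community is a plain
#' binomial sample of N reads from the source pool, so a taxon at source
#' abundance p is observed when at least `ceiling(N d)` of the N draws hit
#' it. With the default one-read threshold (d = 1/N) this is
#' \eqn{1 - (1 - p)^N}.
#'
#' @inheritParams occurrenceProbability
#' @return occurrence probabilities in \[0, 1\].
#' @export
binomialOccurrenceProbability <- function(p, N, d) {
  stopifnot(N >= 2, d > 0, d < 1)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  thr <- ceiling(N * d)
  pbinom(thr - 1, size = N, prob = p, lower.tail = FALSE)
}

#' Coefficient of determination of an occurrence curve
#'
#' `1 - RSS/TSS`: one minus the ratio of the residual sum of squares around
#' the predicted curve to the total sum of squares around the mean observed
#' occurrence frequency. Can be negative for a fit worse than the mean;
#' never exceeds 1.
#'
#' @param f observed occurrence frequencies.
#' @param phi predicted occurrence probabilities, same length.
#' @return a single numeric.
#' @examples
#' rSquared(c(0.2, 0.5, 0.9), c(0.3, 0.5, 0.8))
#' @export
rSquared <- function(f, phi) {
  if (length(f) != length(phi)) stop("f and phi must have equal length")
  if (length(f) < 2L) stop("at least two taxa are required")
  tss <- sum((f - mean(f))^2)
  if (tss == 0) stop("constant observed occurrence frequencies: R^2 undefined")
  1 - sum((f - phi)^2) / tss
}
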