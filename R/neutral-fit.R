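#' Fit the neutral occurrence-abundance curve
#'
#' Calibrates the immigration probability m by nonlinear least squares:
#' \eqn{\hat m = \arg\min_m \sum_i (f_i - \Phi_i(m))^2}, where
#' \eqn{\Phi_i(m)} is [occurrenceProbability()] evaluated at each taxon's
#' mean relative abundance. m is the model's only free parameter. The
#' optimizer is deterministic: bounded L-BFGS-B restarted from a fixed grid
#' of initial values, best residual sum of squares wins, ties broken toward
#' the smaller m. Taxa with `pBar >= 1` are clipped to `1 - 1e-9` before
#' evaluation.
#'
#' The returned [NeutralFit-class] carries the predicted curve, the 95\%
#' prediction band ([confidenceBands()]), the coefficient of determination
#' ([rSquared()]) and least-squares AICs of the neutral (k = 1) and of the
#' parameter-free binomial sampling model (k = 0).
#'
#' @param stats a [TaxonStats-class] with at least 3 usable taxa.
#' @param level band coverage, default 0.95.
#' @param starts initial-value grid for the optimizer.
#' @param lowerM lower bound of the m search interval.
#' @return a [NeutralFit-class].
#' @examples
#' p <- seq(0.001, 0.2, length.out = 50)
#' f <- occurrenceProbability(p, 1000, 0.1, 1 / 1000)
#' fitNeutral(makeTaxonStats(p, f, N = 1000, S = 50))
#' @export
fitNeutral <- function(stats, level = 0.95,
                       starts = c(0.01, 0.05, 0.1, 0.3, 0.7),
                       lowerM = 1e-6) {
  stopifnot(is(stats, "TaxonStats"))
  eps <- 1e-9
  p <- pmin(stats@pBar, 1 - eps)
  f <- stats@f
  if (length(p) < 3L)
    stop("need at least 3 taxa with 0 < pBar < 1 to calibrate m")
  N <- stats@N; d <- stats@d; S <- stats@S

  rss_fun <- function(m) sum((f - occurrenceProbability(p, N, m, d))^2)
  fits <- lapply(starts, function(s0)
    tryCatch(optim(s0, rss_fun, method = "L-BFGS-B", lower = lowerM,
                   upper = 1),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("optimizer failed to converge from every start; starts = ",
         paste(starts, collapse = ", "))
  fits <- fits[ok]
  rss_vals <- vapply(fits, `[[`, numeric(1), "value")
  m_vals <- vapply(fits, function(z) z$par, numeric(1))
  best_rss <- min(rss_vals)
  cand <- which(rss_vals <= best_rss + 1e-12)
  best <- cand[which.min(m_vals[cand])]
  m_hat <- m_vals[best]
  rss <- rss_vals[best]

  phi <- occurrenceProbability(p, N, m_hat, d)
  band <- confidenceBands(phi, S, level = level)
  phi_b <- binomialOccurrenceProbability(p, N, d)
  rss_b <- sum((f - phi_b)^2)
  n <- length(f)
  new("NeutralFit", stats = stats, mHat = m_hat, phi = phi,
      lower = band$lower, upper = band$upper,
      rSquared = rSquared(f, phi),
      aic = .aicLS(n, rss, k = 1L),
      aicBinomial = .aicLS(n, rss_b, k = 0L),
      rss = rss, rssBinomial = rss_b, level = level,
      fitInfo = list(starts = starts[ok], rss = rss_vals, m = m_vals,
                     convergence = vapply(fits, `[[`, numeric(1),
                                          "convergence")))
}

# Least-squares AIC: n log(RSS/n) + 2k. RSS = 0 collapses to -Inf, which
# callers must treat as a flagged sentinel.
.aicLS <- function(n, rss, k) {
  if (rss <= 0) return(-Inf)
  n * log(rss / n) + 2 * k
}

#' Prediction bands for observable occurrence frequencies
#'
#' For a fitted occurrence probability `phi` and S sampled hosts, the
#' observable occurrence frequency is Binomial(S, phi)/S; the band is the
#' pair of exact binomial quantiles at `(alpha/2, 1 - alpha/2)`, i.e. the
#' finite-sample noise a perfectly neutral taxon would show. Degenerate
#' `phi` of 0 or 1 give zero-width bands.
#'
#' @param phi predicted occurrence probabilities.
#' @param S number of samples (>= 2).
#' @param level coverage, default 0.95.
#' @return list with numeric vectors `lower` and `upper`.
#' @examples
#' confidenceBands(0.5, S = 10)  # (0.2, 0.8)
#' @export
confidenceBands <- function(phi, S, level = 0.95) {
  stopifnot(S >= 2, level > 0, level < 1)
  alpha <- (1 - level) / 2
  list(lower = qbinom(alpha, S, phi) / S,
       upper = qbinom(1 - alpha, S, phi) / S)
}

#' Compare the neutral fit against the binomial sampling model
#'
#' Least-squares AIC comparison on the same taxa:
#' `AIC = n log(RSS/n) + 2k` with k = 1 for the neutral curve (the fitted
#' m) and k = 0 for the binomial curve (no free parameter). The preferred
#' model is the one with the smaller AIC.
#'
#' @param fit a [NeutralFit-class].
#' @return a data.frame with one row per model (aic, rss, k) plus
#'   attributes `deltaAIC` (binomial minus neutral) and `preferred`.
#' @export
aicCompare <- function(fit) {
  stopifnot(is(fit, "NeutralFit"))
  out <- data.frame(
    model = c("neutral", "binomial"),
    k = c(1L, 0L),
    rss = c(fit@rss, fit@rssBinomial),
    aic = c(fit@aic, fit@aicBinomial),
    stringsAsFactors = FALSE)
  attr(out, "deltaAIC") <- fit@aicBinomial - fit@aic
  attr(out, "preferred") <-
    out$model[which.min(out$aic)]
  attr(out, "degenerate") <- !all(is.finite(out$aic))
  out
}

#' @describeIn fitNeutral fitted immigration probability.
#' @param x a NeutralFit.
#' @export
setMethod("immigrationRate", "NeutralFit", function(x) x@mHat)

#' @describeIn fitNeutral coefficient of determination of the fit.
#' @export
setMethod("goodnessOfFit", "NeutralFit", function(x) x@rSquared)

setMethod("show", "NeutralFit", function(object) {
  cat("NeutralFit:", length(object@phi), "taxa, S =", object@stats@S,
      ", N =", object@stats@N, "\n")
  cat(sprintf("  m_hat = %.4g   R^2 = %.3f\n", object@mHat,
              object@rSquared))
  cat(sprintf("  AIC neutral = %.1f, binomial = %.1f (preferred: %s)\n",
              object@aic, object@aicBinomial,
              if (object@aic <= object@aicBinomial) "neutral"
              else "binomial"))
})

#' Per-taxon results of a neutral fit as a data.frame
#'
#' Columns: taxon_id, (taxonomy), p_bar, f, phi, lower, upper, label.
#' @param x a [NeutralFit-class].
#' @param ... ignored.
#' @export
#' @method as.data.frame NeutralFit
as.data.frame.NeutralFit <- function(x, ...) {
  cl <- classifyTaxa(x)
  df <- data.frame(taxon_id = x@stats@taxonId,
                   p_bar = x@stats@pBar, f = x@stats@f, phi = x@phi,
                   lower = x@lower, upper = x@upper, label = cl@label,
                   stringsAsFactors = FALSE)
  if (length(x@stats@taxonomy)) df$taxonomy <- x@stats@taxonomy
  df
}

setMethod("as.data.frame", "NeutralFit", as.data.frame.NeutralFit)

#' Fit summary as a plain list (JSON-ready)
#' @param fit a [NeutralFit-class].
#' @export
fitSummary <- function(fit) {
  list(m_hat = fit@mHat, r_squared = fit@rSquared, aic_neutral = fit@aic,
       aic_binomial = fit@aicBinomial,
       delta_aic = fit@aicBinomial - fit@aic,
       n_taxa = length(fit@phi), S = fit@stats@S, N = fit@stats@N,
       d = fit@stats@d)
}
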