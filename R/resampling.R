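# Host-resampling machinery: bootstrap CIs, matched neutral benchmarks,
# subsampling and read-depth sensitivity curves.

# One fit on a column subset of a uniform-depth table; NULL when the
# replicate is unusable (too few taxa, constant f, optimizer failure).
.fitColumns <- function(cts, cols, d = NULL) {
  sub <- cts[, cols, drop = FALSE]
  sub <- sub[rowSums(sub) > 0L, , drop = FALSE]
  colnames(sub) <- paste0("rep_", seq_along(cols))
  tryCatch(fitNeutral(taxonStats(otuExperiment(sub), d = d)),
           error = function(e) NULL)
}

#' Bootstrap confidence intervals for the neutral fit
#'
#' Resamples the hosts (sample columns) with replacement B times,
#' re-running the whole statistics + fit pipeline on each replicate, and
#' reports percentile intervals for the goodness of fit and the
#' immigration estimate. Replicates on which the fit is impossible (fewer
#' than 3 taxa, constant occurrence) are discarded and counted.
#'
#' @param x a uniform-depth [OtuExperiment-class] (rarefy first).
#' @param B bootstrap replicates, default 100. `B = 1` degenerates to a
#'   zero-width interval with a warning.
#' @param seed master seed; replicates use derived substreams, so results
#'   are reproducible and invariant to execution order.
#' @param d detection threshold passed to [taxonStats()].
#' @param level CI coverage, default 0.95.
#' @return list with two [BootstrapResult-class] entries, `rSquared` and
#'   `mHat`.
#' @export
bootstrapFit <- function(x, B = 100L, seed = NULL, d = NULL,
                         level = 0.95) {
  cts <- otuCounts(x)
  cts <- cts[, order(colnames(cts)), drop = FALSE]  # column-order invariance
  S <- ncol(cts)
  if (S < 3L) stop("need at least 3 samples to bootstrap")
  if (B < 1L) stop("B must be >= 1")
  if (B == 1L) warning("B = 1 gives a degenerate (zero-width) interval")
  full <- .fitColumns(cts, seq_len(S), d = d)
  if (is.null(full)) stop("full-data fit failed; nothing to bootstrap")
  seeds <- substreamSeeds(seed, B)
  r2 <- m <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    cols <- withSeed(seeds[b], sample.int(S, S, replace = TRUE))
    fit <- .fitColumns(cts, cols, d = d)
    if (!is.null(fit)) { r2[b] <- fit@rSquared; m[b] <- fit@mHat }
  }
  discarded <- sum(is.na(r2))
  mk <- function(stat, point, reps) {
    ci <- percentileCI(reps, level)
    new("BootstrapResult", statistic = stat, point = point,
        lower = ci[1], upper = ci[2], replicates = reps,
        B = as.integer(B), discarded = as.integer(discarded),
        level = level)
  }
  list(rSquared = mk("rSquared", full@rSquared, r2),
       mHat = mk("mHat", full@mHat, m))
}

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf(
    "BootstrapResult (%s): %.4g, %g%% CI [%.4g, %.4g] from %d replicates",
    object@statistic, object@point, 100 * object@level, object@lower,
    object@upper, object@B))
  if (object@discarded > 0L)
    cat(" (", object@discarded, "discarded )")
  cat("\n")
})

#' Matched neutral benchmark for an empirical fit
#'
#' The yardstick against which an empirical goodness of fit is judged:
#' a completely neutral in-silico metacommunity with the same number of
#' hosts, the same taxon richness, the same reads per sample and the
#' fitted immigration rate, simulated to equilibrium and pushed through
#' the identical fitting pipeline. Even a perfectly neutral community
#' yields R-squared < 1 at finite S and D, so raw R-squared values are
#' only interpretable against this benchmark.
#'
#' @param stats the empirical [TaxonStats-class].
#' @param mHat the fitted immigration probability.
#' @param steps events per community (default 1e6, long enough for
#'   equilibrium at these parameter scales).
#' @param sourceDistribution source-pool shape for the simulation,
#'   `"dirichlet"` (default) or `"geometric"` (see [sourceCommunity()]).
#' @param B bootstrap replicates for the benchmark CI.
#' @param seed integer seed.
#' @return list with `fit` (the benchmark [NeutralFit-class]) and
#'   `rSquared` / `mHat` [BootstrapResult-class] intervals.
#' @export
matchedNeutralBenchmark <- function(stats, mHat, steps = 1e6,
                                    sourceDistribution = "dirichlet",
                                    B = 100L, seed = NULL) {
  stopifnot(is(stats, "TaxonStats"))
  D <- length(stats@taxonId)
  if (D < 3L) stop("too few taxa (D < 3) for a meaningful benchmark")
  src <- sourceCommunity(D, distribution = sourceDistribution,
                         seed = if (is.null(seed)) NULL else seed + 1)
  cfg <- simulationConfig(S = stats@S, N = stats@N, m = mHat,
                          steps = steps, seed = seed)
  ens <- simulateEnsemble(cfg, src)
  tab <- ensembleToOtuTable(ens)
  fit <- fitNeutral(taxonStats(tab, d = stats@d))
  bs <- bootstrapFit(tab, B = B, d = stats@d,
                     seed = if (is.null(seed)) NULL else seed + 2)
  list(fit = fit, rSquared = bs$rSquared, mHat = bs$mHat)
}

#' Goodness of fit as a function of the number of sampled hosts
#'
#' For each requested host count, draws that many sample columns with
#' replacement `reps` times, refits, and aggregates the replicate
#' R-squared values into a mean and percentile interval. Reproduces the
#' subsampling robustness analysis: neutrality estimates stay flat over a
#' wide range of sample sizes and drop only at very small ones.
#'
#' @param x a uniform-depth [OtuExperiment-class].
#' @param sizes integer vector of host counts.
#' @param reps resamples per size, default 100.
#' @param seed master seed (substreams per size x replicate).
#' @param d detection threshold.
#' @param level CI coverage.
#' @return data.frame: size, mean_r_squared, lower, upper, n_used.
#' @export
subsampleCurve <- function(x, sizes, reps = 100L, seed = NULL, d = NULL,
                           level = 0.95) {
  cts <- otuCounts(x)
  cts <- cts[, order(colnames(cts)), drop = FALSE]  # column-order invariance
  S <- ncol(cts)
  stopifnot(all(sizes >= 2), all(sizes == round(sizes)))
  seeds <- substreamSeeds(seed, length(sizes) * reps)
  rows <- lapply(seq_along(sizes), function(i) {
    sz <- sizes[i]
    r2 <- vapply(seq_len(reps), function(r) {
      cols <- withSeed(seeds[(i - 1L) * reps + r],
                       sample.int(S, sz, replace = TRUE))
      fit <- .fitColumns(cts, cols, d = d)
      if (is.null(fit)) NA_real_ else fit@rSquared
    }, numeric(1))
    ci <- percentileCI(r2, level)
    data.frame(size = sz, mean_r_squared = mean(r2, na.rm = TRUE),
               lower = ci[1], upper = ci[2], n_used = sum(!is.na(r2)))
  })
  do.call(rbind, rows)
}

#' Goodness of fit as a function of rarefaction depth
#'
#' Re-rarefies the RAW table independently at each requested depth
#' (samples shallower than a depth are dropped for that depth), refits,
#' and aggregates over `reps` rarefaction draws. A depth no sample reaches
#' is an error.
#'
#' @param x the raw (un-rarefied) [OtuExperiment-class].
#' @param depths integer vector of read depths.
#' @param reps rarefaction draws per depth, default 10.
#' @param seed master seed.
#' @param level CI coverage.
#' @return data.frame: depth, mean_r_squared, lower, upper, n_samples,
#'   n_used.
#' @export
depthCurve <- function(x, depths, reps = 10L, seed = NULL, level = 0.95) {
  stopifnot(all(depths >= 1))
  totals <- colSums(otuCounts(x))
  if (any(depths > max(totals)))
    stop("depth ", max(depths), " exceeds every sample's total reads")
  seeds <- substreamSeeds(seed, length(depths) * reps)
  rows <- lapply(seq_along(depths), function(i) {
    dp <- depths[i]
    n_samples <- sum(totals >= dp)
    r2 <- vapply(seq_len(reps), function(r) {
      tryCatch({
        rar <- suppressWarnings(
          rarefy(x, depth = dp, seed = seeds[(i - 1L) * reps + r]))
        fitNeutral(taxonStats(rar))@rSquared
      }, error = function(e) NA_real_)
    }, numeric(1))
    ci <- percentileCI(r2, level)
    data.frame(depth = dp, mean_r_squared = mean(r2, na.rm = TRUE),
               lower = ci[1], upper = ci[2], n_samples = n_samples,
               n_used = sum(!is.na(r2)))
  })
  do.call(rbind, rows)
}

#' Core taxa and their neutral-band labels
#'
#' The prevalence-based core microbiota (occurrence frequency at or above
#' `threshold`) cross-tabulated against the neutral-band classification.
#' On neutral communities most core taxa fall within the band: high
#' prevalence alone is not evidence of host selection.
#'
#' @param classification a [TaxonClassification-class].
#' @param threshold minimum occurrence frequency, default 0.90.
#' @return data.frame of core taxa (taxon_id, f, label, taxonomy when
#'   present), with a `table` attribute holding the label cross-tab.
#' @export
coreTaxa <- function(classification, threshold = 0.90) {
  stopifnot(is(classification, "TaxonClassification"),
            threshold >= 0, threshold <= 1)
  df <- as.data.frame(classification)
  core <- df[df$f >= threshold, , drop = FALSE]
  rownames(core) <- NULL
  attr(core, "table") <-
    table(factor(core$label, levels = c("above", "within", "below")))
  core
}

#' Taxon overlap between two communities
#'
#' Set comparison of the taxa found in two OTU tables, matched on a
#' taxonomy rank (OTU identifiers are study-specific and do not match
#' across tables). Used e.g. to compare a host microbiota against its
#' surrounding environment.
#'
#' @param x,y [OtuExperiment-class] objects carrying taxonomy.
#' @param rank lineage rank used as key (negative = from the terminal
#'   rank; default -1).
#' @param delim lineage delimiter.
#' @return list with `shared`, `xOnly`, `yOnly` (character vectors of
#'   keys) and `counts` (named integer vector).
#' @export
taxonOverlap <- function(x, y, rank = -1L, delim = ";") {
  kx <- taxonomy(x); ky <- taxonomy(y)
  if (is.null(kx) || is.null(ky))
    stop("both tables must carry taxonomy to be matched")
  kx <- unique(stats::na.omit(.lineageRank(kx, rank, delim)))
  ky <- unique(stats::na.omit(.lineageRank(ky, rank, delim)))
  shared <- intersect(kx, ky)
  out <- list(shared = shared, xOnly = setdiff(kx, ky),
              yOnly = setdiff(ky, kx))
  out$counts <- c(shared = length(out$shared), xOnly = length(out$xOnly),
                  yOnly = length(out$yOnly))
  out
}
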