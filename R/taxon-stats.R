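#' Abundance and occurrence statistics of a rarefied OTU table
#'
#' Computes, for every taxon detected at least once, the mean relative
#' abundance across all S samples (zero-abundance samples included in the
#' mean, so that the x-axis of the occurrence-abundance curve estimates the
#' taxon's source-pool relative abundance) and the occurrence frequency
#' `f`: the fraction of samples whose rarefied count reaches the detection
#' threshold of `ceiling(N * d)` reads. With the default `d = 1/N` a single
#' read counts as detection.
#'
#' @param x an [OtuExperiment-class] already rarefied to a uniform depth N
#'   (non-uniform column sums are a hard error: the statistics are only
#'   defined on equal sample sizes).
#' @param d detection threshold as a fraction of N; default `1/N`.
#' @return a [TaxonStats-class] object.
#' @examples
#' cts <- matrix(c(10L, 990L, 0L, 1000L), nrow = 2,
#'               dimnames = list(c("a", "b"), c("s1", "s2")))
#' taxonStats(otuExperiment(cts))
#' @export
setMethod("taxonStats", "OtuExperiment", function(x, d = NULL, ...) {
  cts <- otuCounts(x)
  totals <- unname(colSums(cts))
  N <- totals[1L]
  if (any(totals != N))
    stop("column totals are not uniform; rarefy the table first")
  if (N < 1L) stop("empty samples")
  S <- ncol(cts)
  if (is.null(d)) d <- 1 / N
  stopifnot(d > 0, d <= 1)
  thr <- ceiling(N * d)
  pBar <- rowMeans(cts / N)
  f <- rowMeans(cts >= thr)
  keep <- f > 0
  tax <- taxonomy(x)
  new("TaxonStats",
      taxonId = rownames(cts)[keep],
      pBar = unname(pBar[keep]),
      f = unname(f[keep]),
      taxonomy = if (is.null(tax)) character() else tax[keep],
      N = as.integer(N), S = as.integer(S), d = d)
})

#' Assemble TaxonStats directly from vectors
#'
#' Escape hatch for synthetic curves and tests; [taxonStats()] on an
#' [OtuExperiment-class] is the data path.
#'
#' @param pBar,f numeric vectors of mean relative abundance and occurrence
#'   frequency.
#' @param N reads per sample; @param S number of samples;
#' @param d detection threshold (default 1/N).
#' @param taxonId,taxonomy optional identifiers/lineages.
#' @return a [TaxonStats-class].
#' @export
makeTaxonStats <- function(pBar, f, N, S, d = 1 / N, taxonId = NULL,
                           taxonomy = NULL) {
  if (is.null(taxonId)) taxonId <- paste0("taxon_", seq_along(pBar))
  new("TaxonStats", taxonId = as.character(taxonId), pBar = pBar, f = f,
      taxonomy = if (is.null(taxonomy)) character() else taxonomy,
      N = as.integer(N), S = as.integer(S), d = d)
}

setMethod("show", "TaxonStats", function(object) {
  cat("TaxonStats:", length(object@taxonId), "taxa from", object@S,
      "samples at", object@N, "reads/sample (d =",
      format(object@d, digits = 3), ")\n")
})

#' @export
#' @method as.data.frame TaxonStats
as.data.frame.TaxonStats <- function(x, ...) {
  df <- data.frame(taxon_id = x@taxonId, p_bar = x@pBar, f = x@f,
                   stringsAsFactors = FALSE)
  if (length(x@taxonomy)) df$taxonomy <- x@taxonomy
  df
}

setMethod("as.data.frame", "TaxonStats", as.data.frame.TaxonStats)
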