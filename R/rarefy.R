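#' Rarefy an OTU table to a common read depth
#'
#' Each sample is subsampled to exactly `depth` reads uniformly WITHOUT
#' replacement (multivariate hypergeometric), the standard way of
#' equalizing sampling effort across hosts. Samples with fewer than `depth`
#' reads are dropped with a warning and recorded in
#' `metadata(result)$rarefaction$dropped`; taxa left with all-zero rows are
#' removed. The draw is exact: taxon counts are generated by sequential
#' conditional hypergeometric sampling, which is equivalent to drawing
#' `depth` reads from the pooled reads of the sample.
#'
#' @param x an [OtuExperiment-class].
#' @param depth target reads per sample (>= 1).
#' @param seed integer; the result is deterministic given `seed`.
#' @return a rarefied [OtuExperiment-class] whose column sums all equal
#'   `depth`.
#' @examples
#' cts <- matrix(rpois(40, 50) + 1L, nrow = 4,
#'               dimnames = list(paste0("t", 1:4), paste0("s", 1:10)))
#' r <- rarefy(otuExperiment(cts), depth = 100, seed = 1)
#' colSums(otuCounts(r))
#' @export
setMethod("rarefy", "OtuExperiment", function(x, depth, seed = NULL, ...) {
  stopifnot(depth >= 1, depth == round(depth))
  cts <- otuCounts(x)
  totals <- colSums(cts)
  keep <- totals >= depth
  if (!any(keep))
    stop("no sample reaches the rarefaction depth of ", depth, " reads")
  dropped <- colnames(cts)[!keep]
  if (length(dropped))
    warning(length(dropped), " sample(s) below depth ", depth,
            " dropped: ", paste(dropped, collapse = ", "))
  cts <- cts[, keep, drop = FALSE]
  out <- withSeed(seed, apply(cts, 2L, .rarefyColumn, depth = depth))
  dimnames(out) <- dimnames(cts)
  nonzero <- rowSums(out) > 0L
  out <- out[nonzero, , drop = FALSE]
  res <- otuExperiment(out, taxonomy = taxonomy(x)[nonzero])
  metadata(res)$rarefaction <- list(depth = depth, dropped = dropped,
                                    seed = seed)
  res
})

# Multivariate hypergeometric draw of `depth` reads from one sample,
# by sequential conditioning: marginal of each taxon given the reads
# already allocated is univariate hypergeometric.
.rarefyColumn <- function(counts, depth) {
  total <- sum(counts)
  if (total == depth) return(as.integer(counts))
  out <- integer(length(counts))
  remaining_reads <- total
  remaining_draw <- depth
  for (i in seq_along(counts)) {
    if (remaining_draw == 0L) break
    ci <- counts[i]
    if (ci == 0L) { remaining_reads <- remaining_reads - ci; next }
    x <- rhyper(1L, m = ci, n = remaining_reads - ci, k = remaining_draw)
    out[i] <- x
    remaining_draw <- remaining_draw - x
    remaining_reads <- remaining_reads - ci
  }
  out
}
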