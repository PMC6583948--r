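#' OtuExperiment: an OTU count table with optional taxonomy
#'
#' A thin subclass of [SummarizedExperiment::SummarizedExperiment] holding a
#' single integer assay `"counts"` with taxa (OTUs) as rows and samples
#' (hosts or environmental replicates) as columns. An optional
#' rank-delimited lineage string per taxon (e.g.
#' `"Bacteria;Proteobacteria;...;Ochrobactrum"`) lives in
#' `rowData(x)$taxonomy`.
#'
#' @slot .placeholder inherited structure only; no extra slots.
#' @seealso [otuExperiment()], [readOtuTable()], [rarefy()], [taxonStats()]
#' @export
setClass("OtuExperiment", contains = "SummarizedExperiment")

setValidity("OtuExperiment", function(object) {
  msgs <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(is.na(cts)))
      msgs <- c(msgs, "counts contain NA")
    else {
      if (any(cts < 0)) msgs <- c(msgs, "counts must be non-negative")
      if (any(cts != round(cts))) msgs <- c(msgs, "counts must be integers")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
      msgs <- c(msgs, "taxon (row) identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
      msgs <- c(msgs, "sample (column) identifiers must be present and unique")
  }
  if (length(msgs)) msgs else TRUE
})

#' TaxonStats: per-taxon abundance/occurrence summaries of a rarefied table
#'
#' For each taxon detected in at least one sample: the mean relative
#' abundance across all S samples (zeros included) and the occurrence
#' frequency, i.e. the fraction of samples in which the taxon's rarefied
#' count reaches the detection threshold `ceiling(N * d)` reads. These are
#' the (x, y) coordinates of the occurrence-abundance curve the neutral
#' model is fitted to.
#'
#' @slot taxonId character, taxon identifiers.
#' @slot pBar numeric, mean relative abundance per taxon (sums to 1 on a
#'   complete table).
#' @slot f numeric in (0, 1], occurrence frequency per taxon.
#' @slot taxonomy character, lineage strings (length 0 when absent).
#' @slot N integer, reads per sample (the local community size).
#' @slot S integer, number of samples.
#' @slot d numeric, detection threshold as a fraction of N (default 1/N).
#' @export
setClass("TaxonStats",
  representation(taxonId = "character", pBar = "numeric", f = "numeric",
                 taxonomy = "character", N = "integer", S = "integer",
                 d = "numeric"))

setValidity("TaxonStats", function(object) {
  msgs <- character()
  n <- length(object@taxonId)
  if (length(object@pBar) != n || length(object@f) != n)
    msgs <- c(msgs, "taxonId, pBar and f must have equal length")
  if (length(object@taxonomy) && length(object@taxonomy) != n)
    msgs <- c(msgs, "taxonomy must be empty or one entry per taxon")
  if (anyDuplicated(object@taxonId))
    msgs <- c(msgs, "taxon identifiers must be unique")
  if (any(object@pBar <= 0) || any(object@pBar > 1))
    msgs <- c(msgs, "pBar must lie in (0, 1]")
  if (any(object@f <= 0) || any(object@f > 1))
    msgs <- c(msgs, "f must lie in (0, 1]")
  if (length(object@d) != 1L || object@d <= 0 || object@d > 1)
    msgs <- c(msgs, "d must be a single value in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' NeutralFit: a calibrated neutral occurrence-abundance curve
#'
#' Result of fitting the stationary neutral prediction to [TaxonStats]:
#' the least-squares immigration parameter `mHat`, the predicted occurrence
#' probability `phi` per taxon, the 95\% prediction band on observable
#' occurrence frequency, the coefficient of determination and the AIC of
#' the neutral and of the parameter-free binomial sampling model.
#'
#' @slot stats the [TaxonStats] the curve was fitted to.
#' @slot mHat numeric in (0, 1], fitted immigration probability.
#' @slot phi numeric, predicted occurrence probability per taxon.
#' @slot lower,upper numeric, per-taxon prediction band on f.
#' @slot rSquared numeric, 1 - RSS/TSS.
#' @slot aic numeric, least-squares AIC of the neutral model (k = 1).
#' @slot aicBinomial numeric, AIC of the binomial model (k = 0).
#' @slot rss,rssBinomial numeric, residual sums of squares.
#' @slot level numeric, band coverage level.
#' @slot fitInfo list, optimizer diagnostics (starts, convergence codes).
#' @export
setClass("NeutralFit",
  representation(stats = "TaxonStats", mHat = "numeric", phi = "numeric",
                 lower = "numeric", upper = "numeric", rSquared = "numeric",
                 aic = "numeric", aicBinomial = "numeric", rss = "numeric",
                 rssBinomial = "numeric", level = "numeric",
                 fitInfo = "list"))

setValidity("NeutralFit", function(object) {
  msgs <- character()
  n <- length(object@stats@taxonId)
  if (length(object@phi) != n || length(object@lower) != n ||
      length(object@upper) != n)
    msgs <- c(msgs, "phi/lower/upper must have one entry per taxon")
  if (object@mHat <= 0 || object@mHat > 1)
    msgs <- c(msgs, "mHat must lie in (0, 1]")
  if (any(object@phi < 0 | object@phi > 1))
    msgs <- c(msgs, "phi must lie in [0, 1]")
  if (any(object@lower > object@upper))
    msgs <- c(msgs, "band lower bounds must not exceed upper bounds")
  if (length(object@rSquared) != 1L || object@rSquared > 1 + 1e-12)
    msgs <- c(msgs, "rSquared must be a single value <= 1")
  if (length(msgs)) msgs else TRUE
})

#' TaxonClassification: neutral-band labels per taxon
#'
#' Per-taxon position relative to the 95\% band around the fitted neutral
#' curve: `"above"` (over-represented: observed in more samples than the
#' neutral expectation), `"within"`, or `"below"` (under-represented).
#'
#' @slot taxonId character.
#' @slot label character, one of above/within/below.
#' @slot f,phi,lower,upper numeric, the quantities behind the call.
#' @slot taxonomy character (length 0 when absent).
#' @export
setClass("TaxonClassification",
  representation(taxonId = "character", label = "character",
                 f = "numeric", phi = "numeric", lower = "numeric",
                 upper = "numeric", taxonomy = "character"))

setValidity("TaxonClassification", function(object) {
  msgs <- character()
  if (!all(object@label %in% c("above", "within", "below")))
    msgs <- c(msgs, "labels must be 'above', 'within' or 'below'")
  n <- length(object@taxonId)
  if (length(object@label) != n)
    msgs <- c(msgs, "one label per taxon required")
  if (length(msgs)) msgs else TRUE
})

#' SimulationConfig: parameters of the death-birth-immigration process
#'
#' @slot S integer, number of local communities (hosts).
#' @slot N integer, individuals per community (constant over time).
#' @slot m numeric in \[0, 1\], immigration probability per replacement.
#' @slot steps numeric, number of death-birth events per community (one
#'   event is one time step; the physical death rate only sets the clock).
#' @slot initMode `"source"` (multinomial draw of N individuals from the
#'   source pool) or `"colonizers"` (k founder taxa picked uniformly, each
#'   at abundance ~N/k: a deliberately non-equilibrium start).
#' @slot k integer, founder count for `initMode = "colonizers"`.
#' @slot seed integer or NA.
#' @export
setClass("SimulationConfig",
  representation(S = "integer", N = "integer", m = "numeric",
                 steps = "numeric", initMode = "character", k = "integer",
                 seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@N < 2L) msgs <- c(msgs, "N must be >= 2")
  if (object@S < 1L) msgs <- c(msgs, "S must be >= 1")
  if (object@m < 0 || object@m > 1) msgs <- c(msgs, "m must lie in [0, 1]")
  if (object@steps < 0) msgs <- c(msgs, "steps must be >= 0")
  if (!object@initMode %in% c("source", "colonizers"))
    msgs <- c(msgs, "initMode must be 'source' or 'colonizers'")
  if (object@initMode == "colonizers" && object@k < 1L)
    msgs <- c(msgs, "k must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' CommunityEnsemble: the state of S simulated local communities
#'
#' @slot counts integer matrix, taxa x communities; every column sums to N.
#' @slot source numeric, source-pool relative abundances (one per taxon).
#' @slot config the [SimulationConfig] that produced the state.
#' @slot events numeric, death-birth events executed per community.
#' @export
setClass("CommunityEnsemble",
  representation(counts = "matrix", source = "numeric",
                 config = "SimulationConfig", events = "numeric"))

setValidity("CommunityEnsemble", function(object) {
  msgs <- character()
  if (nrow(object@counts) != length(object@source))
    msgs <- c(msgs, "one source abundance per taxon row required")
  tot <- colSums(object@counts)
  if (length(tot) && any(tot != object@config@N))
    msgs <- c(msgs, "every community must sum to N (conservation)")
  if (length(msgs)) msgs else TRUE
})

#' BootstrapResult: a percentile bootstrap interval for a fit statistic
#'
#' Note the percentile construction does not guarantee that the full-data
#' point estimate lies inside \[lower, upper\]; lower <= upper always holds.
#'
#' @slot statistic character, e.g. "rSquared" or "mHat".
#' @slot point numeric, full-data point estimate.
#' @slot lower,upper numeric, percentile CI endpoints.
#' @slot replicates numeric, the B replicate values (NA where a replicate
#'   was discarded).
#' @slot B integer, requested number of replicates.
#' @slot discarded integer, replicates dropped (too few taxa / constant f).
#' @slot level numeric.
#' @export
setClass("BootstrapResult",
  representation(statistic = "character", point = "numeric",
                 lower = "numeric", upper = "numeric",
                 replicates = "numeric", B = "integer",
                 discarded = "integer", level = "numeric"))

setValidity("BootstrapResult", function(object) {
  if (isTRUE(object@lower > object@upper))
    "lower must not exceed upper" else TRUE
})
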