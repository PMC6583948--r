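#' Classify taxa against the neutral prediction band
#'
#' A taxon is `"above"` the neutral expectation when its observed
#' occurrence frequency exceeds the upper band limit (observed in more
#' hosts than neutrality predicts), `"below"` when under the lower limit,
#' `"within"` otherwise. Classification is invariant under taxon
#' reordering. No multiple-testing correction is applied; the
#' consistent-direction rule across independent populations
#' ([consistentNonneutral()]) is the false-positive control.
#'
#' @param fit a [NeutralFit-class].
#' @param ... ignored.
#' @return a [TaxonClassification-class].
#' @export
setMethod("classifyTaxa", "NeutralFit", function(fit, ...) {
  f <- fit@stats@f
  label <- ifelse(f > fit@upper, "above",
                  ifelse(f < fit@lower, "below", "within"))
  new("TaxonClassification", taxonId = fit@stats@taxonId, label = label,
      f = f, phi = fit@phi, lower = fit@lower, upper = fit@upper,
      taxonomy = fit@stats@taxonomy)
})

setMethod("show", "TaxonClassification", function(object) {
  tb <- table(factor(object@label, levels = c("above", "within", "below")))
  cat("TaxonClassification:", length(object@label), "taxa —",
      tb[["above"]], "above,", tb[["within"]], "within,",
      tb[["below"]], "below the neutral band\n")
})

#' @export
#' @method as.data.frame TaxonClassification
as.data.frame.TaxonClassification <- function(x, ...) {
  df <- data.frame(taxon_id = x@taxonId, f = x@f, phi = x@phi,
                   lower = x@lower, upper = x@upper, label = x@label,
                   stringsAsFactors = FALSE)
  if (length(x@taxonomy)) df$taxonomy <- x@taxonomy
  df
}

setMethod("as.data.frame", "TaxonClassification",
          as.data.frame.TaxonClassification)

# Extract one rank from a rank-delimited lineage string. `rank` is either a
# 1-based index from the left, or a negative index from the right (-1 = the
# terminal rank, typically genus in the study tables).
.lineageRank <- function(lineage, rank = -1L, delim = ";") {
  parts <- strsplit(lineage, delim, fixed = TRUE)
  vapply(parts, function(p) {
    p <- trimws(p)
    p <- p[nzchar(p)]
    if (!length(p)) return(NA_character_)
    i <- if (rank < 0) length(p) + rank + 1L else rank
    if (i < 1L || i > length(p)) NA_character_ else p[i]
  }, character(1))
}

#' Consistently non-neutral taxa across independent populations
#'
#' The conservative definition of non-neutrality: a taxon (matched across
#' populations by a taxonomy rank, since OTU identifiers differ between
#' studies) is called non-neutral only when it diverges from the neutral
#' band in the SAME direction in every supplied population. Within one
#' population a key (e.g. genus) is assigned a direction when at least one
#' of its member taxa lies off-band and all off-band members agree in
#' direction; keys whose members disagree get no direction.
#'
#' @param classifications a named list of [TaxonClassification-class],
#'   one per population; every element must carry taxonomy.
#' @param rank lineage rank used as the matching key: negative indexes
#'   count from the terminal rank (default -1, the genus in typical
#'   lineage strings).
#' @param delim lineage delimiter, default ";".
#' @return a data.frame keyed by lineage rank with one direction column per
#'   population and a `consistent_label` in `{"above", "below", "none"}`.
#' @export
consistentNonneutral <- function(classifications, rank = -1L, delim = ";") {
  stopifnot(length(classifications) >= 2L)
  per_pop <- lapply(classifications, function(cl) {
    stopifnot(is(cl, "TaxonClassification"))
    if (!length(cl@taxonomy))
      stop("taxonomy is required to match taxa across populations")
    key <- .lineageRank(cl@taxonomy, rank = rank, delim = delim)
    keep <- !is.na(key)
    tapply(cl@label[keep], key[keep], function(lab) {
      above <- any(lab == "above"); below <- any(lab == "below")
      if (above && !below) "above"
      else if (below && !above) "below"
      else "none"
    })
  })
  keys <- Reduce(intersect, lapply(per_pop, names))
  if (!length(keys))
    stop("no shared taxa across populations at the chosen rank")
  dirs <- vapply(per_pop, function(p) as.character(p[keys]),
                 character(length(keys)))
  dirs <- matrix(dirs, nrow = length(keys))
  consistent <- apply(dirs, 1L, function(z) {
    if (all(z == "above")) "above"
    else if (all(z == "below")) "below"
    else "none"
  })
  out <- data.frame(key = keys, dirs, consistent_label = consistent,
                    stringsAsFactors = FALSE)
  names(out) <- c("key", names(classifications) %||%
                    paste0("population_", seq_len(ncol(dirs))),
                  "consistent_label")
  rownames(out) <- NULL
  out
}
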