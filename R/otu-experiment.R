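#' Construct an OtuExperiment from a count matrix
#'
#' @param counts integer matrix of read counts, taxa as rows and samples as
#'   columns; dimnames are required and must be unique.
#' @param taxonomy optional character vector of rank-delimited lineages,
#'   one per taxon.
#' @return an [OtuExperiment-class] object.
#' @examples
#' cts <- matrix(c(5L, 5L, 0L, 10L), nrow = 2,
#'               dimnames = list(c("OTU1", "OTU2"), c("s1", "s2")))
#' otuExperiment(cts)
#' @export
otuExperiment <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) stop("empty OTU table")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("taxon and sample identifiers (dimnames) are required")
  storage.mode(counts) <- "integer"
  rd <- if (is.null(taxonomy)) {
    S4Vectors::DataFrame(row.names = rownames(counts))
  } else {
    if (length(taxonomy) != nrow(counts))
      stop("taxonomy must have one entry per taxon")
    S4Vectors::DataFrame(taxonomy = as.character(taxonomy),
                         row.names = rownames(counts))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd)
  new("OtuExperiment", se)
}

#' @describeIn otuExperiment integer count matrix accessor.
#' @param x an OtuExperiment.
#' @export
setMethod("otuCounts", "OtuExperiment", function(x)
  SummarizedExperiment::assay(x, "counts"))

#' @describeIn otuExperiment taxonomy accessor; NULL when no lineages are
#'   attached.
#' @export
setMethod("taxonomy", "OtuExperiment", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if ("taxonomy" %in% colnames(rd)) as.character(rd$taxonomy) else NULL
})

setMethod("show", "OtuExperiment", function(object) {
  cts <- otuCounts(object)
  cat("OtuExperiment with", nrow(cts), "taxa and", ncol(cts), "samples\n")
  cat("  reads per sample:",
      paste(range(colSums(cts)), collapse = " - "), "\n")
  cat("  taxonomy:", if (is.null(taxonomy(object))) "absent" else "present",
      "\n")
  rl <- metadata(object)$rarefaction
  if (!is.null(rl))
    cat("  rarefied to depth", rl$depth, "(", length(rl$dropped),
        "samples dropped )\n")
})

#' Read an OTU table from delimited text
#'
#' Reads a TSV/CSV OTU count table. In the default `"taxa_rows"` dialect
#' the first column holds taxon identifiers, remaining numeric columns hold
#' per-sample read counts, and an optional trailing non-numeric column
#' (conventionally named `taxonomy`) holds lineage strings. The
#' `"samples_rows"` dialect is the transpose (samples as rows, taxa as
#' columns; no taxonomy column).
#'
#' @param path file path to delimited text.
#' @param sep field separator; default tab, use "," for CSV.
#' @param orientation `"taxa_rows"` (default) or `"samples_rows"`.
#' @return a validated [OtuExperiment-class].
#' @details Malformed numeric cells, negative or fractional counts, and
#'   duplicated identifiers are hard errors naming the offending row and
#'   column; an empty table is a hard error.
#' @export
readOtuTable <- function(path, sep = "\t",
                         orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty OTU table: ", path)
  ids <- raw[[1L]]
  # data.frame subsetting uniquifies duplicated column names; keep the
  # original header so duplicate sample ids are detected, not masked
  header <- colnames(raw)[-1L]
  body <- raw[, -1L, drop = FALSE]
  taxonomy <- NULL
  if (orientation == "taxa_rows" &&
      grepl("^tax|lineage", header[length(header)], ignore.case = TRUE)) {
    taxonomy <- body[[ncol(body)]]
    body <- body[, -ncol(body), drop = FALSE]
    header <- header[-length(header)]
    if (ncol(body) == 0L) stop("no count columns in ", path)
  }
  counts <- matrix(NA_real_, nrow(body), ncol(body))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("malformed numeric cell at row '%s', column '%s'",
                   ids[bad[1L]], header[j]))
    counts[, j] <- v
  }
  if (any(counts < 0))
    stop("negative counts in ", path)
  if (any(counts != round(counts))) {
    idx <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at row '%s', column '%s'",
                 ids[idx[1L]], header[idx[2L]]))
  }
  dimnames(counts) <- list(ids, header)
  if (orientation == "samples_rows") counts <- t(counts)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon identifiers in ", path)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers in ", path)
  otuExperiment(counts, taxonomy = taxonomy)
}

#' Write an OtuExperiment as delimited text
#'
#' Inverse of [readOtuTable()] in the `"taxa_rows"` dialect: taxon
#' identifiers in the first column, one count column per sample, and a
#' trailing `taxonomy` column when lineages are present.
#'
#' @param x an [OtuExperiment-class].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeOtuTable <- function(x, path, sep = "\t") {
  cts <- otuCounts(x)
  df <- data.frame(taxon_id = rownames(cts), cts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  tax <- taxonomy(x)
  if (!is.null(tax)) df$taxonomy <- tax
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
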