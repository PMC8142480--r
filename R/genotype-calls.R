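#' Construct a GenotypeCalls object
#'
#' Wraps a dense character matrix of genotype calls (loci in rows, samples
#' in columns, values among [GT_STATES]) and its [SnpPanel-class] into a
#' [GenotypeCalls-class]. Rows are matched to the panel by rowname and
#' reordered into panel order; every panel locus must be present.
#'
#' @param callMatrix character matrix, `rownames` = marker ids,
#'   `colnames` = sample ids.
#' @param panel the [SnpPanel-class] the calls were made against.
#' @return A [GenotypeCalls-class].
#' @export
GenotypeCalls <- function(callMatrix, panel) {
  stopifnot(is.matrix(callMatrix), is(panel, "SnpPanel"))
  if (is.null(rownames(callMatrix))) {
    if (nrow(callMatrix) != length(panel))
      stop("unnamed call matrix must have one row per panel locus")
    rownames(callMatrix) <- snpIds(panel)
  }
  missingLoci <- setdiff(snpIds(panel), rownames(callMatrix))
  if (length(missingLoci))
    stop("call matrix lacks panel loci: ",
         paste(utils::head(missingLoci, 5), collapse = ", "))
  callMatrix <- callMatrix[snpIds(panel), , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = callMatrix), rowRanges = panel)
  new("GenotypeCalls", se)
}

#' GenotypeCalls accessors
#'
#' `calls()` returns the loci-by-samples character call matrix; `panel()`
#' the underlying [SnpPanel-class]; `snpIds()` the marker ids and
#' `sampleIds()` the sample names.
#'
#' @param x a [GenotypeCalls-class].
#' @name GenotypeCalls-accessors
NULL

#' @rdname GenotypeCalls-accessors
#' @export
setMethod("calls", "GenotypeCalls",
          function(x) SummarizedExperiment::assay(x, "calls"))

#' @rdname GenotypeCalls-accessors
#' @export
setMethod("panel", "GenotypeCalls", function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  if (!is(rr, "SnpPanel")) rr <- .asSnpPanel(rr)
  rr
})

#' @rdname GenotypeCalls-accessors
#' @export
setMethod("snpIds", "GenotypeCalls", function(x) rownames(x))

#' @rdname GenotypeCalls-accessors
#' @export
sampleIds <- function(x) colnames(x)

setMethod("show", "GenotypeCalls", function(object) {
  m <- calls(object)
  cat("GenotypeCalls: ", nrow(object), " loci x ", ncol(object),
      " samples; ", round(100 * mean(m == "MISSING"), 2),
      "% missing calls\n", sep = "")
})
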