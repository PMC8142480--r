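## Per-SNP read-depth QC. A sample whose per-SNP median mapped-read
## count is below ~10 usually has a poor genotyping success rate, so the
## depth distribution is summarised per sample and thin samples flagged.

#' Per-sample distribution of per-SNP read depths
#'
#' Five-number summary plus mean of the mapped-read counts across all
#' panel loci for one sample (loci absent from the depth file already
#' count as 0; see [readDepthTable()]). Quartiles use linear
#' interpolation of the sorted values (quantile type 7), the convention
#' stated here because implementations differ.
#'
#' @param depth integer depth matrix from [readDepthTable()] (loci x
#'   samples).
#' @param sampleId sample column to summarise; unknown ids are an error.
#' @return Named numeric vector `(min, q1, median, q3, max, mean)`.
#' @export
depthDistribution <- function(depth, sampleId) {
  stopifnot(is.matrix(depth))
  if (!sampleId %in% colnames(depth))
    stop("unknown sample: ", sampleId)
  v <- depth[, sampleId]
  q <- stats::quantile(v, probs = c(0, 0.25, 0.5, 0.75, 1),
                       names = FALSE, type = 7)
  c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
    mean = mean(v))
}

#' Flag samples with low median per-SNP depth
#'
#' Samples whose median per-SNP mapped-read count falls below
#' `minMedian` (default 10 reads) are returned; such samples typically
#' genotype poorly and should be re-run or excluded.
#'
#' @param depth integer depth matrix from [readDepthTable()].
#' @param minMedian threshold on the per-sample median (default 10).
#' @return Character vector of flagged sample ids.
#' @export
flagLowDepthSamples <- function(depth, minMedian = 10) {
  stopifnot(is.matrix(depth), minMedian >= 0)
  med <- apply(depth, 2L, stats::median)
  colnames(depth)[med < minMedian]
}

#' Per-sample depth QC table
#'
#' Depth distribution summaries for every sample with a flag column,
#' ready to write as the QC report.
#'
#' @param depth integer depth matrix from [readDepthTable()].
#' @param minMedian threshold passed to [flagLowDepthSamples()].
#' @return data.frame with one row per sample: the six summary columns
#'   and `flagged`.
#' @export
depthQcTable <- function(depth, minMedian = 10) {
  stopifnot(is.matrix(depth))
  flagged <- flagLowDepthSamples(depth, minMedian)
  stats <- t(vapply(colnames(depth),
                    function(s) depthDistribution(depth, s),
                    numeric(6)))
  out <- data.frame(sample_id = colnames(depth), stats,
                    flagged = colnames(depth) %in% flagged,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}
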