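## Chromosomal distribution statistics for a marker set: SNPs per
## chromosome and inter-SNP gap (Mb) summaries, plus a plot-ready
## position table.

#' Chromosomal spacing report for a marker set
#'
#' Computes, for a set of panel loci, the number of markers per
#' chromosome and the distances between adjacent markers on the same
#' chromosome (in Mb; there are no inter-chromosome gaps). A chromosome
#' with n markers contributes `max(n - 1, 0)` gaps. Summary statistics
#' cover markers-per-chromosome (mean/min/max) and gaps genome-wide
#' (mean/min/max). Because it is ambiguous whether a per-chromosome mean
#' should average over all chromosomes in scope or only those carrying at
#' least one marker, both means are reported; min/max are over occupied
#' chromosomes.
#'
#' @param panel a [SnpPanel-class].
#' @param locusIds marker ids to include, or `NULL` for all in scope.
#' @param classes chromosome classes in scope (default autosomes + X).
#' @return List of class `spacing_report`: `perChrom` (data.frame with
#'   chrom, n_snps, mean/min/max gap in Mb), `gaps` (data.frame chrom,
#'   gap_mb), `snpsPerChrom` (mean over occupied, mean over all in-scope
#'   chromosomes, min, max), `gapStats` (mean, min, max; all `NA` when no
#'   gaps exist), `n_loci`.
#' @examples
#' p <- buildPanel(data.frame(chrom = "1",
#'                            pos = c(1e6, 4e6, 5.5e6),
#'                            id = c("a", "b", "c")))
#' spacingReport(p)$gapStats
#' @export
spacingReport <- function(panel, locusIds = NULL,
                          classes = c("AUTOSOME", "X")) {
  stopifnot(is(panel, "SnpPanel"))
  scope <- subsetPanel(panel, classes)
  if (!is.null(locusIds)) {
    unknown <- setdiff(locusIds, snpIds(panel))
    if (length(unknown))
      stop("loci not in panel: ", paste(unknown, collapse = ", "))
    scope <- .asSnpPanel(scope[snpIds(scope) %in% locusIds])
  }
  chromSet <- CHROM_LEVELS[.chromClassOf(CHROM_LEVELS) %in% classes]
  chrom <- as.character(GenomeInfoDb::seqnames(scope))
  pos <- BiocGenerics::start(scope)
  perChrom <- data.frame(chrom = chromSet, n_snps = 0L,
                         mean_gap_mb = NA_real_, min_gap_mb = NA_real_,
                         max_gap_mb = NA_real_, stringsAsFactors = FALSE)
  gaps <- data.frame(chrom = character(0), gap_mb = numeric(0))
  for (i in seq_along(chromSet)) {
    p <- pos[chrom == chromSet[i]]
    perChrom$n_snps[i] <- length(p)
    if (length(p) >= 2L) {
      g <- diff(p) / 1e6
      gaps <- rbind(gaps, data.frame(chrom = chromSet[i], gap_mb = g))
      perChrom$mean_gap_mb[i] <- mean(g)
      perChrom$min_gap_mb[i] <- min(g)
      perChrom$max_gap_mb[i] <- max(g)
    }
  }
  occupied <- perChrom$n_snps > 0L
  snpsPerChrom <- list(
    mean_occupied = if (any(occupied)) mean(perChrom$n_snps[occupied])
                    else NA_real_,
    mean_all = mean(perChrom$n_snps),
    min = if (any(occupied)) min(perChrom$n_snps[occupied]) else NA_integer_,
    max = if (any(occupied)) max(perChrom$n_snps[occupied]) else NA_integer_)
  gapStats <- if (nrow(gaps)) {
    list(mean = mean(gaps$gap_mb), min = min(gaps$gap_mb),
         max = max(gaps$gap_mb))
  } else {
    list(mean = NA_real_, min = NA_real_, max = NA_real_)
  }
  structure(list(perChrom = perChrom, gaps = gaps,
                 snpsPerChrom = snpsPerChrom, gapStats = gapStats,
                 n_loci = length(scope)),
            class = "spacing_report")
}

#' @export
print.spacing_report <- function(x, ...) {
  cat("Spacing report:", x$n_loci, "loci on",
      sum(x$perChrom$n_snps > 0), "chromosomes\n")
  cat(sprintf("  SNPs/chromosome: mean %.1f (occupied) / %.1f (all), min %s, max %s\n",
              x$snpsPerChrom$mean_occupied, x$snpsPerChrom$mean_all,
              x$snpsPerChrom$min, x$snpsPerChrom$max))
  if (is.na(x$gapStats$mean)) {
    cat("  no adjacent-SNP gaps (fewer than 2 SNPs per chromosome)\n")
  } else {
    cat(sprintf("  adjacent-SNP gap (Mb): mean %.3g, min %.3g, max %.3g\n",
                x$gapStats$mean, x$gapStats$min, x$gapStats$max))
  }
  invisible(x)
}

#' Plot-ready marker position table
#'
#' One row per locus (chrom, pos, id) in panel order -- the input format
#' for chromosome ideogram plotting tools.
#'
#' @param panel a [SnpPanel-class].
#' @param locusIds marker ids to include, or `NULL` for the whole panel.
#' @return data.frame with columns `chrom`, `pos`, `id`.
#' @export
positionsTable <- function(panel, locusIds = NULL) {
  stopifnot(is(panel, "SnpPanel"))
  sub <- panel
  if (!is.null(locusIds)) {
    unknown <- setdiff(locusIds, snpIds(panel))
    if (length(unknown))
      stop("loci not in panel: ", paste(unknown, collapse = ", "))
    sub <- panel[snpIds(panel) %in% locusIds]
  }
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(sub)),
             pos = BiocGenerics::start(sub),
             id = names(sub),
             stringsAsFactors = FALSE)
}
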