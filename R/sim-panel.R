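## Synthetic assay panel: marker coordinates emulating the genotyping
## assay (1591 autosomal + 49 X + 29 Y target SNPs, ~1.5 Mb spacing) with
## a designated subset of loci that are truly divergent between the
## donor and recipient strains (819 by default, the density of a
## BALB/c -> C57BL/6J cross, ~3 Mb between diagnostic markers).

#' Simulate an assay marker panel
#'
#' Places markers approximately evenly along each chromosome (positions
#' jittered around a regular grid; autosomal markers are apportioned by
#' physical length), assigns random ref/alt nucleotides, and marks an
#' evenly spread subset of the autosomal + X markers as `divergent`
#' between the donor and recipient strains. Divergent loci are the
#' simulator's ground-truth diagnostic set; Y markers are always treated
#' as divergent (donor and recipient Y lineages differ) but play no role
#' in ancestry summaries. Uses the session RNG; set a seed for
#' reproducibility.
#'
#' @param map genome map from [genomeMap()] (autosomes + X).
#' @param nAutosome,nX,nY marker counts per chromosome class (defaults
#'   1591, 49, 29 -- the assay's composition).
#' @param nDivergent number of autosomal + X markers divergent between
#'   the two strains (default 819).
#' @param jitterFrac jitter amplitude as a fraction of the local marker
#'   spacing (default 0.4).
#' @return A [SnpPanel-class] with metadata column `divergent`.
#' @export
simulatePanel <- function(map = genomeMap(), nAutosome = 1591L, nX = 49L,
                          nY = 29L, nDivergent = 819L, jitterFrac = 0.4) {
  stopifnot(nAutosome > 0L, nX >= 0L, nY >= 0L)
  autos <- map[.chromClassOf(map$chrom) == "AUTOSOME", ]
  # largest-remainder apportionment of autosomal markers by bp length
  share <- nAutosome * autos$length_bp / sum(autos$length_bp)
  nPer <- floor(share)
  rem <- nAutosome - sum(nPer)
  if (rem > 0) {
    extra <- order(share - nPer, decreasing = TRUE)[seq_len(rem)]
    nPer[extra] <- nPer[extra] + 1L
  }
  placeChrom <- function(chrom, len, n) {
    if (n == 0L) return(NULL)
    spacing <- len / n
    pos <- (seq_len(n) - 0.5) * spacing +
      stats::runif(n, -jitterFrac, jitterFrac) * spacing
    pos <- sort(unique(pmax(1, pmin(len, round(pos)))))
    data.frame(chrom = chrom, pos = pos,
               id = sprintf("snp_%s_%04d", chrom, seq_along(pos)),
               stringsAsFactors = FALSE)
  }
  recs <- mapply(placeChrom, autos$chrom, autos$length_bp, nPer,
                 SIMPLIFY = FALSE)
  if (nX > 0L) {
    xLen <- map$length_bp[map$chrom == "X"]
    if (!length(xLen)) stop("map lacks an X chromosome but nX > 0")
    recs <- c(recs, list(placeChrom("X", xLen, nX)))
  }
  if (nY > 0L)
    recs <- c(recs, list(placeChrom("Y", MM10_CHROM_LENGTHS[["Y"]], nY)))
  recs <- do.call(rbind, recs)
  ref <- sample(c("A", "C", "G", "T"), nrow(recs), replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  recs$ref <- ref
  recs$alt <- alt
  pan <- buildPanel(recs)
  cls <- chromClass(pan)
  axIdx <- which(cls != "Y")
  if (nDivergent > length(axIdx))
    stop("nDivergent exceeds the number of autosomal + X markers")
  pick <- axIdx[unique(round(seq(1, length(axIdx),
                                 length.out = nDivergent)))]
  divergent <- rep(FALSE, length(pan))
  divergent[pick] <- TRUE
  divergent[cls == "Y"] <- TRUE
  S4Vectors::mcols(pan)$divergent <- divergent
  pan
}

#' Ground-truth diagnostic set of a simulated panel
#'
#' Builds the [DiagnosticSet-class] containing exactly the autosomal + X
#' loci flagged `divergent` by [simulatePanel()] -- what a perfect
#' diagnostic filter would recover from error-free founder genotypes.
#'
#' @param panel a [SnpPanel-class] with a `divergent` metadata column.
#' @param donor,recipient labels for the result.
#' @return A [DiagnosticSet-class].
#' @export
truthDiagnosticSet <- function(panel, donor = "sim-donor",
                               recipient = "sim-recipient") {
  stopifnot(is(panel, "SnpPanel"))
  divergent <- S4Vectors::mcols(panel)$divergent
  if (is.null(divergent))
    stop("panel has no 'divergent' metadata column")
  ax <- chromClass(panel) != "Y"
  ids <- snpIds(panel)[ax & divergent]
  new("DiagnosticSet", donor = donor, recipient = recipient,
      locusIds = ids,
      provenance = c(n_candidates = sum(ax),
                     n_removed_missing = 0L,
                     n_removed_not_diagnostic = sum(ax) - length(ids),
                     n_diagnostic = length(ids)))
}
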