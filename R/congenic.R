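## Per-sample congenic-ancestry summaries and breeder selection.
##
## The selection statistic is the percent of recipient-strain alleles,
## 100 * (2*AA + AB) / (2 * genotyped), computed over autosomal + X loci
## (Y is excluded: it does not recombine, so its ancestry is fixed by the
## breeding design). Hemizygous male calls contribute two identical
## alleles, so one formula serves both sexes. Failed calls are excluded
## from the denominator; genotyping success is reported separately.

#' Per-sample genotype summaries and percent recipient alleles
#'
#' Counts the four call states per sample over a locus scope and derives
#' the genotyping success rate and the percent of alleles matching the
#' recipient strain, `100 * (2*n_AA + n_AB) / (2 * n_genotyped)`. The
#' default scope is every autosomal + X panel locus; pass the loci of a
#' [DiagnosticSet-class] to compute the selection statistic used for
#' breeder ranking. `pct_recipient` is `NA` (flagged in `undefined`) for
#' samples with no genotyped locus in scope.
#'
#' @param gc a [GenotypeCalls-class].
#' @param loci character vector of marker ids to count (must be panel
#'   loci), or `NULL` for all autosomal + X loci.
#' @param samples sample ids to summarise (default: all). Unknown ids
#'   are an error.
#' @return data.frame with columns `sample_id`, `n_AA`, `n_AB`, `n_BB`,
#'   `n_failed`, `n_genotyped`, `pct_genotyped`, `pct_recipient`,
#'   `undefined`; attribute `locus_scope` records the loci counted.
#' @examples
#' p <- buildPanel(data.frame(chrom = "1", pos = 1:4 * 100,
#'                            id = paste0("m", 1:4), ref = "A", alt = "G"))
#' m <- matrix(c("HOM_REF", "HET", "HOM_ALT", "MISSING"), ncol = 1,
#'             dimnames = list(paste0("m", 1:4), "s1"))
#' summarizeSamples(GenotypeCalls(m, p))
#' @export
summarizeSamples <- function(gc, loci = NULL, samples = NULL) {
  stopifnot(is(gc, "GenotypeCalls"))
  pan <- panel(gc)
  if (is.null(loci)) {
    loci <- snpIds(subsetPanel(pan, c("AUTOSOME", "X")))
  } else {
    unknown <- setdiff(loci, snpIds(pan))
    if (length(unknown))
      stop("loci not in panel: ", paste(utils::head(unknown, 5),
                                        collapse = ", "))
    loci <- snpIds(pan)[snpIds(pan) %in% loci]   # panel order
  }
  if (is.null(samples)) samples <- sampleIds(gc)
  unknown <- setdiff(samples, sampleIds(gc))
  if (length(unknown))
    stop("sample(s) not in matrix: ", paste(unknown, collapse = ", "))
  m <- calls(gc)[loci, samples, drop = FALSE]
  nAA <- colSums(m == "HOM_REF")
  nAB <- colSums(m == "HET")
  nBB <- colSums(m == "HOM_ALT")
  nFail <- colSums(m == "MISSING")
  nGeno <- nAA + nAB + nBB
  pctGeno <- 100 * nGeno / (nGeno + nFail)
  pctRec <- ifelse(nGeno > 0, 100 * (2 * nAA + nAB) / (2 * nGeno), NA_real_)
  out <- data.frame(sample_id = samples,
                    n_AA = as.integer(nAA), n_AB = as.integer(nAB),
                    n_BB = as.integer(nBB), n_failed = as.integer(nFail),
                    n_genotyped = as.integer(nGeno),
                    pct_genotyped = pctGeno, pct_recipient = pctRec,
                    undefined = nGeno == 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "locus_scope") <- loci
  out
}

#' Rank candidate breeders by percent recipient alleles
#'
#' Orders candidate samples by descending percent recipient alleles over
#' the diagnostic loci -- the statistic used to pick the next backcross
#' generation's breeders. Ties are broken by higher genotyping success,
#' then lexicographic sample id (a stable, documented order). Candidates
#' with zero genotyped diagnostic loci are placed last and flagged.
#'
#' @param gc a [GenotypeCalls-class].
#' @param diagnostic a non-empty [DiagnosticSet-class].
#' @param candidates sample ids to rank (default: all samples).
#' @return data.frame with columns `sample_id`, `pct_recipient`,
#'   `pct_genotyped`, `flagged`, best candidate first.
#' @export
rankForBreeding <- function(gc, diagnostic, candidates = NULL) {
  stopifnot(is(diagnostic, "DiagnosticSet"))
  if (length(diagnosticLoci(diagnostic)) == 0L)
    stop("diagnostic set is empty")
  s <- summarizeSamples(gc, loci = diagnosticLoci(diagnostic),
                        samples = candidates)
  ord <- order(s$undefined,
               -ifelse(s$undefined, -Inf, s$pct_recipient),
               -s$pct_genotyped, s$sample_id)
  out <- s[ord, c("sample_id", "pct_recipient", "pct_genotyped")]
  out$flagged <- s$undefined[ord]
  rownames(out) <- NULL
  out
}

#' Flag samples with poor genotyping success
#'
#' Returns the samples whose percent of successfully genotyped loci is
#' below the threshold. Well-performing runs of the assay genotype
#' 94.5-98.4% of autosomal loci, so the default of 90% isolates clear
#' failures.
#'
#' @param summaries data.frame from [summarizeSamples()].
#' @param minPctGenotyped threshold in percent (default 90).
#' @return Character vector of flagged sample ids.
#' @export
flagLowQuality <- function(summaries, minPctGenotyped = 90) {
  stopifnot(minPctGenotyped >= 0, minPctGenotyped <= 100)
  summaries$sample_id[summaries$pct_genotyped < minPctGenotyped]
}

#' Test whether samples have reached congenic status
#'
#' An individual is declared congenic when its percent recipient alleles
#' over the diagnostic markers reaches the threshold; backcrossing
#' conventionally stops at 99.8%. Undefined percentages (no genotyped
#' diagnostic loci) are an error.
#'
#' @param summaries data.frame from [summarizeSamples()] computed over a
#'   diagnostic locus scope, or a numeric vector of percentages.
#' @param threshold percent recipient alleles required (default 99.8).
#' @return Named logical vector, with attribute `report` holding one
#'   human-readable line per sample.
#' @export
isCongenic <- function(summaries, threshold = 99.8) {
  if (is.data.frame(summaries)) {
    pct <- summaries$pct_recipient
    ids <- summaries$sample_id
  } else {
    pct <- as.numeric(summaries)
    ids <- names(summaries)
  }
  if (anyNA(pct))
    stop("percent recipient alleles is undefined for some sample(s)")
  res <- pct >= threshold
  names(res) <- ids
  attr(res, "report") <- sprintf(
    "%s: %.2f%% recipient alleles -> %scongenic at %.1f%%",
    if (is.null(ids)) seq_along(pct) else ids, pct,
    ifelse(res, "", "not "), threshold)
  res
}
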