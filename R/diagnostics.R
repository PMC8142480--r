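## Diagnostic-SNP identification from replicate donor genotypes, the
## recipient-assumption check, and pairwise diagnostic-count prediction
## across a strain genotype table.

#' Identify diagnostic SNPs from donor-strain replicates
#'
#' Applies the two-step filter that defines a diagnostic marker set for a
#' donor -> recipient backcross, assuming the genotypes were called
#' against the recipient strain's reference genome (so HOM_REF is the
#' recipient allele). Starting from the autosomal + X panel loci:
#'
#' 1. drop loci that failed to genotype in more than `maxFailures` donor
#'    individuals;
#' 2. drop loci at which any donor individual is heterozygous or
#'    homozygous for the recipient (reference) allele.
#'
#' The surviving loci are homozygous for the alternate allele in every
#' genotyped donor replicate, hence informative about local ancestry in
#' backcross offspring. Filtering is run per donor source: the same
#' strain from different suppliers can differ genetically, so each source
#' gets its own set.
#'
#' @param gc a [GenotypeCalls-class] containing the donor replicates.
#' @param donorSamples sample ids of the donor individuals (2-3
#'   replicates in routine use). Absent ids are an error.
#' @param maxFailures largest tolerated number of donor individuals with
#'   a failed call at a locus (default 1, the "more than one individual"
#'   rule).
#' @param donor,recipient labels stored in the result.
#' @return A [DiagnosticSet-class]; its [provenance()] records the counts
#'   removed at each step.
#' @export
callDiagnosticSnps <- function(gc, donorSamples, maxFailures = 1L,
                               donor = "donor", recipient = "recipient") {
  stopifnot(is(gc, "GenotypeCalls"), length(donorSamples) > 0L)
  unknown <- setdiff(donorSamples, sampleIds(gc))
  if (length(unknown))
    stop("donor sample(s) not in matrix: ", paste(unknown, collapse = ", "))
  axLoci <- snpIds(subsetPanel(panel(gc), c("AUTOSOME", "X")))
  m <- calls(gc)[axLoci, donorSamples, drop = FALSE]
  nMissing <- rowSums(m == "MISSING")
  pass1 <- nMissing <= maxFailures
  bad <- rowSums(m == "HET" | m == "HOM_REF") > 0L
  keep <- pass1 & !bad
  new("DiagnosticSet",
      donor = donor, recipient = recipient,
      locusIds = axLoci[keep],
      provenance = c(n_candidates = length(axLoci),
                     n_removed_missing = sum(!pass1),
                     n_removed_not_diagnostic = sum(pass1 & bad),
                     n_diagnostic = sum(keep)))
}

#' DiagnosticSet accessors
#'
#' `diagnosticLoci()` returns the retained marker ids in panel order;
#' `provenance()` the per-filter-step removal counts; `donorLabel()` and
#' `recipientLabel()` the strain labels.
#'
#' @param x a [DiagnosticSet-class].
#' @name DiagnosticSet-accessors
NULL

#' @rdname DiagnosticSet-accessors
#' @export
setMethod("diagnosticLoci", "DiagnosticSet", function(x) x@locusIds)

#' @rdname DiagnosticSet-accessors
#' @export
setMethod("provenance", "DiagnosticSet", function(x) x@provenance)

#' @rdname DiagnosticSet-accessors
#' @export
setMethod("donorLabel", "DiagnosticSet", function(x) x@donor)

#' @rdname DiagnosticSet-accessors
#' @export
setMethod("recipientLabel", "DiagnosticSet", function(x) x@recipient)

setMethod("show", "DiagnosticSet", function(object) {
  pv <- provenance(object)
  cat("DiagnosticSet ", donorLabel(object), " -> ", recipientLabel(object),
      ": ", pv[["n_diagnostic"]], " of ", pv[["n_candidates"]],
      " autosomal+X loci (", pv[["n_removed_missing"]],
      " removed for missingness, ", pv[["n_removed_not_diagnostic"]],
      " not diagnostic)\n", sep = "")
})

#' Write a diagnostic set as BED plus provenance TSV
#'
#' @param diagnostic a [DiagnosticSet-class].
#' @param panel the [SnpPanel-class] providing coordinates.
#' @param bedPath output BED path (4 columns).
#' @param provenancePath optional TSV path for the filter provenance.
#' @return `bedPath`, invisibly.
#' @export
writeDiagnosticBed <- function(diagnostic, panel, bedPath,
                               provenancePath = NULL) {
  stopifnot(is(diagnostic, "DiagnosticSet"), is(panel, "SnpPanel"))
  sub <- panel[snpIds(panel) %in% diagnosticLoci(diagnostic)]
  chrom <- as.character(GenomeInfoDb::seqnames(sub))
  pos <- BiocGenerics::start(sub)
  writeLines(paste(chrom, pos - 1L, pos, names(sub), sep = "\t"), bedPath)
  if (!is.null(provenancePath)) {
    pv <- provenance(diagnostic)
    utils::write.table(
      data.frame(step = names(pv), count = as.integer(pv)),
      provenancePath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(bedPath)
}

#' Check the recipient-equals-reference assumption
#'
#' The diagnostic filter assumes the recipient strain is the reference
#' genome, so recipient individuals should be nearly all HOM_REF at the
#' diagnostic loci (reference-matched recipients show ~99.9% reference
#' alleles). This report computes the percent recipient alleles for each
#' recipient sample over the diagnostic loci and warns when any falls
#' below `minPct`, which would indicate the assumption is violated.
#'
#' @param gc a [GenotypeCalls-class].
#' @param recipientSamples sample ids of recipient-strain individuals.
#' @param diagnostic a non-empty [DiagnosticSet-class].
#' @param minPct warning threshold in percent (default 99.5).
#' @return data.frame with columns `sample_id`, `pct_recipient`, `ok`.
#' @export
verifyRecipient <- function(gc, recipientSamples, diagnostic,
                            minPct = 99.5) {
  stopifnot(is(diagnostic, "DiagnosticSet"))
  if (length(diagnosticLoci(diagnostic)) == 0L)
    stop("diagnostic set is empty")
  s <- summarizeSamples(gc, loci = diagnosticLoci(diagnostic),
                        samples = recipientSamples)
  out <- data.frame(sample_id = s$sample_id,
                    pct_recipient = s$pct_recipient,
                    ok = !is.na(s$pct_recipient) & s$pct_recipient >= minPct,
                    stringsAsFactors = FALSE)
  if (any(!out$ok))
    warning("recipient sample(s) below ", minPct,
            "% recipient alleles at diagnostic loci: ",
            paste(out$sample_id[!out$ok], collapse = ", "),
            " -- the recipient-equals-reference assumption may be violated")
  out
}

STRAIN_CODES <- c("A", "B", "H", "N")

#' Read a strain-by-SNP consensus genotype table
#'
#' Reads a TSV whose first column is the strain id and whose remaining
#' columns are marker ids, with consensus genotype codes `A` (reference
#' homozygote), `B` (alternate homozygote), `H` (heterozygous or
#' segregating) and `N` (missing; empty cells and `NA` are also accepted
#' as missing).
#'
#' @param path TSV file path.
#' @return Character matrix, strains in rows, markers in columns.
#' @export
readStrainTable <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  m[is.na(m) | m == ""] <- "N"
  m <- toupper(m)
  bad <- setdiff(unique(as.vector(m)), STRAIN_CODES)
  if (length(bad))
    stop("unknown genotype code(s): ", paste(bad, collapse = ", "))
  if (nrow(m) < 2L)
    stop("at least two strains are required")
  m
}

#' Predict pairwise diagnostic SNP counts across strains
#'
#' For every pair of strains, counts the markers at which both strains
#' carry opposite homozygous genotypes (one `A`, one `B`) -- the
#' predicted number of diagnostic SNPs for a backcross between them.
#' Markers that are heterozygous/segregating (`H`) or missing (`N`) in
#' either strain of a pair are excluded from that pair's count, the
#' conservative reading of "different genotypes".
#'
#' @param table character matrix of codes `A`/`B`/`H`/`N`, strains in
#'   rows (e.g. from [readStrainTable()]).
#' @return Symmetric integer matrix of predicted counts with zero
#'   diagonal.
#' @export
predictPairwiseDiagnostics <- function(table) {
  stopifnot(is.matrix(table), nrow(table) >= 2L)
  bad <- setdiff(unique(as.vector(table)), STRAIN_CODES)
  if (length(bad))
    stop("unknown genotype code(s): ", paste(bad, collapse = ", "))
  A <- table == "A"
  B <- table == "B"
  counts <- A %*% t(B) + B %*% t(A)
  storage.mode(counts) <- "integer"
  diag(counts) <- 0L
  dimnames(counts) <- list(rownames(table), rownames(table))
  counts
}

#' Summary statistics for pairwise diagnostic counts
#'
#' Mean, standard deviation and the fraction of strain pairs exceeding a
#' minimum count, over the upper triangle of a pairwise count matrix
#' (each unordered pair once, diagonal excluded). Panels are judged
#' usable for a cross when the pair clears ~300 diagnostic markers.
#'
#' @param counts symmetric matrix from [predictPairwiseDiagnostics()].
#' @param threshold count that a pair must exceed (default 300).
#' @return List with elements `mean`, `sd`, `frac_above`, `n_pairs`.
#' @export
summarizePairwise <- function(counts, threshold = 300) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts),
            nrow(counts) >= 2L)
  v <- counts[upper.tri(counts)]
  list(mean = mean(v), sd = stats::sd(v),
       frac_above = mean(v > threshold), n_pairs = length(v))
}
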