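## Central S4 data structures: the SNP panel (a GRanges subclass), the
## genotype-call container (a RangedSummarizedExperiment subclass) and the
## diagnostic marker set for one donor -> recipient cross.

#' Chromosome labels accepted by the panel model
#'
#' The marker panel targets the 19 mouse autosomes plus X and Y.
#' Mitochondrial and unplaced contigs are rejected at construction time;
#' the assay contains none.
#'
#' @format Character vector of length 21 (`"1"`..`"19"`, `"X"`, `"Y"`).
#' @export
CHROM_LEVELS <- c(as.character(1:19), "X", "Y")

#' Genotype call states
#'
#' The four call states used throughout: homozygous reference (recipient)
#' allele, heterozygous, homozygous alternate (donor) allele, and failed.
#' In sample reports these correspond to the AA / AB / BB / failed
#' vocabulary.
#'
#' @format Character vector of length 4.
#' @export
GT_STATES <- c("HOM_REF", "HET", "HOM_ALT", "MISSING")

.normChrom <- function(chrom) sub("^chr", "", as.character(chrom))

.chromClassOf <- function(chrom) {
  chrom <- .normChrom(chrom)
  ifelse(chrom == "X", "X", ifelse(chrom == "Y", "Y", "AUTOSOME"))
}

#' SnpPanel: the marker map
#'
#' An ordered collection of SNP loci, stored as a [GenomicRanges::GRanges]
#' subclass with one width-1 range per locus. Locus names are the marker
#' ids; metadata columns `ref` and `alt` hold the reference (recipient)
#' and alternate alleles as single nucleotides, and `provisional` records
#' whether alleles are still to be filled in from a VCF. Loci are kept
#' sorted by chromosome (1..19, X, Y) then position; duplicate positions
#' and ids are invalid.
#'
#' @seealso [buildPanel()], [readPanelBed()], [subsetPanel()]
#' @export
setClass("SnpPanel", contains = "GRanges")

setValidity("SnpPanel", function(object) {
  msg <- character(0)
  if (length(object) == 0L) return(TRUE)
  ids <- names(object)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msg <- c(msg, "every locus must be named by its marker id")
  else if (anyDuplicated(ids))
    msg <- c(msg, paste0("duplicate locus ids: ",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (!all(as.character(GenomeInfoDb::seqnames(object)) %in% CHROM_LEVELS))
    msg <- c(msg, "chromosomes must be within 1..19, X, Y")
  if (!all(IRanges::width(object) == 1L))
    msg <- c(msg, "all loci must have width 1 (SNPs)")
  if (any(BiocGenerics::start(object) < 1L))
    msg <- c(msg, "positions must be >= 1")
  mc <- S4Vectors::mcols(object)
  if (!all(c("ref", "alt", "provisional") %in% colnames(mc))) {
    msg <- c(msg, "metadata columns ref, alt, provisional are required")
  } else {
    ok <- is.na(mc$ref) | grepl("^[ACGT]$", mc$ref)
    ok2 <- is.na(mc$alt) | grepl("^[ACGT]$", mc$alt)
    if (!all(ok) || !all(ok2))
      msg <- c(msg, "alleles must be single nucleotides in {A,C,G,T}")
    same <- !is.na(mc$ref) & !is.na(mc$alt) & mc$ref == mc$alt
    if (any(same))
      msg <- c(msg, paste0("ref and alt alleles identical at: ",
                           paste(ids[same], collapse = ", ")))
  }
  key <- paste(GenomeInfoDb::seqnames(object), BiocGenerics::start(object))
  if (anyDuplicated(key))
    msg <- c(msg, paste0("duplicate (chrom, pos): ",
                         paste(unique(key[duplicated(key)]), collapse = "; ")))
  chromIdx <- match(as.character(GenomeInfoDb::seqnames(object)), CHROM_LEVELS)
  ord <- order(chromIdx, BiocGenerics::start(object))
  if (!identical(ord, seq_along(object)))
    msg <- c(msg, "loci must be sorted by chromosome (1..19, X, Y) then position")
  if (length(msg)) msg else TRUE
})

.asSnpPanel <- function(gr) new("SnpPanel", gr)

#' GenotypeCalls: a samples-by-loci genotype matrix on a SnpPanel
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] subclass whose rows
#' are the panel loci (row ranges are the [SnpPanel-class]) and whose
#' columns are samples. The single assay `"calls"` is a dense character
#' matrix over the four states in [GT_STATES]. Standard `[` subsetting by
#' loci and samples preserves panel order.
#'
#' @seealso [GenotypeCalls()], [readGenotypeVcf()], [summarizeSamples()]
#' @export
setClass("GenotypeCalls", contains = "RangedSummarizedExperiment")

setValidity("GenotypeCalls", function(object) {
  msg <- character(0)
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    return("assay 'calls' is required")
  m <- SummarizedExperiment::assay(object, "calls")
  if (!is.character(m))
    msg <- c(msg, "'calls' must be a character matrix")
  else if (!all(m %in% GT_STATES))
    msg <- c(msg, paste0("calls must be one of ",
                         paste(GT_STATES, collapse = ", ")))
  if (ncol(object) > 0 &&
      (is.null(colnames(object)) || anyDuplicated(colnames(object))))
    msg <- c(msg, "sample names must be present and unique")
  if (length(msg)) msg else TRUE
})

#' DiagnosticSet: diagnostic markers for a donor-to-recipient cross
#'
#' The subset of autosomal + X panel loci that are homozygous for
#' different alleles in the donor and the recipient strain, together with
#' a provenance record of how many candidate loci each filter step
#' removed. The slots are reached through [diagnosticLoci()],
#' [provenance()], `donorLabel()` and `recipientLabel()`.
#'
#' @slot donor label of the donor strain (and source, where known).
#' @slot recipient label of the recipient strain.
#' @slot locusIds marker ids retained as diagnostic, in panel order.
#' @slot provenance named integer vector with elements `n_candidates`,
#'   `n_removed_missing`, `n_removed_not_diagnostic`, `n_diagnostic`.
#' @seealso [callDiagnosticSnps()]
#' @export
setClass("DiagnosticSet",
         representation(donor = "character",
                        recipient = "character",
                        locusIds = "character",
                        provenance = "integer"))

setValidity("DiagnosticSet", function(object) {
  msg <- character(0)
  need <- c("n_candidates", "n_removed_missing",
            "n_removed_not_diagnostic", "n_diagnostic")
  pv <- object@provenance
  if (!all(need %in% names(pv))) {
    msg <- c(msg, paste0("provenance must contain: ",
                         paste(need, collapse = ", ")))
  } else {
    if (pv[["n_diagnostic"]] != length(object@locusIds))
      msg <- c(msg, "provenance n_diagnostic must equal the number of loci")
    if (pv[["n_candidates"]] != pv[["n_removed_missing"]] +
          pv[["n_removed_not_diagnostic"]] + pv[["n_diagnostic"]])
      msg <- c(msg, "provenance counts must sum to n_candidates")
  }
  if (anyDuplicated(object@locusIds))
    msg <- c(msg, "diagnostic locus ids must be unique")
  if (length(msg)) msg else TRUE
})
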