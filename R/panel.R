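#' Build a SNP panel from locus records
#'
#' Constructs a [SnpPanel-class] from per-locus records, sorting by
#' chromosome (1..19, X, Y) then position. Duplicate marker ids or
#' duplicate (chromosome, position) pairs are rejected with the offending
#' entries named, as are unknown chromosome labels and indel-like allele
#' fields (the assay is SNP-only).
#'
#' @param records data.frame with columns `chrom`, `pos`, `id` and
#'   optionally `ref`, `alt` (single nucleotides). `"chr"` prefixes on
#'   chromosome labels are accepted and stripped. Positions are 1-based.
#' @return A [SnpPanel-class].
#' @examples
#' buildPanel(data.frame(chrom = c("1", "1", "X"),
#'                       pos = c(900, 500, 100),
#'                       id = c("rsB", "rsA", "rsX"),
#'                       ref = "A", alt = "G"))
#' @export
buildPanel <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("chrom", "pos", "id")
  if (!all(need %in% names(records)))
    stop("records must have columns chrom, pos, id")
  if (nrow(records) == 0L)
    stop("records must be non-empty")
  chrom <- .normChrom(records$chrom)
  bad <- setdiff(unique(chrom), CHROM_LEVELS)
  if (length(bad))
    stop("unknown chromosome label(s): ", paste(bad, collapse = ", "))
  pos <- as.integer(records$pos)
  if (anyNA(pos) || any(pos < 1L))
    stop("positions must be integers >= 1")
  id <- as.character(records$id)
  if (anyDuplicated(id))
    stop("duplicate locus ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  key <- paste0(chrom, ":", pos)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  ref <- if ("ref" %in% names(records)) toupper(as.character(records$ref))
         else rep(NA_character_, nrow(records))
  alt <- if ("alt" %in% names(records)) toupper(as.character(records$alt))
         else rep(NA_character_, nrow(records))
  badAllele <- (!is.na(ref) & !grepl("^[ACGT]$", ref)) |
               (!is.na(alt) & !grepl("^[ACGT]$", alt))
  if (any(badAllele))
    stop("non-SNP allele field(s) at: ",
         paste(id[badAllele], collapse = ", "),
         " (alleles must be single nucleotides)")
  ord <- order(match(chrom, CHROM_LEVELS), pos)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom[ord], levels = CHROM_LEVELS),
    ranges = IRanges::IRanges(start = pos[ord], width = 1L),
    seqinfo = GenomeInfoDb::Seqinfo(seqnames = CHROM_LEVELS))
  names(gr) <- id[ord]
  S4Vectors::mcols(gr)$ref <- ref[ord]
  S4Vectors::mcols(gr)$alt <- alt[ord]
  S4Vectors::mcols(gr)$provisional <- is.na(ref[ord]) | is.na(alt[ord])
  new("SnpPanel", gr)
}

#' Loci per chromosome class
#'
#' Number of loci in each chromosome class, as a named integer vector
#' `c(AUTOSOME=, X=, Y=)`. The full assay panel gives (1591, 49, 29).
#'
#' @param x a [SnpPanel-class].
#' @return Named integer vector of length 3.
#' @rdname countsByClass
#' @export
setMethod("countsByClass", "SnpPanel", function(x) {
  cls <- chromClass(x)
  c(AUTOSOME = sum(cls == "AUTOSOME"),
    X = sum(cls == "X"),
    Y = sum(cls == "Y"))
})

#' Marker ids of a panel
#' @param x a [SnpPanel-class] or [GenotypeCalls-class].
#' @return Character vector of marker ids in panel order.
#' @rdname snpIds
#' @export
setMethod("snpIds", "SnpPanel", function(x) names(x))

#' Chromosome class of each locus
#' @param x a [SnpPanel-class].
#' @return Character vector over `"AUTOSOME"`, `"X"`, `"Y"`.
#' @rdname chromClass
#' @export
setMethod("chromClass", "SnpPanel", function(x) {
  .chromClassOf(as.character(GenomeInfoDb::seqnames(x)))
})

#' Panel allele accessors
#'
#' `refAllele()` and `altAllele()` return the per-locus alleles (NA where
#' still provisional); `isProvisional()` flags loci whose alleles have not
#' yet been filled in from genotype data.
#'
#' @param x a [SnpPanel-class].
#' @return Character (alleles) or logical vector, one element per locus.
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
setMethod("refAllele", "SnpPanel", function(x) S4Vectors::mcols(x)$ref)

#' @rdname panel-accessors
#' @export
setMethod("altAllele", "SnpPanel", function(x) S4Vectors::mcols(x)$alt)

#' @rdname panel-accessors
#' @export
setMethod("isProvisional", "SnpPanel",
          function(x) S4Vectors::mcols(x)$provisional)

#' Subset a panel by chromosome class
#'
#' Returns the loci whose chromosome class is in `classes`, preserving
#' panel order. The usual analysis scope is `c("AUTOSOME", "X")`: Y
#' markers are excluded from percent-recipient summaries because the Y
#' does not recombine and its ancestry is fixed by the breeding design.
#'
#' @param panel a [SnpPanel-class].
#' @param classes non-empty subset of `c("AUTOSOME", "X", "Y")`.
#' @return A [SnpPanel-class] (possibly empty).
#' @export
subsetPanel <- function(panel, classes) {
  stopifnot(is(panel, "SnpPanel"))
  classes <- match.arg(classes, c("AUTOSOME", "X", "Y"), several.ok = TRUE)
  .asSnpPanel(panel[chromClass(panel) %in% classes])
}

#' Export a panel back to plain records
#'
#' Inverse of [buildPanel()]: returns the data.frame representation
#' (chrom, pos, id, ref, alt) so that `buildPanel(asPanelData(p))`
#' reproduces `p` exactly.
#'
#' @param panel a [SnpPanel-class].
#' @return data.frame with one row per locus, in panel order.
#' @export
asPanelData <- function(panel) {
  stopifnot(is(panel, "SnpPanel"))
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(panel)),
             pos = BiocGenerics::start(panel),
             id = names(panel),
             ref = refAllele(panel),
             alt = altAllele(panel),
             stringsAsFactors = FALSE)
}

setMethod("show", "SnpPanel", function(object) {
  cbc <- countsByClass(object)
  cat("SnpPanel with ", length(object), " loci (",
      cbc[["AUTOSOME"]], " autosomal, ", cbc[["X"]], " X, ",
      cbc[["Y"]], " Y); ", sum(isProvisional(object)),
      " with provisional alleles\n", sep = "")
  if (length(object)) methods::callNextMethod()
})
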