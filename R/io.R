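## Readers and writers for the plain-text formats at the workflow
## boundary: BED panel files (Table S1 dialect), multi-sample VCF,
## per-SNP depth tables and the per-sample summary TSV.
##
## The panel BED is deliberately parsed as a plain tab table rather than
## through a track-oriented BED importer: the extended dialect carries
## ref/alt alleles in columns 5-6 where standard BED expects score and
## strand, and malformed records must be reported with line numbers.

#' Read a SNP panel from a BED file
#'
#' Reads a 4+ column BED file (chrom, start, end, name) of SNP target
#' positions, 0-based half-open with `end == start + 1` for every record,
#' and returns a [SnpPanel-class] with 1-based positions
#' (`pos = start + 1`). If columns 5 and 6 hold single nucleotides they
#' are taken as ref and alt alleles (an extended dialect); otherwise
#' alleles are left provisional, to be filled from VCF REF/ALT by
#' [readGenotypeVcf()]. Records whose span is not exactly one base, and
#' unparseable lines, raise errors naming the line.
#'
#' @param path BED file path. `"chr"`-prefixed and bare chromosome names
#'   are both accepted.
#' @return A [SnpPanel-class].
#' @export
readPanelBed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no BED records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop("malformed BED line ", lineNo[which(nf < 4L)[1]],
         ": fewer than 4 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  id <- vapply(fields, `[[`, "", 4L)
  if (anyNA(start) || anyNA(end))
    stop("unparseable coordinates at line ",
         lineNo[which(is.na(start) | is.na(end))[1]])
  badSpan <- end != start + 1L
  if (any(badSpan))
    stop("malformed SNP record at line ", lineNo[which(badSpan)[1]],
         ": end must equal start + 1")
  ref <- rep(NA_character_, length(lines))
  alt <- rep(NA_character_, length(lines))
  hasAlleles <- nf >= 6L
  if (any(hasAlleles)) {
    c5 <- toupper(vapply(fields[hasAlleles], `[[`, "", 5L))
    c6 <- toupper(vapply(fields[hasAlleles], `[[`, "", 6L))
    use <- grepl("^[ACGT]$", c5) & grepl("^[ACGT]$", c6)
    ref[hasAlleles][use] <- c5[use]
    alt[hasAlleles][use] <- c6[use]
  }
  buildPanel(data.frame(chrom = chrom, pos = start + 1L, id = id,
                        ref = ref, alt = alt, stringsAsFactors = FALSE))
}

#' Write a SNP panel as a BED file
#'
#' Writes the panel in the 4-column BED dialect (chrom, start, end, name;
#' 0-based half-open), appending ref/alt allele columns 5-6 when the
#' panel carries concrete alleles so that [readPanelBed()] inverts the
#' file exactly.
#'
#' @param panel a [SnpPanel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePanelBed <- function(panel, path) {
  stopifnot(is(panel, "SnpPanel"))
  chrom <- as.character(GenomeInfoDb::seqnames(panel))
  pos <- BiocGenerics::start(panel)
  base <- paste(chrom, pos - 1L, pos, names(panel), sep = "\t")
  withAlleles <- !isProvisional(panel)
  base[withAlleles] <- paste(base[withAlleles],
                             refAllele(panel)[withAlleles],
                             altAllele(panel)[withAlleles], sep = "\t")
  writeLines(base, path)
  invisible(path)
}

.GT_FROM_CODE <- c("0/0" = "HOM_REF", "0/1" = "HET", "1/0" = "HET",
                   "1/1" = "HOM_ALT", "0" = "HOM_REF", "1" = "HOM_ALT",
                   "./." = "MISSING", "." = "MISSING")

#' Read genotype calls from a multi-sample VCF
#'
#' Parses the GT field of a joint-genotyped multi-sample VCF at the panel
#' loci. Diploid codes map 0/0 to HOM_REF, 0/1 and 1/0 to HET, 1/1 to
#' HOM_ALT and ./. to MISSING; phased separators are accepted and
#' ignored; haploid calls on X/Y (hemizygous males under a haploid model)
#' map 0 to HOM_REF and 1 to HOM_ALT. VCF records outside the panel are
#' skipped (the panel BED is the source of truth for locus membership);
#' panel loci absent from the VCF are MISSING for all samples.
#' Multiallelic or non-SNP records at panel loci are demoted to MISSING
#' for all samples and reported in a warning tally rather than rejected.
#' Provisional panel alleles are filled in from the VCF REF/ALT columns.
#'
#' @param path VCF (v4.x) file path, plain text.
#' @param panel the [SnpPanel-class] defining locus membership.
#' @return A [GenotypeCalls-class] with one column per VCF sample.
#' @export
readGenotypeVcf <- function(path, panel) {
  stopifnot(is(panel, "SnpPanel"))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(vcf@gt) || ncol(vcf@gt) < 2L)
    stop("VCF has no sample columns: ", path)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- .normChrom(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  panelKey <- paste0(as.character(GenomeInfoDb::seqnames(panel)), ":",
                     BiocGenerics::start(panel))
  recKey <- paste0(chrom, ":", pos)
  hit <- match(recKey, panelKey)          # NA for off-panel records
  samples <- colnames(vcf@gt)[-1L]
  m <- matrix("MISSING", nrow = length(panel), ncol = length(samples),
              dimnames = list(snpIds(panel), samples))
  inPanel <- which(!is.na(hit))
  multi <- 0L
  if (length(inPanel)) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(vcf@gt),
                                       dimnames = list(NULL, samples))
    isSnp <- grepl("^[ACGT]$", ref) & grepl("^[ACGT]$", alt)
    for (i in inPanel) {
      row <- hit[i]
      if (!isSnp[i]) { multi <- multi + 1L; next }   # stays MISSING
      g <- gsub("|", "/", gt[i, ], fixed = TRUE)
      call <- .GT_FROM_CODE[g]
      call[is.na(call)] <- "MISSING"
      m[row, ] <- call
    }
    # fill provisional alleles from the VCF record
    prov <- isProvisional(panel)
    fillable <- inPanel[isSnp[inPanel] & prov[hit[inPanel]]]
    if (length(fillable)) {
      S4Vectors::mcols(panel)$ref[hit[fillable]] <- ref[fillable]
      S4Vectors::mcols(panel)$alt[hit[fillable]] <- alt[fillable]
      S4Vectors::mcols(panel)$provisional[hit[fillable]] <- FALSE
      validObject(panel)
    }
  }
  if (multi > 0L)
    warning(multi, " multiallelic/non-SNP record(s) at panel loci were set ",
            "to MISSING")
  GenotypeCalls(m, panel)
}

.GT_TO_CODE <- c(HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1",
                 MISSING = "./.")

#' Write genotype calls as a minimal VCF
#'
#' Emits a minimal VCF v4.2 (CHROM, POS, ID, REF, ALT, GT only) that
#' [readGenotypeVcf()] inverts exactly. Heterozygous calls are written in
#' the canonical unphased form `0/1`, missing calls as `./.`. All panel
#' loci must carry concrete (non-provisional) alleles.
#'
#' @param gc a [GenotypeCalls-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypeVcf <- function(gc, path) {
  stopifnot(is(gc, "GenotypeCalls"))
  pan <- panel(gc)
  if (any(isProvisional(pan)))
    stop("panel has provisional alleles; fill them before writing VCF")
  m <- calls(gc)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=speedcongenics",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", colnames(m)), collapse = "\t"))
  gtBody <- matrix(.GT_TO_CODE[m], nrow = nrow(m))
  rows <- paste(as.character(GenomeInfoDb::seqnames(pan)),
                BiocGenerics::start(pan), names(pan),
                refAllele(pan), altAllele(pan), ".", ".", ".", "GT",
                apply(gtBody, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a per-SNP mapped-read depth table
#'
#' Accepts either a long table with columns `sample`, `locus`, `count`
#' or a wide table whose first column is the locus id and whose remaining
#' columns are samples. Counts must be non-negative; locus ids must
#' belong to the panel (unknown ids are an error listing them). Panel
#' loci absent from the file are assigned depth 0 -- absence of mapped
#' reads is the signal the QC looks for.
#'
#' @param path TSV file path.
#' @param panel a [SnpPanel-class].
#' @return Integer matrix, panel loci in rows (all of them, panel order),
#'   samples in columns.
#' @export
readDepthTable <- function(path, panel) {
  stopifnot(is(panel, "SnpPanel"))
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  lowered <- tolower(names(tab))
  long <- ncol(tab) == 3L && all(c("sample", "locus", "count") %in% lowered)
  if (long) {
    names(tab) <- lowered
    loci <- as.character(tab$locus)
    samplesVec <- as.character(tab$sample)
    counts <- tab$count
    unknown <- setdiff(unique(loci), snpIds(panel))
    if (length(unknown))
      stop("depth table has locus ids not in the panel: ",
           paste(unknown, collapse = ", "))
    if (any(is.na(counts)) || any(counts < 0))
      stop("depth counts must be non-negative")
    samples <- sort(unique(samplesVec))
    m <- matrix(0L, nrow = length(panel), ncol = length(samples),
                dimnames = list(snpIds(panel), samples))
    m[cbind(match(loci, snpIds(panel)), match(samplesVec, samples))] <-
      as.integer(counts)
  } else {
    loci <- as.character(tab[[1L]])
    unknown <- setdiff(unique(loci), snpIds(panel))
    if (length(unknown))
      stop("depth table has locus ids not in the panel: ",
           paste(unknown, collapse = ", "))
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    if (any(is.na(vals)) || any(vals < 0))
      stop("depth counts must be non-negative")
    m <- matrix(0L, nrow = length(panel), ncol = ncol(vals),
                dimnames = list(snpIds(panel), colnames(vals)))
    m[match(loci, snpIds(panel)), ] <- as.integer(vals)
  }
  m
}

#' Write per-sample genotype summaries as a TSV report
#'
#' Serialises the output of [summarizeSamples()] with the column
#' vocabulary of the sample-report format: LibraryID, BB, AB, AA, failed,
#' TotalGenotyped, ProportionAA (fraction of genotyped SNPs homozygous
#' reference) and ProportionA (fraction of reference alleles among
#' genotyped SNPs). Proportions are written with 4 decimal places.
#'
#' @param summaries data.frame from [summarizeSamples()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSummaryTable <- function(summaries, path) {
  stopifnot(is.data.frame(summaries), nrow(summaries) > 0L)
  out <- data.frame(
    LibraryID = summaries$sample_id,
    BB = summaries$n_BB,
    AB = summaries$n_AB,
    AA = summaries$n_AA,
    failed = summaries$n_failed,
    TotalGenotyped = summaries$n_genotyped,
    ProportionAA = sprintf("%.4f", summaries$n_AA / summaries$n_genotyped),
    ProportionA = sprintf("%.4f", summaries$pct_recipient / 100),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
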