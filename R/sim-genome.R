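## Backcross simulator: diploid mouse genomes as ancestry-labelled
## chromosome segments, gamete formation under a no-interference
## (Poisson / Haldane) crossover model, and genotyping with missingness.
##
## A haplotype is a list(ends, anc): `ends` are strictly increasing
## segment right endpoints in bp (the last equals the chromosome length)
## and `anc` the matching ancestry labels (0 = donor, 1 = recipient),
## with adjacent equal labels merged. Individuals are lightweight lists;
## the S4 layer is reserved for the analysis-side containers that users
## exchange with files.

.ANC_DONOR <- 0L
.ANC_RECIPIENT <- 1L

#' mm10 chromosome lengths
#'
#' Physical lengths (bp) of the mouse chromosomes in the UCSC mm10
#' (GRCm38) assembly, used as the simulator's default genome.
#'
#' @format Named numeric vector (`"1"`..`"19"`, `"X"`, `"Y"`).
#' @export
MM10_CHROM_LENGTHS <- c(
  `1` = 195471971, `2` = 182113224, `3` = 160039680, `4` = 156508116,
  `5` = 151834684, `6` = 149736546, `7` = 145441459, `8` = 129401213,
  `9` = 124595110, `10` = 130694993, `11` = 122082543, `12` = 120129022,
  `13` = 120421639, `14` = 124902244, `15` = 104043685, `16` = 98207768,
  `17` = 94987271, `18` = 90702639, `19` = 61431566,
  X = 171031299, Y = 91744698)

#' Genome map for the simulator
#'
#' Physical and genetic lengths of the chromosomes over which
#' recombination is simulated (autosomes and X; the Y does not recombine
#' and is carried as a paternal label only). Defaults to the mm10
#' physical lengths with a single genome-wide rate of 0.56 cM/Mb, giving
#' an autosomal map of roughly 1380 cM -- adequate for trajectory-level
#' validation. Genetic positions are interpolated linearly within each
#' chromosome.
#'
#' @param cMPerMb genome-wide recombination rate (default 0.56).
#' @param chroms chromosomes to include (default 1..19 and X).
#' @param lengths named vector of physical lengths in bp (default mm10).
#' @return data.frame with columns `chrom`, `length_bp`, `cm`.
#' @export
genomeMap <- function(cMPerMb = 0.56,
                      chroms = c(as.character(1:19), "X"),
                      lengths = MM10_CHROM_LENGTHS) {
  chroms <- .normChrom(chroms)
  stopifnot(all(chroms %in% names(lengths)), cMPerMb > 0)
  data.frame(chrom = chroms,
             length_bp = as.numeric(lengths[chroms]),
             cm = as.numeric(lengths[chroms]) / 1e6 * cMPerMb,
             stringsAsFactors = FALSE)
}

.mapRow <- function(map, chrom) {
  i <- match(chrom, map$chrom)
  if (is.na(i)) stop("chromosome not in map: ", chrom)
  i
}

#' Construct and validate a haplotype
#'
#' @param ends strictly increasing segment right endpoints (bp); the last
#'   must equal `length_bp`.
#' @param anc ancestry labels per segment, 0 = donor, 1 = recipient.
#' @param lengthBp chromosome length in bp.
#' @return list(ends, anc) with adjacent equal labels merged.
#' @export
haplotype <- function(ends, anc, lengthBp) {
  stopifnot(length(ends) == length(anc), length(ends) >= 1L)
  if (any(diff(ends) <= 0)) stop("segment ends must be strictly increasing")
  if (ends[length(ends)] != lengthBp)
    stop("segments must tile the chromosome exactly")
  if (ends[1] <= 0) stop("first segment must have positive length")
  if (!all(anc %in% c(.ANC_DONOR, .ANC_RECIPIENT)))
    stop("ancestry labels must be 0 (donor) or 1 (recipient)")
  .mergeHap(ends, as.integer(anc))
}

.mergeHap <- function(ends, anc) {
  n <- length(anc)
  if (n > 1L) {
    keep <- c(anc[-1L] != anc[-n], TRUE)
    if (!all(keep)) { ends <- ends[keep]; anc <- anc[keep] }
  }
  list(ends = ends, anc = anc)
}

.pureHap <- function(lengthBp, label) list(ends = lengthBp, anc = label)

# ancestry label at physical position(s); segment i covers (ends[i-1], ends[i]]
.ancAt <- function(hap, pos) {
  hap$anc[findInterval(pos, hap$ends, left.open = TRUE) + 1L]
}

# recipient-labelled length of a haplotype
.recLength <- function(hap) {
  sum(diff(c(0, hap$ends))[hap$anc == .ANC_RECIPIENT])
}

# gamete from one chromosome pair under the Haldane model; crossover
# positions are uniform in genetic coordinates, which the default linear
# map makes uniform in physical coordinates too
.gamete <- function(hapA, hapB, lengthBp, cM) {
  # homozygous-ancestry fast path: both haplotypes one identical segment
  if (length(hapA$anc) == 1L && length(hapB$anc) == 1L &&
      hapA$anc == hapB$anc)
    return(hapA)
  nxo <- stats::rpois(1L, cM / 100)
  startA <- stats::runif(1L) < 0.5
  if (nxo == 0L) return(if (startA) hapA else hapB)
  xo <- sort(stats::runif(nxo, min = 0, max = lengthBp))
  xo <- xo[xo > 0 & xo < lengthBp]
  if (!length(xo)) return(if (startA) hapA else hapB)
  .recombine(hapA, hapB, xo, startA)
}

.recombine <- function(hapA, hapB, xo, startA) {
  lengthBp <- hapA$ends[length(hapA$ends)]
  bounds <- c(xo, lengthBp)
  ends <- numeric(0)
  anc <- integer(0)
  prev <- 0
  useA <- startA
  for (b in bounds) {
    h <- if (useA) hapA else hapB
    i1 <- findInterval(prev, h$ends) + 1L     # first segment ending > prev
    i2 <- i1 + sum(h$ends[i1:length(h$ends)] < b)  # first segment ending >= b
    idx <- i1:i2
    ends <- c(ends, pmin(h$ends[idx], b))
    anc <- c(anc, h$anc[idx])
    prev <- b
    useA <- !useA
  }
  .mergeHap(ends, anc)
}

#' Create an ancestry-pure founder individual
#'
#' @param role `"DONOR"` or `"RECIPIENT"`.
#' @param sex `"M"` or `"F"`.
#' @param map genome map from [genomeMap()].
#' @param id individual id.
#' @return An individual: a list with elements `id`, `sex`, `generation`,
#'   `haps` (per-chromosome list of haplotypes; autosomes and female X
#'   carry two, male X one), and `yLabel` (males only).
#' @export
makeFounder <- function(role = c("DONOR", "RECIPIENT"), sex = c("M", "F"),
                        map = genomeMap(), id = NULL) {
  role <- match.arg(role)
  sex <- match.arg(sex)
  label <- if (role == "DONOR") .ANC_DONOR else .ANC_RECIPIENT
  haps <- list()
  for (i in seq_len(nrow(map))) {
    chrom <- map$chrom[i]
    n <- if (chrom == "X" && sex == "M") 1L else 2L
    haps[[chrom]] <- rep(list(.pureHap(map$length_bp[i], label)), n)
  }
  list(id = if (is.null(id)) paste0(role, "_", sex) else id,
       sex = sex, generation = "F0", haps = haps,
       yLabel = if (sex == "M") label else NA_integer_)
}

#' Simulate one meiosis for one chromosome
#'
#' Draws a gamete haplotype from a parent: the crossover count is
#' Poisson(genetic length / 100 Morgans), crossover positions are
#' uniform on the genetic map, and the gamete alternates between the two
#' parental haplotypes starting from a fair-coin choice (Haldane's
#' no-interference model). The male X is transmitted intact (no
#' recombination outside the pseudoautosomal region, which is not
#' modelled).
#'
#' @param parent an individual (see [makeFounder()]).
#' @param chrom chromosome label.
#' @param map genome map from [genomeMap()].
#' @return A haplotype (list of `ends`, `anc`).
#' @export
meiosis <- function(parent, chrom, map = genomeMap()) {
  chrom <- .normChrom(chrom)
  i <- .mapRow(map, chrom)
  haps <- parent$haps[[chrom]]
  if (is.null(haps)) stop("parent has no chromosome ", chrom)
  if (chrom == "X" && parent$sex == "M") return(haps[[1L]])
  .gamete(haps[[1L]], haps[[2L]], map$length_bp[i], map$cm[i])
}

#' Cross a dam and a sire
#'
#' Produces offspring: each receives one gamete per parent per autosome,
#' an X gamete from the dam, and from the sire either his intact X
#' (daughters) or his Y label (sons). Sex is a fair coin unless forced.
#' When `geneLocus` is given, each offspring's `carrier` flag records
#' whether it inherited donor ancestry at that position (transmission is
#' ~1/2 from a hemizygous/heterozygous carrier parent).
#'
#' @param dam female individual.
#' @param sire male individual.
#' @param nOffspring number of offspring.
#' @param map genome map from [genomeMap()].
#' @param geneLocus optional `list(chrom=, pos=)` of the gene of
#'   interest.
#' @param generation generation label for the offspring.
#' @param forceSex `"M"`, `"F"`, or `NULL` for random sex.
#' @param idPrefix prefix for offspring ids.
#' @return List of individuals.
#' @export
cross <- function(dam, sire, nOffspring = 1L, map = genomeMap(),
                  geneLocus = NULL, generation = NA_character_,
                  forceSex = NULL, idPrefix = "off") {
  if (dam$sex != "F" || sire$sex != "M")
    stop("cross requires a female dam and a male sire")
  lapply(seq_len(nOffspring), function(k) {
    sex <- if (is.null(forceSex)) sample(c("M", "F"), 1L) else forceSex
    haps <- list()
    for (i in seq_len(nrow(map))) {
      chrom <- map$chrom[i]
      if (chrom == "X") {
        matX <- meiosis(dam, "X", map)
        haps[["X"]] <- if (sex == "F") list(matX, sire$haps[["X"]][[1L]])
                       else list(matX)
      } else {
        haps[[chrom]] <- list(meiosis(dam, chrom, map),
                              meiosis(sire, chrom, map))
      }
    }
    ind <- list(id = paste0(idPrefix, "_", k), sex = sex,
                generation = generation, haps = haps,
                yLabel = if (sex == "M") sire$yLabel else NA_integer_)
    if (!is.null(geneLocus)) ind$carrier <- isCarrier(ind, geneLocus)
    ind
  })
}

#' Does an individual carry the gene of interest?
#'
#' True when any haplotype of the gene's chromosome has donor ancestry at
#' the gene position (the transgene travels on donor background).
#'
#' @param ind an individual.
#' @param geneLocus `list(chrom=, pos=)`.
#' @return Logical.
#' @export
isCarrier <- function(ind, geneLocus) {
  haps <- ind$haps[[.normChrom(geneLocus$chrom)]]
  if (is.null(haps)) stop("gene locus chromosome not in genome")
  any(vapply(haps, function(h) .ancAt(h, geneLocus$pos) == .ANC_DONOR,
             logical(1)))
}

#' True recipient-ancestry fraction of an individual
#'
#' Length-weighted fraction of recipient-labelled genome over all
#' haplotype copies of the chromosomes in scope (physical distance; Y
#' always excluded). This is the simulator's ground truth against which
#' marker-based percent-recipient estimates are validated. Note the X
#' enters with one copy in males and two in females; the textbook
#' backcross expectation 1 - 2^-g applies to the autosomal scope.
#'
#' @param ind an individual.
#' @param map genome map from [genomeMap()].
#' @param classes chromosome classes to include (default autosomes + X).
#' @return Fraction in `[0, 1]`.
#' @export
recipientFraction <- function(ind, map = genomeMap(),
                              classes = c("AUTOSOME", "X")) {
  chroms <- map$chrom[.chromClassOf(map$chrom) %in% classes]
  tot <- 0
  rec <- 0
  for (chrom in chroms) {
    for (h in ind$haps[[chrom]]) {
      tot <- tot + h$ends[length(h$ends)]
      rec <- rec + .recLength(h)
    }
  }
  rec / tot
}

#' Genotype a simulated individual on a panel
#'
#' Converts local ancestry at each panel locus into a genotype call. At
#' truly divergent loci (metadata column `divergent`, default all) the
#' ancestry pair maps recipient/recipient to HOM_REF, donor/recipient to
#' HET and donor/donor to HOM_ALT; at non-divergent loci both strains
#' share the reference allele, so the call is HOM_REF regardless of
#' ancestry. Hemizygous male X calls come from the single X; Y loci are
#' called from the paternal Y label in males and are MISSING in females.
#' Each call then fails with probability `missingRate`, and is replaced
#' by a different state uniformly at random with probability `errorRate`.
#'
#' @param ind an individual.
#' @param panel a [SnpPanel-class] whose coordinates lie within the map.
#' @param map genome map from [genomeMap()] (Y length taken from
#'   `MM10_CHROM_LENGTHS` if absent).
#' @param missingRate per-call failure probability (default 0.025, the
#'   assay's typical 97.5% genotyping success).
#' @param errorRate per-call wrong-genotype probability (default 0).
#' @return Named character vector of calls over the panel loci.
#' @export
genotypeIndividual <- function(ind, panel, map = genomeMap(),
                               missingRate = 0.025, errorRate = 0) {
  stopifnot(is(panel, "SnpPanel"), missingRate >= 0, missingRate <= 1,
            errorRate >= 0, errorRate <= 1)
  chrom <- as.character(GenomeInfoDb::seqnames(panel))
  pos <- BiocGenerics::start(panel)
  divergent <- S4Vectors::mcols(panel)$divergent
  if (is.null(divergent)) divergent <- rep(TRUE, length(panel))
  out <- character(length(panel))
  names(out) <- snpIds(panel)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    p <- pos[sel]
    if (ch == "Y") {
      if (ind$sex == "M") {
        donorY <- !is.na(ind$yLabel) && ind$yLabel == .ANC_DONOR
        call <- if (donorY) "HOM_ALT" else "HOM_REF"
        out[sel] <- ifelse(divergent[sel], call, "HOM_REF")
      } else {
        out[sel] <- "MISSING"
      }
      next
    }
    haps <- ind$haps[[ch]]
    if (is.null(haps))
      stop("panel chromosome ", ch, " not in simulated genome")
    len <- if (ch %in% map$chrom) map$length_bp[.mapRow(map, ch)]
           else MM10_CHROM_LENGTHS[[ch]]
    if (any(p > len)) stop("locus outside chromosome ", ch, " length")
    nRec <- Reduce(`+`, lapply(haps, .ancAt, pos = p))
    if (length(haps) == 1L) nRec <- 2L * nRec   # hemizygous = two identical
    call <- c("HOM_ALT", "HET", "HOM_REF")[nRec + 1L]
    out[sel] <- ifelse(divergent[sel], call, "HOM_REF")
  }
  if (errorRate > 0) {
    err <- stats::runif(length(out)) < errorRate & out != "MISSING"
    if (any(err)) {
      out[err] <- vapply(out[err], function(g)
        sample(setdiff(c("HOM_REF", "HET", "HOM_ALT"), g), 1L), "")
    }
  }
  if (missingRate > 0) {
    fail <- stats::runif(length(out)) < missingRate
    out[fail] <- "MISSING"
  }
  out
}
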