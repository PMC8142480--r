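## In-silico replica of the marker-assisted backcross experiment: one
## donor male crossed to recipient females, three F1 sires, then five
## backcross generations in which all carrier offspring are genotyped
## and the top-ranked carriers breed the next generation.

#' Define a breeding scheme
#'
#' Parameters of the simulated speed-congenics program. The defaults
#' reproduce the reference experiment: 1 donor male x 2 recipient
#' females, 3 F1 males each bred to 2 recipient females, carrier
#' offspring counts of 13, 8, 14, 28 and 6 at backcross generations 2-6
#' (first backcross offspring are "generation 2"), and 3, 3, 2, 2
#' top-ranked carriers selected as breeders after generations 2-5.
#' All genotyped carriers of both sexes are eligible as breeders; a
#' selected male is mated to pure recipient females and a selected
#' female to a pure recipient male, as in routine speed-congenics
#' practice. Carrier counts are fixed scheme parameters rather than
#' litter-size draws, which keeps an unmodelled nuisance out of
#' trajectory comparisons; non-carrier littermates are generated and
#' discarded.
#'
#' @param geneLocus `list(chrom=, pos=)` of the gene of interest. The
#'   default places it at the midpoint of chromosome 11; set it for any
#'   study-specific use, since linkage drag around this position is what
#'   limits the attainable percent recipient.
#' @param nF1Sires number of F1 males bred (default 3; F1 individuals
#'   are genetically exchangeable so no selection applies).
#' @param carriersPerGeneration named integer vector, carriers genotyped
#'   at each backcross generation.
#' @param breedersSelected named integer vector, breeders selected from
#'   each generation except the last.
#' @param missingRate,errorRate per-call genotyping failure and error
#'   probabilities (defaults 0.025 and 0).
#' @param selection `"top"` for marker-assisted selection, `"random"`
#'   for unselected breeding (same structure, random carriers).
#' @return List of class `breeding_scheme`.
#' @export
breedingScheme <- function(geneLocus = list(chrom = "11",
                                            pos = 61041272L),
                           nF1Sires = 3L,
                           carriersPerGeneration = c(`2` = 13L, `3` = 8L,
                                                     `4` = 14L, `5` = 28L,
                                                     `6` = 6L),
                           breedersSelected = c(`2` = 3L, `3` = 3L,
                                                `4` = 2L, `5` = 2L),
                           missingRate = 0.025, errorRate = 0,
                           selection = c("top", "random")) {
  stopifnot(all(carriersPerGeneration >= 1L),
            missingRate >= 0, missingRate <= 1,
            errorRate >= 0, errorRate <= 1)
  gens <- names(carriersPerGeneration)
  if (is.null(gens)) {
    gens <- as.character(seq_along(carriersPerGeneration) + 1L)
    names(carriersPerGeneration) <- gens
  }
  if (is.null(names(breedersSelected)))
    names(breedersSelected) <- utils::head(gens, length(breedersSelected))
  need <- utils::head(gens, -1L)
  if (!all(need %in% names(breedersSelected)))
    stop("breedersSelected must cover every generation except the last")
  structure(list(geneLocus = geneLocus, nF1Sires = as.integer(nF1Sires),
                 carriersPerGeneration = carriersPerGeneration,
                 breedersSelected = breedersSelected,
                 missingRate = missingRate, errorRate = errorRate,
                 selection = match.arg(selection)),
            class = "breeding_scheme")
}

# produce carrier offspring round-robin across the selected breeders
# until `target` carriers are collected; every breeder is mated to a
# pure recipient partner of the opposite sex
.collectCarriers <- function(breeders, target, map, geneLocus, generation,
                             maxAttempts = 200L * target + 400L) {
  dam <- makeFounder("RECIPIENT", "F", map, id = "recipient_dam")
  sire <- makeFounder("RECIPIENT", "M", map, id = "recipient_sire")
  carriers <- vector("list", target)
  found <- 0L
  attempts <- 0L
  while (found < target) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop("could not obtain ", target, " carrier offspring at generation ",
           generation, " (no carriers available?)")
    b <- breeders[[(attempts - 1L) %% length(breeders) + 1L]]
    off <- if (b$sex == "M") {
      cross(dam, b, 1L, map, geneLocus = geneLocus,
            generation = generation)[[1L]]
    } else {
      cross(b, sire, 1L, map, geneLocus = geneLocus,
            generation = generation)[[1L]]
    }
    if (isTRUE(off$carrier)) {
      found <- found + 1L
      off$id <- sprintf("G%s_%02d", generation, found)
      carriers[[found]] <- off
    }
  }
  carriers
}

#' Simulate a marker-assisted backcross program
#'
#' Runs the full speed-congenics loop: donor male x recipient females,
#' `nF1Sires` F1 males, then for each backcross generation the scheme's
#' number of carrier offspring are produced (dams are always fresh pure
#' recipient females), genotyped on the panel, and ranked by percent
#' recipient alleles over the diagnostic markers; the top-ranked
#' carriers (either sex) become the next breeders, each mated to a pure
#' recipient partner. Per generation it returns the
#' [GenotypeCalls-class], a truth table pairing each carrier's
#' marker-based estimate with its true ancestry fraction, and the
#' selected breeders. Fully reproducible given `seed`.
#'
#' @param scheme a [breedingScheme()].
#' @param panel a [SnpPanel-class], typically from [simulatePanel()].
#' @param diagnostic a [DiagnosticSet-class]; default, the panel's
#'   ground-truth divergent set via [truthDiagnosticSet()].
#' @param map genome map from [genomeMap()].
#' @param seed optional integer seed.
#' @return List of class `congenic_sim` with elements `generations` (one
#'   entry per backcross generation: `calls`, `truth`, `selected`),
#'   `scheme`, `diagnostic`. Each `truth` data.frame has columns
#'   `sample_id`, `sex`, `true_recipient_pct` (autosome + X scope),
#'   `marker_pct`, `pct_genotyped`.
#' @export
simulateBreedingProgram <- function(scheme = breedingScheme(),
                                    panel, diagnostic = NULL,
                                    map = genomeMap(), seed = NULL) {
  stopifnot(inherits(scheme, "breeding_scheme"), is(panel, "SnpPanel"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(diagnostic)) diagnostic <- truthDiagnosticSet(panel)
  geneLocus <- scheme$geneLocus
  donor <- makeFounder("DONOR", "M", map, id = "donor_F0")
  recipDam <- makeFounder("RECIPIENT", "F", map, id = "recipient_dam")
  # F1 sires: all F1 carry the gene (donor founder is homozygous), so
  # take the first males produced
  sires <- list()
  guard <- 0L
  while (length(sires) < scheme$nF1Sires) {
    guard <- guard + 1L
    if (guard > 1000L) stop("failed to obtain F1 males")
    off <- cross(recipDam, donor, 1L, map, geneLocus = geneLocus,
                 generation = "F1")[[1L]]
    if (off$sex == "M") {
      off$id <- sprintf("F1_%02d", length(sires) + 1L)
      sires <- c(sires, list(off))
    }
  }
  gens <- names(scheme$carriersPerGeneration)
  out <- vector("list", length(gens))
  names(out) <- gens
  for (gi in seq_along(gens)) {
    g <- gens[gi]
    carriers <- .collectCarriers(sires, scheme$carriersPerGeneration[[g]],
                                 map, geneLocus, g)
    callMat <- vapply(carriers, genotypeIndividual, character(length(panel)),
                      panel = panel, map = map,
                      missingRate = scheme$missingRate,
                      errorRate = scheme$errorRate)
    rownames(callMat) <- snpIds(panel)
    colnames(callMat) <- vapply(carriers, `[[`, "", "id")
    gc <- GenotypeCalls(callMat, panel)
    ranking <- rankForBreeding(gc, diagnostic)
    truth <- data.frame(
      sample_id = colnames(callMat),
      sex = vapply(carriers, `[[`, "", "sex"),
      true_recipient_pct = 100 * vapply(carriers, recipientFraction,
                                        numeric(1), map = map),
      stringsAsFactors = FALSE)
    truth$marker_pct <-
      ranking$pct_recipient[match(truth$sample_id, ranking$sample_id)]
    truth$pct_genotyped <-
      ranking$pct_genotyped[match(truth$sample_id, ranking$sample_id)]
    selected <- character(0)
    if (gi < length(gens)) {
      k <- scheme$breedersSelected[[g]]
      ids <- truth$sample_id
      if (!length(ids))
        stop("no carriers available at generation ", g)
      selected <- if (scheme$selection == "top") {
        utils::head(ranking$sample_id, k)
      } else {
        sample(ids, min(k, length(ids)))
      }
      byId <- stats::setNames(carriers, truth$sample_id)
      sires <- byId[selected]
    }
    out[[g]] <- list(calls = gc, truth = truth, selected = selected)
  }
  structure(list(generations = out, scheme = scheme,
                 diagnostic = diagnostic),
            class = "congenic_sim")
}

#' @export
print.congenic_sim <- function(x, ...) {
  cat("Simulated marker-assisted backcross program\n")
  for (g in names(x$generations)) {
    tr <- x$generations[[g]]$truth
    cat(sprintf(
      "  generation %s: n=%d carriers, mean %.1f%% (range %.1f-%.1f%%) recipient alleles\n",
      g, nrow(tr), mean(tr$marker_pct), min(tr$marker_pct),
      max(tr$marker_pct)))
  }
  invisible(x)
}

#' Generation means of a simulated program
#'
#' Convenience extraction of the per-generation mean, min and max of the
#' marker-based percent recipient alleles from a [simulateBreedingProgram()]
#' result.
#'
#' @param sim a `congenic_sim` object.
#' @return data.frame with columns `generation`, `n`, `mean_pct`,
#'   `min_pct`, `max_pct`.
#' @export
trajectorySummary <- function(sim) {
  stopifnot(inherits(sim, "congenic_sim"))
  do.call(rbind, lapply(names(sim$generations), function(g) {
    tr <- sim$generations[[g]]$truth
    data.frame(generation = g, n = nrow(tr),
               mean_pct = mean(tr$marker_pct),
               min_pct = min(tr$marker_pct),
               max_pct = max(tr$marker_pct),
               stringsAsFactors = FALSE)
  }))
}

#' Unselected backcross trajectory
#'
#' Simulates independent male-line backcross lineages with no marker
#' selection and no carrier conditioning: each lineage starts from an F1
#' male and at every generation a random male offspring (of a pure
#' recipient dam) continues the line. Records the true autosomal
#' recipient-ancestry fraction of the offspring at each generation,
#' whose expectation follows the closed form 1 - 2^-g (g = 2 for the
#' first backcross offspring).
#'
#' @param nLineages number of independent lineages.
#' @param lastGeneration final backcross generation (default 6).
#' @param map genome map from [genomeMap()].
#' @param seed optional integer seed.
#' @param classes chromosome scope for the recorded fraction (default
#'   `"AUTOSOME"`, where the closed form holds; in male-line
#'   backcrossing the X is structurally recipient from generation 2 on).
#' @return Numeric matrix, lineages in rows, one column per generation
#'   (named `"2"`..).
#' @export
simulateUnselectedTrajectory <- function(nLineages = 2000L,
                                         lastGeneration = 6L,
                                         map = genomeMap(), seed = NULL,
                                         classes = "AUTOSOME") {
  if (!is.null(seed)) set.seed(seed)
  gens <- as.character(2:lastGeneration)
  res <- matrix(NA_real_, nrow = nLineages, ncol = length(gens),
                dimnames = list(NULL, gens))
  donor <- makeFounder("DONOR", "M", map)
  dam <- makeFounder("RECIPIENT", "F", map)
  for (l in seq_len(nLineages)) {
    sire <- cross(dam, donor, 1L, map, generation = "F1",
                  forceSex = "M")[[1L]]
    for (g in gens) {
      off <- cross(dam, sire, 1L, map, generation = g,
                   forceSex = "M")[[1L]]
      res[l, g] <- recipientFraction(off, map, classes = classes)
      sire <- off
    }
  }
  res
}
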