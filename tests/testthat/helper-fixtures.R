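# Shared fixture builders and independent oracles. Fixtures are built in
# code; nothing is read from disk except files the tests write themselves.

makeTestPanel <- function(n = 10, chrom = "1", spacing = 100L,
                          ref = "A", alt = "G") {
  buildPanel(data.frame(chrom = chrom, pos = seq_len(n) * spacing,
                        id = paste0("m", seq_len(n)),
                        ref = ref, alt = alt))
}

# random multi-chromosome panel with concrete alleles
randomPanel <- function(nLoci = 30, chroms = c("1", "2", "X")) {
  chrom <- sample(chroms, nLoci, replace = TRUE)
  pos <- integer(nLoci)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    pos[sel] <- sample.int(1e6, sum(sel))
  }
  ref <- sample(c("A", "C", "G", "T"), nLoci, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  buildPanel(data.frame(chrom = chrom, pos = pos,
                        id = sprintf("r%03d", seq_len(nLoci)),
                        ref = ref, alt = alt))
}

randomCallMatrix <- function(panel, nSamples = 3,
                             probs = c(0.45, 0.1, 0.35, 0.1)) {
  n <- length(panel)
  matrix(sample(GT_STATES, n * nSamples, replace = TRUE, prob = probs),
         nrow = n,
         dimnames = list(snpIds(panel), paste0("s", seq_len(nSamples))))
}

# independent brute-force evaluation of the two-step diagnostic predicate
oracleDiagnosticLoci <- function(callMat, donorSamples, maxFailures) {
  kept <- character(0)
  for (locus in rownames(callMat)) {
    gts <- callMat[locus, donorSamples]
    failures <- 0L
    disqualified <- FALSE
    for (g in gts) {
      if (g == "MISSING") failures <- failures + 1L
      if (g == "HET" || g == "HOM_REF") disqualified <- TRUE
    }
    if (failures <= maxFailures && !disqualified)
      kept <- c(kept, locus)
  }
  kept
}

# sort-based type-7 quantile, written independently of stats::quantile
oracleQuantile7 <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# a tiny two-chromosome genome for fast simulator tests
toyMap <- function() genomeMap(cMPerMb = 0.5,
                               chroms = c("1", "11"),
                               lengths = c(`1` = 1.6e8, `11` = 1.2e8))
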