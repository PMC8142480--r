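test_that("the two-step diagnostic filter applies the stated predicates", {
  p <- makeTestPanel(4)
  m <- matrix("HOM_ALT", 4, 3, dimnames = list(snpIds(p),
                                               c("d1", "d2", "d3")))
  m["m1", ] <- c("HOM_ALT", "HOM_ALT", "MISSING")  # 1 failure: retained
  m["m2", ] <- c("HOM_ALT", "HET", "HOM_ALT")      # HET donor: removed
  m["m3", ] <- c("MISSING", "MISSING", "HOM_ALT")  # 2 failures: removed
  ds <- callDiagnosticSnps(GenotypeCalls(m, p), c("d1", "d2", "d3"))
  expect_identical(diagnosticLoci(ds), c("m1", "m4"))
  pv <- provenance(ds)
  expect_identical(pv[["n_removed_missing"]], 1L)
  expect_identical(pv[["n_removed_not_diagnostic"]], 1L)
  expect_identical(pv[["n_candidates"]], 4L)
})

test_that("all-HOM_ALT donors keep the whole autosome+X panel; all-HOM_REF keep none", {
  p <- buildPanel(data.frame(chrom = c("1", "X", "Y"), pos = c(1, 1, 1),
                             id = c("a", "x", "y"), ref = "A", alt = "G"))
  full <- GenotypeCalls(matrix("HOM_ALT", 3, 2,
                               dimnames = list(snpIds(p), c("d1", "d2"))), p)
  ds <- callDiagnosticSnps(full, c("d1", "d2"))
  expect_identical(diagnosticLoci(ds), c("a", "x"))  # Y never a candidate
  none <- GenotypeCalls(matrix("HOM_REF", 3, 2,
                               dimnames = list(snpIds(p), c("d1", "d2"))), p)
  expect_length(diagnosticLoci(callDiagnosticSnps(none, c("d1", "d2"))), 0)
})

test_that("diagnostic filter matches the brute-force oracle on random matrices", {
  set.seed(51)
  for (i in 1:60) {
    pan <- randomPanel(sample(5:50, 1), chroms = c("1", "2", "X"))
    nd <- sample(1:5, 1)
    m <- randomCallMatrix(pan, nd, probs = c(0.2, 0.15, 0.45, 0.2))
    donors <- colnames(m)
    maxF <- sample(0:2, 1)
    ds <- callDiagnosticSnps(GenotypeCalls(m, pan), donors,
                             maxFailures = maxF)
    expect_identical(diagnosticLoci(ds),
                     oracleDiagnosticLoci(m, donors, maxF))
  }
})

test_that("tightening max failures or adding donors never enlarges the set", {
  set.seed(52)
  for (i in 1:20) {
    pan <- randomPanel(30)
    m <- randomCallMatrix(pan, 4, probs = c(0.15, 0.1, 0.55, 0.2))
    gc <- GenotypeCalls(m, pan)
    d1 <- diagnosticLoci(callDiagnosticSnps(gc, colnames(m)[1:3],
                                            maxFailures = 1))
    d0 <- diagnosticLoci(callDiagnosticSnps(gc, colnames(m)[1:3],
                                            maxFailures = 0))
    expect_true(all(d0 %in% d1))
    dMore <- diagnosticLoci(callDiagnosticSnps(gc, colnames(m),
                                               maxFailures = 1))
    # a fourth replicate can only disqualify loci via HET/HOM_REF, but a
    # fourth MISSING can also push a locus over the failure budget
    expect_true(all(dMore %in% d1))
  }
})

test_that("simulator founders yield the true divergent set minus missingness casualties", {
  set.seed(53)
  pan <- simulatePanel(nAutosome = 300, nX = 10, nY = 5, nDivergent = 150)
  map <- genomeMap()
  donors <- lapply(1:3, function(i) makeFounder("DONOR", "M", map,
                                                id = paste0("d", i)))
  m <- vapply(donors, genotypeIndividual, character(length(pan)),
              panel = pan, map = map, missingRate = 0.025)
  dimnames(m) <- list(snpIds(pan), c("d1", "d2", "d3"))
  ds <- callDiagnosticSnps(GenotypeCalls(m, pan), c("d1", "d2", "d3"))
  truthIds <- diagnosticLoci(truthDiagnosticSet(pan))
  overBudget <- rownames(m)[rowSums(m == "MISSING") > 1]
  expect_identical(diagnosticLoci(ds), setdiff(truthIds, overBudget))
})

test_that("recipient verification reports and warns below threshold", {
  p <- makeTestPanel(10)
  ids <- snpIds(p)
  ds <- new("DiagnosticSet", donor = "D", recipient = "R",
            locusIds = ids,
            provenance = c(n_candidates = 10L, n_removed_missing = 0L,
                           n_removed_not_diagnostic = 0L,
                           n_diagnostic = 10L))
  good <- GenotypeCalls(matrix("HOM_REF", 10, 1,
                               dimnames = list(ids, "r1")), p)
  rep1 <- verifyRecipient(good, "r1", ds)
  expect_true(rep1$ok)
  expect_equal(rep1$pct_recipient, 100)
  bad <- GenotypeCalls(matrix(rep(c("HOM_REF", "HOM_ALT"), c(9, 1)), 10, 1,
                              dimnames = list(ids, "r1")), p)
  expect_warning(rep2 <- verifyRecipient(bad, "r1", ds), "assumption")
  expect_false(rep2$ok)
  empty <- new("DiagnosticSet", donor = "D", recipient = "R",
               locusIds = character(0),
               provenance = c(n_candidates = 10L, n_removed_missing = 0L,
                              n_removed_not_diagnostic = 10L,
                              n_diagnostic = 0L))
  expect_error(verifyRecipient(good, "r1", empty), "empty")
})

test_that("pairwise prediction counts opposite homozygotes only", {
  tbl <- rbind(s1 = c("A", "A", "B", "B", "A"),
               s2 = c("A", "B", "B", "A", "N"))
  cnt <- predictPairwiseDiagnostics(tbl)
  expect_identical(cnt["s1", "s2"], 2L)   # loci 2 and 4
  expect_identical(diag(cnt), c(s1 = 0L, s2 = 0L))
  tblH <- rbind(s1 = c("A", "H"), s2 = c("B", "B"))
  expect_identical(predictPairwiseDiagnostics(tblH)["s1", "s2"], 1L)
  expect_error(predictPairwiseDiagnostics(rbind(s1 = "Z", s2 = "A")),
               "unknown genotype code")
})

test_that("pairwise prediction is symmetric and matches brute force on random tables", {
  set.seed(61)
  for (i in 1:25) {
    ns <- sample(2:6, 1)
    nl <- sample(5:60, 1)
    tbl <- matrix(sample(c("A", "B", "H", "N"), ns * nl, replace = TRUE),
                  ns, nl, dimnames = list(paste0("s", 1:ns), NULL))
    cnt <- predictPairwiseDiagnostics(tbl)
    expect_identical(cnt, t(cnt))
    for (a in 1:(ns - 1)) for (b in (a + 1):ns) {
      brute <- sum(vapply(seq_len(nl), function(j) {
        g1 <- tbl[a, j]; g2 <- tbl[b, j]
        g1 %in% c("A", "B") && g2 %in% c("A", "B") && g1 != g2
      }, logical(1)))
      expect_identical(cnt[a, b], as.integer(brute))
    }
  }
})

test_that("pairwise summaries cover the upper triangle", {
  cnt <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  cnt[upper.tri(cnt)] <- c(10L, 20L, 30L)
  cnt <- cnt + t(cnt)
  s <- summarizePairwise(cnt)
  expect_equal(s$mean, 20)
  expect_equal(s$n_pairs, 3)
  expect_equal(s$frac_above, 0)
  expect_equal(summarizePairwise(cnt, threshold = 0)$frac_above, 1)
  flat <- matrix(5L, 3, 3); diag(flat) <- 0L
  expect_equal(summarizePairwise(flat)$sd, 0)
})

test_that("diagnostic sets serialise to BED with provenance", {
  set.seed(62)
  pan <- randomPanel(20)
  m <- randomCallMatrix(pan, 3, probs = c(0.2, 0.1, 0.6, 0.1))
  ds <- callDiagnosticSnps(GenotypeCalls(m, pan), colnames(m))
  bed <- withr::local_tempfile(fileext = ".bed")
  prov <- withr::local_tempfile(fileext = ".tsv")
  writeDiagnosticBed(ds, pan, bed, prov)
  back <- readPanelBed(bed)
  expect_identical(snpIds(back), diagnosticLoci(ds))
  pv <- read.delim(prov)
  expect_identical(pv$count[pv$step == "n_diagnostic"],
                   length(diagnosticLoci(ds)))
})
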