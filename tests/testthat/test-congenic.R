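test_that("percent recipient alleles follows the allele-counting formula", {
  p <- makeTestPanel(10)
  gc <- GenotypeCalls(matrix("HOM_REF", 10, 1,
                             dimnames = list(snpIds(p), "s1")), p)
  s <- summarizeSamples(gc)
  expect_equal(s$pct_recipient, 100)
  expect_equal(s$pct_genotyped, 100)

  gc <- GenotypeCalls(matrix("HET", 10, 1,
                             dimnames = list(snpIds(p), "s1")), p)
  expect_equal(summarizeSamples(gc)$pct_recipient, 50)  # F1 expectation

  # 800 AA, 10 AB, 190 BB, 640 failed: pct = (2*800+10)/(2*1000) * 100
  p2 <- makeTestPanel(1640)
  callsVec <- rep(c("HOM_REF", "HET", "HOM_ALT", "MISSING"),
                  c(800, 10, 190, 640))
  gc2 <- GenotypeCalls(matrix(callsVec, 1640, 1,
                              dimnames = list(snpIds(p2), "s1")), p2)
  s2 <- summarizeSamples(gc2)
  expect_equal(s2$pct_recipient, 80.5)
  expect_equal(s2$pct_genotyped, 100 * 1000 / 1640)
  expect_equal(s2$n_genotyped, 1000L)
})

test_that("allele counts conserve and the percent is order-invariant", {
  set.seed(41)
  for (i in 1:10) {
    pan <- randomPanel(25)
    gc <- GenotypeCalls(randomCallMatrix(pan, 4), pan)
    s <- summarizeSamples(gc)
    expect_equal((2 * s$n_AA + s$n_AB) + (s$n_AB + 2 * s$n_BB),
                 2 * s$n_genotyped)
    # shuffle sample order; per-sample values unchanged
    perm <- sample(sampleIds(gc))
    s2 <- summarizeSamples(gc, samples = perm)
    expect_equal(s2$pct_recipient[match(s$sample_id, s2$sample_id)],
                 s$pct_recipient)
    # shuffle the locus subset given to the function
    ax <- sample(attr(s, "locus_scope"))
    s3 <- summarizeSamples(gc, loci = ax)
    expect_equal(s3$pct_recipient, s$pct_recipient)
  }
})

test_that("Y loci are excluded from the default summary scope", {
  p <- buildPanel(data.frame(chrom = c("1", "Y"), pos = c(10, 10),
                             id = c("a", "y"), ref = "A", alt = "G"))
  m <- matrix(c("HOM_REF", "HOM_ALT"), 2, 1,
              dimnames = list(c("a", "y"), "s1"))
  s <- summarizeSamples(GenotypeCalls(m, p))
  expect_identical(s$n_genotyped, 1L)      # Y HOM_ALT not counted
  expect_equal(s$pct_recipient, 100)
})

test_that("undefined percentages are flagged, not silently computed", {
  p <- makeTestPanel(3)
  gc <- GenotypeCalls(matrix("MISSING", 3, 1,
                             dimnames = list(snpIds(p), "s1")), p)
  s <- summarizeSamples(gc)
  expect_true(s$undefined)
  expect_true(is.na(s$pct_recipient))
  expect_error(isCongenic(s), "undefined")
})

test_that("breeder ranking sorts by percent, breaks ties by success then id", {
  p <- makeTestPanel(40)
  ids <- snpIds(p)
  col <- function(nAA, nAB, nBB, nMiss) {
    rep(c("HOM_REF", "HET", "HOM_ALT", "MISSING"), c(nAA, nAB, nBB, nMiss))
  }
  m <- cbind(a = col(30, 0, 0, 10),   # 100%, 75% genotyped
             b = col(40, 0, 0, 0),    # 100%, 100% genotyped
             c = col(20, 10, 10, 0),  # 62.5%
             d = col(0, 0, 0, 40))    # undefined
  rownames(m) <- ids
  ds <- new("DiagnosticSet", donor = "D", recipient = "R",
            locusIds = ids,
            provenance = c(n_candidates = 40L, n_removed_missing = 0L,
                           n_removed_not_diagnostic = 0L,
                           n_diagnostic = 40L))
  r <- rankForBreeding(GenotypeCalls(m, p), ds)
  expect_identical(r$sample_id, c("b", "a", "c", "d"))
  expect_identical(r$flagged, c(FALSE, FALSE, FALSE, TRUE))
  r1 <- rankForBreeding(GenotypeCalls(m, p), ds, candidates = "c")
  expect_identical(nrow(r1), 1L)
})

test_that("low-quality flagging respects the threshold boundaries", {
  s <- data.frame(sample_id = c("good", "ok", "bad"),
                  pct_genotyped = c(98.4, 94.5, 50))
  expect_identical(flagLowQuality(s), "bad")
  expect_identical(flagLowQuality(s, 0), character(0))
  expect_identical(flagLowQuality(s, 95), c("ok", "bad"))
})

test_that("congenic status uses the 99.8% convention inclusively", {
  expect_true(unname(isCongenic(99.8)))
  expect_false(unname(isCongenic(99.4)))
  expect_true(all(isCongenic(c(10, 50, 99.9), threshold = 0)))
  res <- isCongenic(c(s1 = 99.9, s2 = 90))
  expect_identical(as.logical(res), c(TRUE, FALSE))
  expect_length(attr(res, "report"), 2)
})
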