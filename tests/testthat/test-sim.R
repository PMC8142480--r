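# structural check used throughout: segments tile the chromosome with
# strictly increasing ends and no adjacent same-label segments
expectValidHap <- function(hap, lengthBp) {
  expect_true(all(diff(c(0, hap$ends)) > 0))
  expect_equal(hap$ends[length(hap$ends)], lengthBp)
  expect_length(hap$anc, length(hap$ends))
  if (length(hap$anc) > 1)
    expect_true(all(hap$anc[-1] != hap$anc[-length(hap$anc)]))
}

test_that("haplotype constructor enforces tiling and merges equal neighbours", {
  h <- haplotype(c(50, 100), c(1, 1), 100)
  expect_identical(h$ends, 100)        # merged into one segment
  expect_length(h$anc, 1)
  expect_error(haplotype(c(60, 50), c(0, 1), 100), "strictly increasing")
  expect_error(haplotype(c(50, 90), c(0, 1), 100), "tile")
  expect_error(haplotype(100, 2, 100), "labels")
})

test_that("founders are ancestry-pure and the donor founder carries the gene", {
  map <- toyMap()
  locus <- list(chrom = "11", pos = 6e7)
  don <- makeFounder("DONOR", "M", map)
  rec <- makeFounder("RECIPIENT", "F", map)
  expect_equal(recipientFraction(don, map), 0)
  expect_equal(recipientFraction(rec, map), 1)
  expect_true(isCarrier(don, locus))
  expect_false(isCarrier(rec, locus))
})

test_that("meiosis preserves segment tiling and homozygous ancestry", {
  set.seed(91)
  map <- toyMap()
  rec <- makeFounder("RECIPIENT", "F", map)
  for (i in 1:5) {
    g <- meiosis(rec, "1", map)
    expect_identical(g$anc, 1L)   # both haplotypes recipient -> pure gamete
  }
  f1 <- cross(rec, makeFounder("DONOR", "M", map), 1L, map)[[1]]
  for (i in 1:50) {
    g <- meiosis(f1, "1", map)
    expectValidHap(g, map$length_bp[map$chrom == "1"])
  }
})

test_that("crossover count over many meioses matches the Poisson map length", {
  set.seed(92)
  map <- genomeMap(cMPerMb = 1, chroms = "1", lengths = c(`1` = 1e8))
  expect_equal(map$cm, 100)
  parent <- list(id = "p", sex = "F", haps = list(
    `1` = list(list(ends = 1e8, anc = 0L), list(ends = 1e8, anc = 1L))))
  # with one pure-donor and one pure-recipient haplotype every crossover
  # produces a label switch, so switches count crossovers exactly
  n <- 10000
  switches <- vapply(seq_len(n), function(i)
    length(meiosis(parent, "1", map)$anc) - 1L, integer(1))
  expect_lt(abs(mean(switches) - 1.0), 0.03)   # 3 SE at n = 10000
})

test_that("F1 offspring pair one pure donor with one pure recipient haplotype", {
  set.seed(93)
  map <- toyMap()
  off <- cross(makeFounder("RECIPIENT", "F", map),
               makeFounder("DONOR", "M", map), 6L, map,
               geneLocus = list(chrom = "11", pos = 6e7))
  for (o in off) {
    expect_equal(recipientFraction(o, map, classes = "AUTOSOME"), 0.5)
    expect_true(o$carrier)
    for (ch in c("1", "11"))
      expect_setequal(vapply(o$haps[[ch]], function(h) h$anc[1], 0L),
                      c(0L, 1L))
  }
  offRR <- cross(makeFounder("RECIPIENT", "F", map),
                 makeFounder("RECIPIENT", "M", map), 3L, map)
  expect_true(all(vapply(offRR, recipientFraction, 0, map = map) == 1))
  expect_error(cross(makeFounder("RECIPIENT", "M", map),
                     makeFounder("DONOR", "M", map), 1L, map),
               "female dam")
})

test_that("X transmission follows sex: sons take the dam's X, daughters the sire's intact X", {
  set.seed(94)
  map <- genomeMap(chroms = c("1", "X"),
                   lengths = c(`1` = 1e8, X = 8e7))
  dam <- makeFounder("RECIPIENT", "F", map)
  sire <- makeFounder("DONOR", "M", map)
  sons <- cross(dam, sire, 8L, map, forceSex = "M")
  for (s in sons) {
    expect_length(s$haps[["X"]], 1)
    expect_identical(s$haps[["X"]][[1]]$anc, 1L)   # from recipient dam
    expect_identical(s$yLabel, 0L)                 # donor Y label
  }
  daughters <- cross(dam, sire, 8L, map, forceSex = "F")
  for (d in daughters) {
    expect_length(d$haps[["X"]], 2)
    expect_setequal(vapply(d$haps[["X"]], function(h) h$anc[1], 0L),
                    c(0L, 1L))
  }
})

test_that("carrier transmission from a heterozygous parent is one half", {
  set.seed(95)
  map <- toyMap()
  locus <- list(chrom = "11", pos = 6e7)
  dam <- makeFounder("RECIPIENT", "F", map)
  f1 <- cross(dam, makeFounder("DONOR", "M", map), 1L, map,
              geneLocus = locus, forceSex = "M")[[1]]
  off <- cross(dam, f1, 10000L, map, geneLocus = locus)
  frac <- mean(vapply(off, `[[`, TRUE, "carrier"))
  expect_lt(abs(frac - 0.5), 0.015)   # 3 SE at n = 10000
})

test_that("true recipient fraction is length-weighted segment arithmetic", {
  map <- toyMap()   # chr1 160 Mb, chr11 120 Mb
  ind <- makeFounder("RECIPIENT", "F", map)
  ind$haps[["1"]][[1]] <- haplotype(c(8e7, 1.6e8), c(0, 1), 1.6e8)
  # 80 Mb donor out of 2 * (160 + 120) Mb
  expect_equal(recipientFraction(ind, map), 1 - 8e7 / 5.6e8)
})

test_that("genotyping converts ancestry to calls with divergence awareness", {
  set.seed(96)
  map <- genomeMap()
  pan <- simulatePanel(nAutosome = 120, nX = 6, nY = 4, nDivergent = 60)
  divergent <- S4Vectors::mcols(pan)$divergent
  cls <- chromClass(pan)
  rec <- makeFounder("RECIPIENT", "F", map)
  gRec <- genotypeIndividual(rec, pan, map, missingRate = 0)
  expect_true(all(gRec[cls != "Y"] == "HOM_REF"))
  expect_true(all(gRec[cls == "Y"] == "MISSING"))   # female has no Y
  don <- makeFounder("DONOR", "M", map)
  gDon <- genotypeIndividual(don, pan, map, missingRate = 0)
  expect_true(all(gDon[divergent & cls != "Y"] == "HOM_ALT"))
  expect_true(all(gDon[!divergent] == "HOM_REF"))  # shared alleles
  expect_true(all(gDon[divergent & cls == "Y"] == "HOM_ALT"))
  f1 <- cross(rec, don, 1L, map, forceSex = "F")[[1]]
  gF1 <- genotypeIndividual(f1, pan, map, missingRate = 0)
  expect_true(all(gF1[divergent & cls != "Y"] == "HET"))
})

test_that("genotyping failure rate matches the missingness parameter", {
  set.seed(97)
  map <- toyMap()
  pan <- simulatePanel(map, nAutosome = 819, nX = 0, nY = 0,
                       nDivergent = 819)
  f1 <- cross(makeFounder("RECIPIENT", "F", map),
              makeFounder("DONOR", "M", map), 1L, map)[[1]]
  g <- replicate(30, genotypeIndividual(f1, pan, map, missingRate = 0.025))
  obs <- mean(g != "MISSING")
  se <- sqrt(0.025 * 0.975 / length(g))
  expect_lt(abs(obs - 0.975), 3 * se)
})

test_that("a fixed seed makes the breeding program fully reproducible", {
  map <- toyMap()
  set.seed(98)
  pan <- simulatePanel(map, nAutosome = 80, nX = 0, nY = 0,
                       nDivergent = 50)
  scheme <- breedingScheme(geneLocus = list(chrom = "11", pos = 6e7),
                           carriersPerGeneration = c(`2` = 5L, `3` = 4L),
                           breedersSelected = c(`2` = 2L))
  s1 <- simulateBreedingProgram(scheme, pan, map = map, seed = 123)
  s2 <- simulateBreedingProgram(scheme, pan, map = map, seed = 123)
  expect_identical(lapply(s1$generations, `[[`, "truth"),
                   lapply(s2$generations, `[[`, "truth"))
  expect_identical(calls(s1$generations[["3"]]$calls),
                   calls(s2$generations[["3"]]$calls))
})

test_that("marker-assisted selection beats random breeder choice by generation 6", {
  set.seed(99)
  pan <- simulatePanel()
  reps <- 50
  g6 <- function(selection, seed) {
    sim <- simulateBreedingProgram(breedingScheme(selection = selection),
                                   pan, seed = seed)
    mean(sim$generations[["6"]]$truth$marker_pct)
  }
  sel <- vapply(seq_len(reps), function(r) g6("top", 5000 + r), 0)
  rnd <- vapply(seq_len(reps), function(r) g6("random", 6000 + r), 0)
  expect_gt(mean(sel), mean(rnd))
  # the gap should be decisive, not a coin flip
  expect_gt(mean(sel) - mean(rnd),
            3 * sqrt(var(sel) / reps + var(rnd) / reps))
})
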