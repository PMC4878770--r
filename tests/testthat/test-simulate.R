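test_that("founder site counts follow the configured density", {
  lay <- GenomeLayout(data.frame(chrom = "c1", length = 10e6, isZ = FALSE,
                                 parStart = NA, parEnd = NA),
                      snpDensity = 1e-4)
  fh <- simulateFounders(lay, seed = 1)
  n <- nrow(founderSites(fh)$c1)
  # Poisson(1000): within 4 SD
  expect_gt(n, 1000 - 4 * sqrt(1000))
  expect_lt(n, 1000 + 4 * sqrt(1000))
  st <- founderSites(fh)$c1
  expect_true(all(st$ref %in% c("A", "C", "G", "T")))
  expect_true(all(st$ref != st$alt))
  # both weak:strong and weak:weak / strong:strong site types occur
  ws <- (st$ref %in% c("A", "T")) != (st$alt %in% c("A", "T"))
  expect_gt(sum(ws), 0)
  expect_gt(sum(!ws), 0)
  expect_false(is.unsorted(st$pos))
})

test_that("zero density or zero-length chromosomes are rejected", {
  expect_error(simulateFounders(
    GenomeLayout(data.frame(chrom = "c1", length = 10e6, isZ = FALSE,
                            parStart = NA, parEnd = NA), snpDensity = 0)),
    "[Dd]ensity")
  expect_error(GenomeLayout(data.frame(chrom = "c1", length = -5,
                                       isZ = FALSE, parStart = NA,
                                       parEnd = NA)))
})

test_that("identical seeds give identical founders and truth tables", {
  lay <- defaultGenomeLayout()
  f1 <- simulateFounders(lay, seed = 42)
  f2 <- simulateFounders(lay, seed = 42)
  expect_identical(founderSites(f1), founderSites(f2))
  expect_identical(founderHaplotypes(f1), founderHaplotypes(f2))
  s1 <- simulatePedigree(lay, seed = 9)
  s2 <- simulatePedigree(lay, seed = 9)
  expect_identical(coBreakpoints(s1$truth), coBreakpoints(s2$truth))
  d1 <- file.path(tempdir(), "truthA"); d2 <- file.path(tempdir(), "truthB")
  writeTruthTables(s1$truth, d1); writeTruthTables(s2$truth, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("crossover counts are Poisson at shape 1 and match the map length", {
  lay <- GenomeLayout(data.frame(chrom = "a", length = 30e6, isZ = FALSE,
                                 parStart = NA, parEnd = NA), 1e-4)
  # nu = 1, rate 3 cM/Mb on 30 Mb: mean 0.9 CO per gamete
  mod <- MeiosisModel(rateFemale = 3, rateMale = 3, interferenceShape = 1,
                      obligateCO = FALSE)
  ev <- simulateCOTruth(lay, mod, nFemale = 0, nMale = 2500, seed = 5)
  counts <- tabulate(as.integer(sub("m", "", ev$meiosis)), nbins = 2500)
  m <- mean(counts)
  se <- sd(counts) / sqrt(2500)
  expect_lt(abs(m - 0.9), 3 * se)
  # variance consistent with Poisson
  expect_lt(abs(var(counts) - 0.9), 0.15)
  # map-length consistency under interference (shape 5) as well
  mod5 <- MeiosisModel(rateFemale = 3, rateMale = 3, interferenceShape = 5)
  ev5 <- simulateCOTruth(lay, mod5, nFemale = 0, nMale = 2500, seed = 6)
  counts5 <- tabulate(as.integer(sub("m", "", ev5$meiosis)), nbins = 2500)
  expect_lt(abs(100 * mean(counts5) - 90), 3 * 100 * sd(counts5) / sqrt(2500))
})

test_that("obligate crossover conditioning leaves no empty chromosome", {
  lay <- GenomeLayout(data.frame(chrom = "micro", length = 5e6,
                                 isZ = FALSE, parStart = NA, parEnd = NA),
                      1e-4)
  mod <- MeiosisModel(rateFemale = 2, rateMale = 2, obligateCO = TRUE)
  ev <- simulateCOTruth(lay, mod, nFemale = 50, nMale = 50, seed = 3)
  # every one of the 100 meioses must carry >= 1 CO on the chromosome
  expect_equal(length(unique(ev$meiosis)), 100L)
})

test_that("female meiosis on the Z recombines only in the PAR", {
  sim <- cleanSim(1)
  tb <- coBreakpoints(sim$truth)
  zMat <- tb[tb$chrom == "chrZ" & tb$side == "maternal", ]
  if (nrow(zMat) > 0) {
    expect_true(all(zMat$pos >= 1 & zMat$pos <= 6e5))
  }
  # accumulate over more seeds so the assertion has teeth
  mod <- MeiosisModel(rateParFemale = 500)  # many PAR events
  lay <- defaultGenomeLayout()
  ev <- simulateCOTruth(lay, mod, nFemale = 200, nMale = 0, seed = 11)
  zf <- ev[ev$chrom == "chrZ", ]
  expect_gt(nrow(zf), 50)
  expect_true(all(zf$pos <= 6e5))
  expect_error(simulateMeiosis(list(), "X", mod, lay, list()), "sex")
})

test_that("strong-allele transmission is symmetric at c = 0", {
  lay <- GenomeLayout(data.frame(chrom = "c1", length = 10e6, isZ = FALSE,
                                 parStart = NA, parEnd = NA), 5e-4)
  sim <- simulatePedigree(lay, model = MeiosisModel(ncoRatePerMb = 5,
                                                    tractLengthMean = 1000,
                                                    gbgcC = 0),
                          error = cleanErrorModel(), seed = 21)
  cv <- ncoConversions(sim$truth)
  nWS <- sum(cv$direction == "W>S"); nSW <- sum(cv$direction == "S>W")
  n <- nWS + nSW
  expect_gt(n, 20)
  expect_lt(abs(nWS / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("NCO tracts stay clear of same-meiosis crossover breakpoints", {
  sim <- cleanSim(2)
  tr <- ncoTracts(sim$truth); tb <- coBreakpoints(sim$truth)
  if (nrow(tr) > 0 && nrow(tb) > 0) {
    for (i in seq_len(nrow(tr))) {
      co <- tb$pos[tb$offspring == tr$offspring[i] &
                     tb$side == tr$side[i] & tb$chrom == tr$chrom[i]]
      if (length(co))
        expect_false(any(co >= tr$start[i] - 1 & co <= tr$end[i] + 1))
    }
  }
  expect_true(TRUE)
})

test_that("error channels surface in the emitted genotypes", {
  lay <- GenomeLayout(data.frame(chrom = "c1", length = 20e6, isZ = FALSE,
                                 parStart = NA, parEnd = NA), 1e-3)
  # all-missing: nothing phasable downstream
  simM <- simulatePedigree(lay, error = ErrorModel(missingRate = 1,
                                                   genotypeErrorRate = 0,
                                                   gqFloorFraction = 0),
                           seed = 2)
  expect_true(all(is.na(assay(simM$genotypes, "A1"))))
  ph <- phaseOffspring(simM$genotypes)
  expect_equal(nrow(ph), 0L)
  # genotype errors produce Mendelian violations at >= 1 site for 2e4 sites
  simE <- simulatePedigree(lay, error = ErrorModel(genotypeErrorRate = 0.01,
                                                   missingRate = 0,
                                                   gqFloorFraction = 0),
                           seed = 3)
  expect_gt(nrow(simE$genotypes), 1e4)
  expect_gt(sum(!mendelianConsistent(simE$genotypes)), 0)
  # clean emission is deterministic
  simC <- simulatePedigree(lay, error = cleanErrorModel(), seed = 4)
  expect_true(all(assay(simC$genotypes, "DP") == 42L))
  expect_true(all(assay(simC$genotypes, "GQ") == 99L))
})

test_that("W-contamination channel injects its diagnostic pattern", {
  lay <- GenomeLayout(data.frame(chrom = "c1", length = 10e6, isZ = FALSE,
                                 parStart = NA, parEnd = NA), 1e-3)
  sim <- simulatePedigree(lay, error = ErrorModel(genotypeErrorRate = 0,
                                                  missingRate = 0,
                                                  gqFloorFraction = 0,
                                                  wContamRate = 0.01),
                          seed = 5)
  art <- truthArtifacts(sim$truth)
  expect_gt(nrow(art), 0)
  pg <- sim$genotypes
  fem <- pedigree(pg)$sex == "F"
  idx <- match(art$pos, start(rowRanges(pg)))
  A1 <- assay(pg, "A1")[idx, , drop = FALSE]
  A2 <- assay(pg, "A2")[idx, , drop = FALSE]
  expect_true(all(A1[, fem] == 0L & A2[, fem] == 1L))
  expect_true(all(A1[, !fem] == 0L & A2[, !fem] == 0L))
})
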