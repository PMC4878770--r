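test_that("map arithmetic reproduces the pedigree study's headline values", {
  expect_equal(mapDistance(119, 5), 2380)
  expect_equal(mapDistance(186, 5), 3720)
  expect_equal(mapDistance(0, 5), 0)
  expect_error(mapDistance(-1, 5), ">= 0")
  expect_error(mapDistance(10, 0), "> 0")
  expect_equal(round(rateCmPerMb(mapDistance(2, 5), 0.6)), 67)
  expect_equal(round(rateCmPerMb(260, 260 / 2.2), 1), 2.2)
  expect_equal(rateCmPerMb(0, 50), 0)
  expect_error(rateCmPerMb(10, 0), "> 0")
})

test_that("the bundled per-chromosome table behaves like the printed one", {
  tab <- flycatcherMapTable()
  expect_equal(nrow(tab), 31L)
  auto <- tab[tab$chrom != "Z", ]
  expect_equal(sum(auto$distanceCM), 3030)
  expect_equal(sum(auto$linkageCM), 3067)
  r <- correlateWithLinkage(tab)
  expect_equal(round(r, 2), 0.95)
  expect_equal(round(correlateWithLinkage(auto), 2), 0.95)
})

test_that("linkage correlation is scale-invariant and guards degeneracy", {
  tab <- data.frame(distanceCM = c(10, 20, 30, 40),
                    linkageCM = c(11, 19, 33, 41))
  r <- correlateWithLinkage(tab)
  tab2 <- tab; tab2$distanceCM <- tab2$distanceCM * 10
  expect_equal(correlateWithLinkage(tab2), r)
  tab3 <- data.frame(distanceCM = 1:4, linkageCM = (1:4) * 2.5)
  expect_equal(correlateWithLinkage(tab3), 1)
  expect_error(correlateWithLinkage(data.frame(distanceCM = c(1, 2),
                                               linkageCM = c(2, 4))),
               "3 chromosomes")
  expect_error(correlateWithLinkage(data.frame(distanceCM = c(1, 1, 1),
                                               linkageCM = c(1, 2, 3))),
               "variance")
})

test_that("map tables split counts by side and use the Z convention", {
  ev <- data.frame(chrom = c("a", "a", "a", "z", "z"),
                   side = c("maternal", "paternal", "paternal",
                            "paternal", "maternal"))
  tab <- buildMapTable(ev, c(a = 10e6, z = 5e6), nFemale = 5, nMale = 5,
                       zChrom = "z")
  expect_equal(tab$nMaternal, c(1, 1))
  expect_equal(tab$nPaternal, c(2, 1))
  expect_equal(tab$distanceCM[tab$chrom == "a"], 100 * 3 / 10)
  # Z uses paternal events only over all meioses
  expect_equal(tab$distanceCM[tab$chrom == "z"], 100 * 1 / 10)
})

test_that("end-distance profile folds positions and compares sexes", {
  lens <- c(c1 = 100e6)
  ev <- data.frame(chrom = "c1", pos = c(0.4e6, 99.7e6, 50e6),
                   side = c("paternal", "paternal", "maternal"))
  prof <- endDistanceProfile(ev, lens)
  expect_equal(prof$distances$distance, c(0.4e6, 0.3e6, 50e6))
  # terminal 1 Mb bin contains the two male events
  expect_equal(sum(prof$histTerminal[, "M"]), 2)
  expect_error(endDistanceProfile(data.frame(chrom = "c1", pos = 2e8,
                                             side = "paternal"), lens),
               "beyond")
  # symmetric inputs give symmetric folded histograms
  ev2 <- data.frame(chrom = "c1", pos = c(1e6, 99e6, 20e6, 80e6),
                    side = "paternal")
  prof2 <- endDistanceProfile(ev2, lens)
  expect_equal(prof2$distances$distance, c(1e6, 1e6, 20e6, 20e6))
})

test_that("coincidence coefficient matches a brute-force oracle", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    pos <- sort(sample.int(10e6, n))
    meio <- sample(paste0("m", 1:4), n, replace = TRUE)
    ev <- data.frame(chrom = "t", pos = pos, meiosis = meio)
    got <- coincidenceCoefficient(ev, c(t = 10e6), nMeioses = 4)
    orc <- cocOracle(pos, meio, 10e6, 4)
    expect_equal(got$sepMb, orc$sepMb)
    expect_equal(got$observed, unname(orc$observed))
    expect_equal(got$expected, unname(orc$expected), tolerance = 1e-12)
  }
})

test_that("coincidence handles co-occurrence-free and undefined bins", {
  # two meioses, events never within 5 Mb of each other
  ev <- data.frame(chrom = "t", pos = c(1e6 + 1, 8e6 + 1, 1e6 + 2, 9e6 + 1),
                   meiosis = c("m1", "m1", "m2", "m2"))
  coc <- coincidenceCoefficient(ev, c(t = 10e6), nMeioses = 2)
  short <- coc[coc$sepMb < 5 & !is.na(coc$coc), ]
  expect_true(all(short$coc == 0))
  expect_true(any(is.na(coc$coc)))   # bins with zero expectation: undefined
  # hand-computed toy: windows 1..10, m1 in w2,w9; m2 in w2,w9
  ev2 <- data.frame(chrom = "t", pos = c(1.5e6, 8.5e6, 1.2e6, 8.2e6),
                    meiosis = c("m1", "m1", "m2", "m2"))
  coc2 <- coincidenceCoefficient(ev2, c(t = 10e6), nMeioses = 2)
  row <- coc2[coc2$sepMb == 7, ]
  # obs = 2; exp = p2 * p9 * M = 1 * 1 * 2
  expect_equal(row$observed, 2)
  expect_equal(row$expected, 2)
  expect_equal(row$coc, 1)
})

test_that("hot-spot statistic counts cross-meiosis pairs and calibrates", {
  lens <- c(c1 = 100e6)
  # three events at 10 kb spacing from three meioses: all 3 pairs count
  ev <- data.frame(chrom = "c1", pos = c(5e6, 5.01e6, 5.02e6),
                   meiosis = c("m1", "m2", "m3"))
  hs <- hotspotRandomization(ev, lens, nPerm = 1000, seed = 1)
  expect_equal(hs$observed, 3L)
  expect_lt(hs$pValue, 0.05)
  # same-meiosis pairs are excluded
  ev2 <- ev; ev2$meiosis <- "m1"
  expect_equal(hotspotRandomization(ev2, lens, nPerm = 1000,
                                    seed = 1)$observed, 0L)
  # zero events
  hs0 <- hotspotRandomization(ev[0, ], lens, nPerm = 1000, seed = 1)
  expect_equal(hs0$observed, 0L)
  expect_equal(hs0$pValue, 1)
  expect_error(hotspotRandomization(ev, lens, nPerm = 10), ">= 1000")
})

test_that("feature weights are proportional overlaps of the interval", {
  lens <- c(c1 = 100000)
  # one gene: exons [10001,10200], [11001,11200], [12001,12300], + strand
  genes <- GRangesList(g1 = GRanges("c1", IRanges(c(10001, 11001, 12001),
                                                  c(10200, 11200, 12300)),
                                    strand = "+"))
  cats <- genomicCategories(genes, lens, promoterBp = 2000)
  expect_equal(start(cats$promoter), 8001)
  expect_equal(end(cats$promoter), 10000)
  expect_equal(sum(width(cats$first_exon)), 200)
  expect_equal(start(cats$first_intron), 10201)
  expect_equal(sum(width(cats$other_exons)), 200 + 300)
  expect_equal(sum(width(cats$intergenic)),
               100000 - (2000 + 200 + 800 + 500 + 800))
  # event spanning 400 bp promoter + 600 bp intergenic
  ev <- GRanges("c1", IRanges(7401, 8400))
  fa <- featureAssignment(ev, genes, lens)
  expect_equal(fa$eventWeight[fa$category == "promoter"], 0.4)
  expect_equal(fa$eventWeight[fa$category == "intergenic"], 0.6)
  # event fully inside the first intron
  ev2 <- GRanges("c1", IRanges(10300, 10400))
  fa2 <- featureAssignment(ev2, genes, lens)
  expect_equal(fa2$eventWeight[fa2$category == "first_intron"], 1)
  expect_equal(fa2$density[fa2$category == "first_intron"], 1 / 800)
  # minus-strand gene: promoter downstream of the rightmost exon
  genesM <- GRangesList(g1 = GRanges("c1", IRanges(c(10001, 11001),
                                                   c(10200, 11200)),
                                     strand = "-"))
  catsM <- genomicCategories(genesM, lens)
  expect_equal(start(catsM$promoter), 11201)
  expect_equal(sum(width(catsM$first_exon)), 200)
  expect_equal(start(catsM$first_exon), 11001)
  expect_error(genomicCategories(
    GRangesList(g = GRanges("c1", IRanges(1, 10), strand = "*")), lens),
    "stranded")
})

test_that("feature densities match a brute-force overlap computation", {
  set.seed(314)
  lens <- c(c1 = 200000)
  genes <- GRangesList(
    g1 = GRanges("c1", IRanges(c(20001, 22001, 25001),
                               c(20500, 22400, 25800)), strand = "+"),
    g2 = GRanges("c1", IRanges(c(90001, 95001), c(90300, 95600)),
                 strand = "-"))
  cats <- genomicCategories(genes, lens)
  for (rep in 1:25) {
    n <- sample(1:10, 1)
    st <- sample.int(195000, n)
    ev <- GRanges("c1", IRanges(st, st + sample(100:5000, n, TRUE)))
    fa <- featureAssignment(ev, genes, lens)
    for (cat in fa$category) {
      manual <- 0
      cr <- as.data.frame(cats[[cat]])
      for (i in seq_along(ev)) {
        ov <- sum(pmax(0, pmin(end(ev)[i], cr$end) -
                         pmax(start(ev)[i], cr$start) + 1))
        manual <- manual + ov / width(ev)[i]
      }
      expect_equal(fa$eventWeight[fa$category == cat], manual,
                   tolerance = 1e-12)
    }
  }
})

test_that("region overlap test reduces to the closed-form odds ratio", {
  lens <- 1e6
  regions <- GRanges("c1", IRanges(c(1, 500001), c(70000, 570000)))
  ev <- GRanges("c1", IRanges(c(100, 520000, 800000, 900000),
                              width = 1))
  res <- regionOverlapTest(ev, regions, lens)
  expect_equal(res$nIn, 2L)
  expect_equal(res$nOut, 2L)
  expect_equal(res$expectedFraction, 0.14)
  ft <- fisher.test(rbind(c(2, 2), c(140, 860)))
  expect_equal(res$oddsRatio, unname(ft$estimate))
  expect_equal(res$pValue, ft$p.value)
  # zero overlap gives OR 0; degenerate regions error
  res0 <- regionOverlapTest(GRanges("c1", IRanges(2e5, 2e5)), regions, lens)
  expect_equal(res0$oddsRatio, 0)
  expect_error(regionOverlapTest(ev, GRanges("c1", IRanges(1, 1e6)), lens),
               "100%")
})

test_that("GC comparison matches the textbook paired t statistic", {
  pairs <- data.frame(chrom = c("a", "b", "c"),
                      gcEvents = c(0.46, 0.44, 0.48),
                      gcBackground = c(0.42, 0.41, 0.43))
  res <- gcContentComparison(GRanges(), pairs)
  d <- pairs$gcEvents - pairs$gcBackground
  tManual <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$t, tManual)
  expect_equal(res$pValue, 2 * pt(-abs(tManual), df = 2))
  # identical pairs: explicit degenerate path
  same <- data.frame(chrom = c("a", "b"), gcEvents = c(0.4, 0.5),
                     gcBackground = c(0.4, 0.5))
  res2 <- gcContentComparison(GRanges(), same)
  expect_true(is.na(res2$t))
  expect_equal(res2$pValue, 1)
})

test_that("GC comparison works from sequence and detects a shift", {
  set.seed(11)
  nChrom <- 12
  seqs <- Biostrings::DNAStringSet(vapply(1:nChrom, function(i)
    paste(sample(c("A", "C", "G", "T"), 20000, TRUE,
                 prob = c(0.3, 0.2, 0.2, 0.3)), collapse = ""), ""))
  names(seqs) <- paste0("c", 1:nChrom)
  # GC-rich insert at a fixed window on each chromosome
  for (i in 1:nChrom) {
    s <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE,
                      prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
    seqs[[i]] <- Biostrings::replaceAt(seqs[[i]],
                                       IRanges(5001, 7000), s)
  }
  ev <- GRanges(names(seqs), IRanges(5001, 7000))
  res <- gcContentComparison(ev, seqs)
  expect_lt(res$pValue, 0.05)
  expect_gt(mean(res$pairs$gcEvents - res$pairs$gcBackground), 0)
})

test_that("transmission bias reproduces the reconstructed study counts", {
  tb <- transmissionBias(c(rep("W>S", 135), rep("S>W", 94),
                           rep("neither", 38)))
  expect_equal(tb$nWS, 135L)
  expect_equal(tb$nSW, 94L)
  expect_equal(round(tb$pHat, 2), 0.59)
  expect_equal(round(tb$c, 2), 0.18)
  expect_equal(round(tb$ciLow, 2), 0.52)
  expect_equal(round(tb$ciHigh, 2), 0.65)
  expect_lt(tb$pValue, 0.05)
  bt <- binom.test(135, 229, 0.5)
  expect_equal(tb$pValue, bt$p.value)
  # symmetric counts: no bias
  tb2 <- transmissionBias(c(rep("W>S", 50), rep("S>W", 50)))
  expect_equal(tb2$pHat, 0.5)
  expect_equal(tb2$c, 0)
  expect_equal(tb2$pValue, 1)
  expect_error(transmissionBias(rep("neither", 5)), "no weak:strong")
  expect_output(print(tb), "W>S")
})
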