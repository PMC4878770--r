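# A container with candidate-friendly geometry: informative paternal sites
# at regular spacing on chr1, where off1 mismatches the surrounding block
# at the middle site.
ncoFixture <- function(n = 7, spacing = 10000, mismatchAt = 4,
                       ref = "A", alt = "G") {
  d <- do.call(rbind, lapply(seq_len(n), function(i)
    baseSite(pos = i * spacing, ref = ref, alt = alt)))
  # off1 paternal transmission: allele 1 (-> pgm) except at the mismatch
  # site where allele 0 (-> pgf); partner (mother) is 0/0 so off 0/1 traces
  d$off1 <- "0/1"
  d$off1[mismatchAt] <- "0/0"
  makePG(d)
}

test_that("single-site phase mismatches become candidates", {
  pg <- ncoFixture()
  ph <- phaseOffspring(pg)
  p1 <- ph[ph$offspring == "off1" & ph$side == "paternal", ]
  expect_equal(p1$label, c(2L, 2L, 2L, 1L, 2L, 2L, 2L)[seq_len(nrow(p1))])
  pr <- pruneBlocks(buildHaploblocks(ph), phased = ph)
  cand <- collectCandidates(pr)
  cand1 <- cand[cand$offspring == "off1", ]
  expect_equal(nrow(cand1), 1L)
  expect_equal(cand1$pos, 40000)
  expect_equal(cand1$focalAllele, 0L)
})

test_that("the filter cascade removes each published artifact class", {
  pg <- ncoFixture()
  ph <- phaseOffspring(pg)
  pr <- pruneBlocks(buildHaploblocks(ph), phased = ph)
  cand <- collectCandidates(pr)
  cand <- cand[cand$offspring == "off1", ]

  # clean candidate passes everything
  out <- filterNCO(cand, pg)
  expect_equal(nrow(out), 1L)
  expect_match(out$filterTrace, "tranche90=P")

  # an indel 8 bp away disqualifies; 11 bp away does not
  near <- GRanges("chr1", IRanges(40008, 40008))
  far <- GRanges("chr1", IRanges(40011, 40011))
  expect_equal(nrow(filterNCO(cand, pg, indels = near)), 0L)
  expect_equal(nrow(filterNCO(cand, pg, indels = far)), 1L)

  # four called SNPs within 30 bp disqualify
  clustered <- c(granges(rowRanges(pg)),
                 GRanges("chr1", IRanges(c(39990, 40005, 40010),
                                         c(39990, 40005, 40010))))
  out2 <- filterNCO(cand, pg, fullSites = clustered)
  expect_equal(nrow(out2), 0L)
  expect_match(attr(out2, "trace")$filterTrace, "cluster30=F")

  # failing the strict tranche
  pg90 <- pg
  rr <- rowRanges(pg90); mcols(rr)$tranche90[4] <- FALSE
  rowRanges(pg90) <- rr
  out3 <- filterNCO(cand, pg90)
  expect_equal(nrow(out3), 0L)

  # allele balance: a heterozygous individual at 15% minor fraction
  ADR <- assay(pg, "ADREF"); ADA <- assay(pg, "ADALT")
  ADR[4, "father"] <- 3L; ADA[4, "father"] <- 17L
  pgAB <- PedigreeGenotypes(rowRanges(pg), pedigree(pg), assay(pg, "A1"),
                            assay(pg, "A2"), DP = assay(pg, "DP"),
                            ADREF = ADR, ADALT = ADA)
  out4 <- filterNCO(cand, pgAB)
  expect_equal(nrow(out4), 0L)
  expect_match(attr(out4, "trace")$filterTrace, "allele_balance=F")
  # 25% exactly passes
  ADR[4, "father"] <- 5L; ADA[4, "father"] <- 15L
  pgAB2 <- PedigreeGenotypes(rowRanges(pg), pedigree(pg), assay(pg, "A1"),
                             assay(pg, "A2"), DP = assay(pg, "DP"),
                             ADREF = ADR, ADALT = ADA)
  expect_equal(nrow(filterNCO(cand, pgAB2)), 1L)

  # reads on a third allele
  ADO <- matrix(0L, nrow(pg), ncol(pg),
                dimnames = list(NULL, colnames(pg)))
  ADO[4, "off2"] <- 2L
  pg3a <- PedigreeGenotypes(rowRanges(pg), pedigree(pg), assay(pg, "A1"),
                            assay(pg, "A2"), DP = assay(pg, "DP"),
                            ADOTH = ADO)
  out5 <- filterNCO(cand, pg3a)
  expect_equal(nrow(out5), 0L)
  expect_match(attr(out5, "trace")$filterTrace, "third_allele=F")
})

test_that("deviating-site density within 5 kb disqualifies candidates", {
  # three deviating sites; the middle one sees both others within +-2.5 kb
  pg <- ncoFixture(n = 9, spacing = 1000)
  cand <- data.frame(offspring = "off1", side = "paternal", chrom = "chr1",
                     pos = c(2000, 4000, 5000),
                     label = 1L, surroundLabel = 2L, focalAllele = 0L)
  out <- filterNCO(cand, pg)
  expect_equal(out$pos, c(2000, 5000))
  expect_match(attr(out, "trace")$filterTrace[2], "deviant5k=F")
  # two deviating sites within the window are allowed
  cand2 <- cand[c(1, 3), ]
  expect_equal(nrow(filterNCO(cand2, pg)), 2L)
})

test_that("the W-contamination pattern filter is exact on tagged artifacts", {
  lay <- GenomeLayout(data.frame(chrom = "c1", length = 10e6, isZ = FALSE,
                                 parStart = NA, parEnd = NA), 1e-3)
  sim <- simulatePedigree(lay, error = ErrorModel(genotypeErrorRate = 0,
                                                  missingRate = 0,
                                                  gqFloorFraction = 0,
                                                  wContamRate = 0.005),
                          seed = 8)
  art <- truthArtifacts(sim$truth)
  expect_gt(nrow(art), 3)
  # artifact sites pass Mendelian checks (0/0 x 0/1 parents) and surface
  # as paternal-side mismatch candidates where the site was informative;
  # feed all artifact positions through the filter directly
  pg <- sim$genotypes
  cand <- data.frame(offspring = "off1", side = "paternal",
                     chrom = art$chrom, pos = art$pos,
                     label = 1L, surroundLabel = 2L, focalAllele = 1L)
  out <- filterNCO(cand, pg)
  tr <- attr(out, "trace")
  expect_true(all(grepl("w_contamination=F", tr$filterTrace)))
  expect_equal(nrow(out), 0L)
})

test_that("conversion direction uses the weak/strong classes", {
  expect_equal(classifyDirection("G", "A"), "W>S")
  expect_equal(classifyDirection("C", "T"), "W>S")
  expect_equal(classifyDirection("T", "C"), "S>W")
  expect_equal(classifyDirection("A", "T"), "neither")
  expect_equal(classifyDirection("G", "C"), "neither")
  expect_equal(classifyDirection(c("G", "A"), c("A", "G")), c("W>S", "S>W"))
  expect_error(classifyDirection("N", "A"), "A, C, G or T")
})

test_that("surviving events on clean simulations are true conversions", {
  hits <- 0
  for (seed in 1:6) {
    sim <- cleanSim(seed)
    ch <- runChain(sim)
    nco <- filterNCO(collectCandidates(ch$pruned), ch$filtered$genotypes)
    ev <- evaluateNCORecovery(sim$truth, nco)
    if (ev$nCalled > 0) {
      expect_equal(ev$precision, 1)
      hits <- hits + ev$nCalled
    }
  }
  expect_gt(hits, 0)   # the check must actually have exercised events
})
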