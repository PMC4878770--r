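#' @importFrom GenomicRanges findOverlaps countOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

# Z-row bookkeeping: which rows sit on the Z chromosome, and which of those
# are outside the PAR. Taken from explicit arguments or the layout stored in
# metadata at simulation time.
zInfo <- function(x, zChrom = NULL, par = NULL) {
  lay <- metadata(x)$layout
  if (is.null(zChrom) && !is.null(lay)) {
    ct <- lay@chromosomes
    if (any(ct$isZ)) zChrom <- ct$chrom[ct$isZ]
  }
  if (is.null(par) && !is.null(lay)) par <- parRanges(lay)
  chrom <- as.character(seqnames(rowRanges(x)))
  onZ <- if (is.null(zChrom)) rep(FALSE, nrow(x)) else chrom %in% zChrom
  inPar <- rep(FALSE, nrow(x))
  if (!is.null(par) && length(par) > 0)
    inPar <- countOverlaps(rowRanges(x), par) > 0
  list(onZ = onZ, nonParZ = onZ & !inPar)
}

#' Coerce female Z genotypes to their haploid semantics
#'
#' On the non-PAR Z, females are hemizygous: a diploid homozygous call is
#' coerced to a haploid call, and a diploid heterozygous call (impossible
#' without a mapping artifact, absent haploid recall data) causes the site
#' to be removed. PAR sites are left untouched.
#'
#' @param x a [PedigreeGenotypes-class].
#' @param zChrom Z chromosome name(s); default from the layout in
#'   \code{metadata(x)}.
#' @param par PAR interval as a GRanges; default from the layout.
#' @return list with \code{genotypes} (modified object) and \code{nRemoved}
#'   (sites dropped for female heterozygosity on the non-PAR Z).
#' @export
applyZSemantics <- function(x, zChrom = NULL, par = NULL) {
  zi <- zInfo(x, zChrom, par)
  fem <- colData(x)$sex == "F"
  if (!any(zi$nonParZ) || !any(fem))
    return(list(genotypes = x, nRemoved = 0L))
  A1 <- assay(x, "A1"); A2 <- assay(x, "A2")
  sub1 <- A1[zi$nonParZ, fem, drop = FALSE]
  sub2 <- A2[zi$nonParZ, fem, drop = FALSE]
  het <- !is.na(sub1) & !is.na(sub2) & sub1 != sub2
  bad <- rowSums(het) > 0
  sub2[!is.na(sub2)] <- NA_integer_
  A2[zi$nonParZ, fem] <- sub2
  assays(x)$A2 <- A2
  keep <- rep(TRUE, nrow(x))
  keep[which(zi$nonParZ)[bad]] <- FALSE
  list(genotypes = x[keep, ], nRemoved = sum(bad))
}

#' Site-level quality filtering
#'
#' Applies the pre-phasing site filters in a fixed order so that removal
#' counts are comparable across runs: (1) repeat/gap masks, (2) biallelic
#' SNPs only (multi-allelic records removed), (3) per-individual coverage bounds
#' (DP >= \code{minDP} and DP <= \code{maxDPFactor} x mean autosomal
#' coverage; for females on the non-PAR Z the upper bound is 1 x the mean
#' autosomal coverage), (4) genotype quality GQ >= \code{minGQ} for every
#' individual, and (5) Mendelian consistency across the whole pedigree
#' (ZW-aware: a haploid female's Z allele must come from her father).
#'
#' @param x a [PedigreeGenotypes-class]; run [applyZSemantics()] first when
#'   the input carries diploid female Z calls.
#' @param meanCoverage mean autosomal coverage (reads), > 0.
#' @param repeats,gaps mask GRanges; combined with the \code{inRepeat} /
#'   \code{inGap} row flags.
#' @param minDP,maxDPFactor,minGQ thresholds (defaults 15 reads, 2x, 30).
#' @param pedigree pedigree table the samples must belong to (defaults to
#'   the container's own colData).
#' @param zChrom,par Z/PAR location, defaulting from the stored layout.
#' @return list with \code{genotypes} (surviving sites) and \code{report}
#'   (data.frame: filter, removed; attributes \code{input} and
#'   \code{surviving}).
#' @examples
#' sim <- simulatePedigree(defaultGenomeLayout(), seed = 1,
#'                         error = cleanErrorModel())
#' fl <- filterSites(sim$genotypes, meanCoverage = 42)
#' fl$report
#' @export
filterSites <- function(x, meanCoverage, repeats = NULL, gaps = NULL,
                        minDP = 15, maxDPFactor = 2, minGQ = 30,
                        pedigree = NULL, zChrom = NULL, par = NULL) {
  if (meanCoverage <= 0) stop("meanCoverage must be > 0")
  ped <- if (is.null(pedigree)) as.data.frame(colData(x)) else pedigree
  if (!all(colnames(x) %in% ped$id)) {
    miss <- setdiff(colnames(x), ped$id)
    stop("sample(s) not in pedigree: ", paste(miss, collapse = ", "))
  }
  n0 <- nrow(x)
  report <- data.frame(filter = character(), removed = integer())
  drop1 <- function(x, keep, name) {
    report <<- rbind(report,
                     data.frame(filter = name, removed = sum(!keep)))
    x[keep, ]
  }

  ## 1. masks
  m <- mcols(rowRanges(x))
  masked <- m$inRepeat | m$inGap
  if (!is.null(repeats) && length(repeats) > 0)
    masked <- masked | countOverlaps(rowRanges(x), repeats) > 0
  if (!is.null(gaps) && length(gaps) > 0)
    masked <- masked | countOverlaps(rowRanges(x), gaps) > 0
  x <- drop1(x, !masked, "mask")

  ## 2. biallelic SNPs
  m <- mcols(rowRanges(x))
  bad <- !(m$REF %in% c("A", "C", "G", "T")) |
    !(m$ALT %in% c("A", "C", "G", "T")) | m$REF == m$ALT
  if (!is.null(m$multiallelic)) bad <- bad | m$multiallelic
  x <- drop1(x, !bad, "biallelic")

  ## 3. coverage
  zi <- zInfo(x, zChrom, par)
  DP <- assay(x, "DP")
  maxDP <- matrix(maxDPFactor * meanCoverage, nrow(x), ncol(x))
  fem <- colData(x)$sex == "F"
  if (any(zi$nonParZ) && any(fem))
    maxDP[zi$nonParZ, fem] <- meanCoverage
  ok <- !is.na(DP) & DP >= minDP & DP <= maxDP
  x <- drop1(x, rowSums(!ok) == 0, "coverage")

  ## 4. genotype quality
  GQ <- assay(x, "GQ")
  ok <- !is.na(GQ) & GQ >= minGQ
  x <- drop1(x, rowSums(!ok) == 0, "GQ")

  ## 5. Mendelian consistency
  x <- drop1(x, mendelianConsistent(x), "mendelian")

  attr(report, "input") <- n0
  attr(report, "surviving") <- nrow(x)
  list(genotypes = x, report = report)
}

#' Mendelian consistency of every site across the pedigree
#'
#' A site is consistent when every child's genotype can be produced from its
#' parents': one allele present in the father and the other in the mother.
#' Haploid children (females on the non-PAR Z) must carry an allele present
#' in the father (the Z is paternally inherited in ZW systems); a haploid
#' mother contributes her single allele. Sites with a missing genotype in a
#' trio are not judged for that trio.
#'
#' @param x a [PedigreeGenotypes-class].
#' @return logical vector, one element per site.
#' @export
mendelianConsistent <- function(x) {
  ped <- pedigree(x)
  A1 <- assay(x, "A1"); A2 <- assay(x, "A2")
  ok <- rep(TRUE, nrow(x))
  kids <- which(!is.na(ped$father))
  for (j in kids) {
    fa <- match(ped$father[j], ped$id)
    mo <- match(ped$mother[j], ped$id)
    c1 <- A1[, j]; c2 <- A2[, j]
    f1 <- A1[, fa]; f2 <- A2[, fa]
    m1 <- A1[, mo]; m2 <- A2[, mo]
    judged <- !is.na(c1) & !is.na(f1) & !is.na(m1)
    hapChild <- judged & is.na(c2)
    inF1 <- hasAllele(f1, f2, 0L); inF2 <- hasAllele(f1, f2, 1L)
    inM1 <- hasAllele(m1, m2, 0L); inM2 <- hasAllele(m1, m2, 1L)
    inF <- function(a) ifelse(a == 0L, inF1, inF2)
    inM <- function(a) ifelse(a == 0L, inM1, inM2)
    dip <- judged & !is.na(c2)
    good <- rep(TRUE, nrow(x))
    good[dip] <- ((inF(c1) & inM(c2)) | (inF(c2) & inM(c1)))[dip]
    good[hapChild] <- inF(c1)[hapChild]
    ok <- ok & good
  }
  ok
}
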