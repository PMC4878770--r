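#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges granges seqnames start end width mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData
#'   assay assays assays<-
NULL

## ------------------------------------------------------------------------
## GenomeLayout
## ------------------------------------------------------------------------

#' Genome layout for the pedigree simulator
#'
#' Describes the chromosomes of a (down-scaled) genome: physical lengths, a
#' Z-chromosome flag, an optional pseudoautosomal region (PAR) on the Z, and
#' the expected density of segregating sites among the founders.
#'
#' In birds the female is the heterogametic sex (ZW); the Z and W pair and
#' recombine only in the PAR, so the PAR is the only region of the Z that
#' recombines in female meiosis.
#'
#' @slot chromosomes data.frame with columns \code{chrom} (character),
#'   \code{length} (bp), \code{isZ} (logical), \code{parStart}, \code{parEnd}
#'   (1-based inclusive bp, \code{NA} when absent).
#' @slot snpDensity expected heterozygous-site density per bp among founders.
#' @export
setClass("GenomeLayout",
  representation(chromosomes = "data.frame", snpDensity = "numeric"))

setValidity("GenomeLayout", function(object) {
  ch <- object@chromosomes
  req <- c("chrom", "length", "isZ", "parStart", "parEnd")
  if (!all(req %in% names(ch)))
    return(paste("chromosomes must have columns:", paste(req, collapse = ", ")))
  if (nrow(ch) == 0) return("at least one chromosome required")
  if (anyDuplicated(ch$chrom)) return("duplicated chromosome names")
  if (any(ch$length <= 0)) return("chromosome lengths must be > 0")
  hasPar <- !is.na(ch$parStart)
  if (any(hasPar != !is.na(ch$parEnd)))
    return("parStart/parEnd must both be set or both NA")
  if (any(hasPar & !ch$isZ))
    return("PAR interval only allowed on the Z-flagged chromosome")
  if (any(hasPar & (ch$parStart < 1 | ch$parEnd > ch$length |
                    ch$parStart > ch$parEnd)))
    return("PAR interval must lie within its chromosome")
  if (length(object@snpDensity) != 1 || object@snpDensity < 0)
    return("snpDensity must be a single non-negative number")
  TRUE
})

#' @param chromosomes data.frame as described in the class slots.
#' @param snpDensity expected segregating-site density per bp.
#' @rdname GenomeLayout-class
#' @export
GenomeLayout <- function(chromosomes, snpDensity = 1e-4) {
  chromosomes$chrom <- as.character(chromosomes$chrom)
  if (is.null(chromosomes$isZ)) chromosomes$isZ <- FALSE
  if (is.null(chromosomes$parStart)) chromosomes$parStart <- NA_real_
  if (is.null(chromosomes$parEnd)) chromosomes$parEnd <- NA_real_
  new("GenomeLayout", chromosomes = chromosomes, snpDensity = snpDensity)
}

#' Default desk-scale genome layout
#'
#' Three chromosomes: two autosomes (20 Mb, 8 Mb) and a 15 Mb Z carrying a
#' 0.6 Mb PAR, at a segregating-site density of 1e-4 per bp. Small enough to
#' simulate and analyse in seconds while exercising autosomal, Z and PAR
#' code paths.
#'
#' @param snpDensity expected segregating-site density per bp.
#' @return A [GenomeLayout-class] object.
#' @export
defaultGenomeLayout <- function(snpDensity = 1e-4) {
  GenomeLayout(data.frame(
    chrom    = c("chr1", "chr2", "chrZ"),
    length   = c(20e6, 8e6, 15e6),
    isZ      = c(FALSE, FALSE, TRUE),
    parStart = c(NA, NA, 1),
    parEnd   = c(NA, NA, 6e5)
  ), snpDensity = snpDensity)
}

#' @rdname GenomeLayout-class
#' @param object,x a \code{GenomeLayout}.
#' @export
setMethod("show", "GenomeLayout", function(object) {
  ch <- object@chromosomes
  cat("GenomeLayout with", nrow(ch), "chromosome(s), density",
      format(object@snpDensity), "per bp\n")
  for (i in seq_len(nrow(ch))) {
    cat(sprintf("  %-8s %10.0f bp%s%s\n", ch$chrom[i], ch$length[i],
                if (ch$isZ[i]) " [Z]" else "",
                if (!is.na(ch$parStart[i]))
                  sprintf(" PAR [%d, %d]", as.integer(ch$parStart[i]),
                          as.integer(ch$parEnd[i])) else ""))
  }
})

#' @rdname GenomeLayout-class
#' @export
chromLengths <- function(x) {
  stats::setNames(x@chromosomes$length, x@chromosomes$chrom)
}

#' @rdname GenomeLayout-class
#' @export
chromTable <- function(x) x@chromosomes

#' PAR interval of a layout as GRanges (empty if no PAR)
#' @param x a \code{GenomeLayout}.
#' @export
parRanges <- function(x) {
  ch <- x@chromosomes
  i <- which(!is.na(ch$parStart))
  GRanges(ch$chrom[i], IRanges(ch$parStart[i], ch$parEnd[i]))
}

## ------------------------------------------------------------------------
## MeiosisModel
## ------------------------------------------------------------------------

#' Meiosis model for the simulator
#'
#' Parameters of the crossover (CO) and non-crossover (NCO) processes in one
#' meiosis. COs are placed by a stationary gamma-renewal process whose shape
#' \code{interferenceShape} controls crossover interference (1 = Poisson, no
#' interference; larger values suppress nearby double COs). Rates are gamete
#' rates in cM/Mb, i.e. expected transmitted COs per Mb is rate/100. NCO
#' initiation is Poisson along the chromosome with geometric tract lengths;
#' inside a tract, at heterozygous weak/strong (A,T vs G,C) sites the strong
#' allele is transmitted with probability (1 + c)/2 (GC-biased gene
#' conversion), and at weak:weak or strong:strong heterozygous sites either
#' allele with probability 1/2.
#'
#' @slot rateFemale,rateMale sex-specific CO rates, cM/Mb.
#' @slot rateParFemale female CO rate inside the Z PAR, cM/Mb.
#' @slot obligateCO if TRUE, a chromosome's CO set is rejection-resampled
#'   until non-empty (gamete-level approximation of the obligate chiasma).
#' @slot interferenceShape gamma-renewal shape (>= 1).
#' @slot ncoRatePerMb expected NCO tract initiations per Mb per meiosis.
#' @slot tractLengthMean mean NCO conversion-tract length, bp.
#' @slot gbgcC transmission distortion c in [-1, 1].
#' @export
setClass("MeiosisModel",
  representation(rateFemale = "numeric", rateMale = "numeric",
                 rateParFemale = "numeric", obligateCO = "logical",
                 interferenceShape = "numeric", ncoRatePerMb = "numeric",
                 tractLengthMean = "numeric", gbgcC = "numeric"))

setValidity("MeiosisModel", function(object) {
  if (object@rateFemale < 0 || object@rateMale < 0 || object@rateParFemale < 0)
    return("CO rates must be >= 0")
  if (object@interferenceShape < 1)
    return("interferenceShape must be >= 1")
  if (object@ncoRatePerMb < 0) return("ncoRatePerMb must be >= 0")
  if (object@tractLengthMean < 1) return("tractLengthMean must be >= 1 bp")
  p <- (1 + object@gbgcC) / 2
  if (p < 0 || p > 1) return("gbgcC must lie in [-1, 1]")
  TRUE
})

#' @param rateFemale,rateMale,rateParFemale,obligateCO,interferenceShape,ncoRatePerMb,tractLengthMean,gbgcC
#'   see slot documentation. Defaults are the study conditions: 2.28 / 3.56
#'   cM/Mb female/male genome-wide rates, 67 cM/Mb in the PAR, interference
#'   shape 5, 0.1 NCO initiations per Mb with 500 bp mean tracts, c = 0.18.
#' @rdname MeiosisModel-class
#' @export
MeiosisModel <- function(rateFemale = 2.28, rateMale = 3.56,
                         rateParFemale = 67, obligateCO = FALSE,
                         interferenceShape = 5, ncoRatePerMb = 0.1,
                         tractLengthMean = 500, gbgcC = 0.18) {
  new("MeiosisModel", rateFemale = rateFemale, rateMale = rateMale,
      rateParFemale = rateParFemale, obligateCO = obligateCO,
      interferenceShape = interferenceShape, ncoRatePerMb = ncoRatePerMb,
      tractLengthMean = tractLengthMean, gbgcC = gbgcC)
}

#' @rdname MeiosisModel-class
#' @param object a \code{MeiosisModel}.
#' @export
setMethod("show", "MeiosisModel", function(object) {
  cat("MeiosisModel:",
      sprintf("female %.2f / male %.2f cM/Mb (PAR %.1f), nu = %g%s\n",
              object@rateFemale, object@rateMale, object@rateParFemale,
              object@interferenceShape,
              if (object@obligateCO) ", obligate CO" else ""))
  cat(sprintf("  NCO: %.3g /Mb/meiosis, mean tract %g bp, gBGC c = %.3g\n",
              object@ncoRatePerMb, object@tractLengthMean, object@gbgcC))
})

## ------------------------------------------------------------------------
## ErrorModel
## ------------------------------------------------------------------------

#' Genotype-call error model
#'
#' Artifact channels applied when genotypes are emitted: random genotype
#' miscalls, missing calls, Poisson read depth, a fraction of low-GQ sites,
#' and a W-contamination channel that overwrites autosomal sites with the
#' all-females-heterozygous / all-males-homozygous-reference pattern typical
#' of W-linked reads mapping to a male-derived assembly.
#'
#' When every stochastic channel is zero the emission is fully deterministic
#' (DP = \code{depthMean}, GQ = 99, exact allele-depth split), so that a
#' "clean" simulation survives quality filtering completely.
#'
#' @slot genotypeErrorRate per-site, per-individual miscall probability.
#' @slot missingRate per-site, per-individual missing-call probability.
#' @slot depthMean mean read depth.
#' @slot gqFloorFraction fraction of calls emitted with GQ < 30.
#' @slot wContamRate fraction of autosomal sites overwritten with the
#'   W-contamination pattern (truth-tagged).
#' @export
setClass("ErrorModel",
  representation(genotypeErrorRate = "numeric", missingRate = "numeric",
                 depthMean = "numeric", gqFloorFraction = "numeric",
                 wContamRate = "numeric"))

setValidity("ErrorModel", function(object) {
  p <- c(object@genotypeErrorRate, object@missingRate,
         object@gqFloorFraction, object@wContamRate)
  if (any(p < 0 | p > 1)) return("probabilities must lie in [0, 1]")
  if (object@depthMean <= 0) return("depthMean must be > 0")
  TRUE
})

#' @param genotypeErrorRate,missingRate,depthMean,gqFloorFraction,wContamRate
#'   see slots.
#' @rdname ErrorModel-class
#' @export
ErrorModel <- function(genotypeErrorRate = 1e-3, missingRate = 0.01,
                       depthMean = 42, gqFloorFraction = 0.02,
                       wContamRate = 0) {
  new("ErrorModel", genotypeErrorRate = genotypeErrorRate,
      missingRate = missingRate, depthMean = depthMean,
      gqFloorFraction = gqFloorFraction, wContamRate = wContamRate)
}

#' @rdname ErrorModel-class
#' @export
cleanErrorModel <- function(depthMean = 42) {
  ErrorModel(genotypeErrorRate = 0, missingRate = 0, depthMean = depthMean,
             gqFloorFraction = 0, wContamRate = 0)
}

isCleanErrorModel <- function(em) {
  em@genotypeErrorRate == 0 && em@missingRate == 0 &&
    em@gqFloorFraction == 0 && em@wContamRate == 0
}

#' @rdname ErrorModel-class
#' @param object an \code{ErrorModel}.
#' @export
setMethod("show", "ErrorModel", function(object) {
  cat(sprintf(paste0("ErrorModel: miscall %.3g, missing %.3g, depth %g, ",
                     "GQ-floor %.3g, W-contam %.3g%s\n"),
              object@genotypeErrorRate, object@missingRate, object@depthMean,
              object@gqFloorFraction, object@wContamRate,
              if (isCleanErrorModel(object)) " [clean/deterministic]" else ""))
})

## ------------------------------------------------------------------------
## SimTruth
## ------------------------------------------------------------------------

#' Simulation ground truth
#'
#' Crossover breakpoints and non-crossover conversion tracts of the observable
#' F1-to-F2 meioses, plus injected-artifact site positions. All positions are
#' 1-based bp.
#'
#' @slot coBreakpoints data.frame: offspring, side ("paternal"/"maternal"),
#'   chrom, pos.
#' @slot ncoTracts data.frame: offspring, side, chrom, start, end.
#' @slot ncoConversions data.frame: offspring, side, chrom, pos, fromAllele,
#'   toAllele, direction ("W>S", "S>W", "neither"). One row per heterozygous
#'   site inside a tract whose transmitted allele differs from the background
#'   haplotype.
#' @slot artifacts data.frame: chrom, pos of injected W-contamination sites.
#' @export
setClass("SimTruth",
  representation(coBreakpoints = "data.frame", ncoTracts = "data.frame",
                 ncoConversions = "data.frame", artifacts = "data.frame"))

emptyTruth <- function() {
  new("SimTruth",
      coBreakpoints = data.frame(offspring = character(), side = character(),
                                 chrom = character(), pos = numeric()),
      ncoTracts = data.frame(offspring = character(), side = character(),
                             chrom = character(), start = numeric(),
                             end = numeric()),
      ncoConversions = data.frame(offspring = character(), side = character(),
                                  chrom = character(), pos = numeric(),
                                  fromAllele = character(),
                                  toAllele = character(),
                                  direction = character()),
      artifacts = data.frame(chrom = character(), pos = numeric()))
}

#' @rdname SimTruth-class
#' @param object a \code{SimTruth}.
#' @export
setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@coBreakpoints), "CO breakpoints,",
      nrow(object@ncoTracts), "NCO tracts,",
      nrow(object@ncoConversions), "converted sites,",
      nrow(object@artifacts), "artifact sites\n")
})

#' @rdname SimTruth-class
#' @param x a \code{SimTruth}.
#' @export
coBreakpoints <- function(x) x@coBreakpoints

#' @rdname SimTruth-class
#' @export
ncoTracts <- function(x) x@ncoTracts

#' @rdname SimTruth-class
#' @export
ncoConversions <- function(x) x@ncoConversions

#' @rdname SimTruth-class
#' @export
truthArtifacts <- function(x) x@artifacts

## ------------------------------------------------------------------------
## PedigreeGenotypes
## ------------------------------------------------------------------------

#' Multi-sample site genotypes for the pedigree
#'
#' A \code{RangedSummarizedExperiment} with one row per biallelic SNP site and
#' one column per pedigree individual. Assays (all site-by-individual
#' matrices): \code{A1}, \code{A2} integer allele codes (0 = REF, 1 = ALT,
#' \code{NA} = missing; \code{A2} is \code{NA} for haploid calls, which occur
#' only for females on the non-PAR Z), \code{DP}, \code{GQ}, \code{ADREF},
#' \code{ADALT}, \code{ADOTH} (reads on a third allele). Row metadata carries
#' \code{REF}, \code{ALT} bases and site flags \code{inRepeat}, \code{inGap},
#' \code{nearIndel}, \code{tranche90}, \code{tranche999}. \code{colData}
#' carries the pedigree (id, sex, generation, father, mother).
#'
#' @export
setClass("PedigreeGenotypes", contains = "RangedSummarizedExperiment")

setValidity("PedigreeGenotypes", function(object) {
  need <- c("A1", "A2", "DP", "GQ", "ADREF", "ADALT", "ADOTH")
  if (!all(need %in% names(assays(object))))
    return(paste("missing assays:", paste(setdiff(need, names(assays(object))),
                                          collapse = ", ")))
  cd <- colData(object)
  needc <- c("id", "sex", "generation", "father", "mother")
  if (!all(needc %in% names(cd)))
    return(paste("colData must have:", paste(needc, collapse = ", ")))
  if (!all(cd$sex %in% c("F", "M"))) return("sex must be 'F' or 'M'")
  m <- mcols(rowRanges(object))
  needr <- c("REF", "ALT", "inRepeat", "inGap", "nearIndel",
             "tranche90", "tranche999")
  if (!all(needr %in% names(m)))
    return(paste("rowRanges mcols must have:", paste(needr, collapse = ", ")))
  if (any(start(rowRanges(object)) < 1)) return("positions must be >= 1")
  ad <- assay(object, "ADREF") + assay(object, "ADALT")
  dp <- assay(object, "DP")
  if (any(!is.na(ad) & !is.na(dp) & ad > dp + 1L))
    return("AD entries must sum to <= DP (+1 rounding tolerance)")
  TRUE
})

#' Construct a PedigreeGenotypes container
#'
#' @param gr GRanges of site positions (width 1) with mcols REF/ALT; flag
#'   columns are added as FALSE when absent.
#' @param pedigree data.frame with id, sex, generation, father, mother
#'   (see [flycatcherPedigree()]).
#' @param A1,A2,DP,GQ,ADREF,ADALT,ADOTH site-by-individual matrices; missing
#'   AD/DP/GQ matrices default to generous values so hand-built toy
#'   containers pass filters unless a test sets them.
#' @return A [PedigreeGenotypes-class] object.
#' @export
PedigreeGenotypes <- function(gr, pedigree, A1, A2, DP = NULL, GQ = NULL,
                              ADREF = NULL, ADALT = NULL, ADOTH = NULL) {
  n <- length(gr); k <- nrow(pedigree)
  m <- mcols(gr)
  for (fl in c("inRepeat", "inGap", "nearIndel"))
    if (is.null(m[[fl]])) m[[fl]] <- rep(FALSE, n)
  for (fl in c("tranche90", "tranche999"))
    if (is.null(m[[fl]])) m[[fl]] <- rep(TRUE, n)
  mcols(gr) <- m
  full <- function(v) matrix(as.integer(v), n, k)
  if (is.null(DP)) DP <- full(42L)
  if (is.null(GQ)) GQ <- full(99L)
  if (is.null(ADREF) || is.null(ADALT)) {
    ad <- genotypeToAD(A1, A2, DP)
    if (is.null(ADREF)) ADREF <- ad$ADREF
    if (is.null(ADALT)) ADALT <- ad$ADALT
  }
  if (is.null(ADOTH)) ADOTH <- full(0L)
  storage.mode(A1) <- "integer"; storage.mode(A2) <- "integer"
  dimn <- list(NULL, pedigree$id)
  al <- lapply(list(A1 = A1, A2 = A2, DP = DP, GQ = GQ, ADREF = ADREF,
                    ADALT = ADALT, ADOTH = ADOTH),
               function(x) { dimnames(x) <- dimn
                             storage.mode(x) <- "integer"; x })
  se <- SummarizedExperiment(assays = al, rowRanges = gr,
                             colData = DataFrame(pedigree,
                                                 row.names = pedigree$id))
  new("PedigreeGenotypes", se)
}

#' @rdname PedigreeGenotypes-class
#' @param object a \code{PedigreeGenotypes}.
#' @export
setMethod("show", "PedigreeGenotypes", function(object) {
  cat("PedigreeGenotypes:", nrow(object), "sites x", ncol(object),
      "individuals on",
      length(unique(as.character(seqnames(rowRanges(object))))),
      "chromosome(s)\n")
  gen <- colData(object)$generation
  cat("  generations:",
      paste(sprintf("%s=%d", c("P", "F1", "F2"),
                    vapply(c("P", "F1", "F2"),
                           function(g) sum(gen == g), 0L)),
           collapse = " "), "\n")
})

#' Pedigree table of a PedigreeGenotypes object
#' @param x a \code{PedigreeGenotypes}.
#' @export
pedigree <- function(x) as.data.frame(colData(x))
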