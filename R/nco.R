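# Non-crossover gene-conversion detection: candidate collection, the
# stringent filter cascade, and weak/strong direction classification.

#' Collect non-crossover candidates
#'
#' Every single-site phase mismatch inside a haploblock — i.e. every
#' single-site block removed by [pruneBlocks()] — becomes a candidate,
#' carrying the label of the surrounding block. Multi-site removed blocks
#' remain in the suspect log and are not candidates.
#'
#' @param pruned result of [pruneBlocks()].
#' @return data.frame of candidates (offspring, side, chrom, pos, label,
#'   surroundLabel and, if available, focalAllele).
#' @export
collectCandidates <- function(pruned) {
  pruned$ncoCandidates
}

ncoFilterNames <- c("tranche90", "indel", "cluster30", "deviant5k",
                    "third_allele", "allele_balance", "w_contamination")

#' Apply the stringent non-crossover filter cascade
#'
#' A candidate survives only if it passes every filter (pure conjunction;
#' the recorded trace order is fixed for reporting):
#' \itemize{
#'   \item \code{tranche90}: site passes the strict 90\% recalibration
#'     tranche (row flag).
#'   \item \code{indel}: no indel overlapping or within 10 bp.
#'   \item \code{cluster30}: no more than 3 called SNPs within a 30 bp
#'     window centred on the candidate, evaluated on the full called site
#'     set.
#'   \item \code{deviant5k}: no more than 2 phase-deviating sites within a
#'     5 kb window centred on the candidate, evaluated on the same
#'     offspring/side sequence.
#'   \item \code{third_allele}: no individual has reads supporting a third
#'     allele.
#'   \item \code{allele_balance}: in every heterozygous individual the
#'     minor allele is supported by at least 25\% of the reads; candidates
#'     lacking allele-depth data are removed with trace code \code{no_ad}.
#'   \item \code{w_contamination}: the site does not show the
#'     all-females-heterozygous / all-males-homozygous-reference pattern of
#'     W-linked reads mis-mapped to a male-derived assembly.
#' }
#'
#' @param candidates data.frame from [collectCandidates()].
#' @param x the [PedigreeGenotypes-class] providing genotypes, allele
#'   depths and tranche flags at candidate sites.
#' @param fullSites GRanges of all called SNPs for the cluster filter
#'   (default: the sites of \code{x}).
#' @param indels GRanges of indel positions (optional).
#' @param indelPad bp distance below which an indel disqualifies (10).
#' @param clusterWindow,clusterMax SNP-cluster rule (30 bp, >3 SNPs).
#' @param deviantWindow,deviantMax deviating-site rule (5 kb, >2 sites).
#' @param minAlleleFrac minimum minor-allele read fraction (0.25).
#' @return data.frame of surviving events with \code{refAllele},
#'   \code{altAllele}, \code{convertedFrom}, \code{convertedTo},
#'   \code{direction} and \code{filterTrace}; attribute \code{"trace"}
#'   holds the per-candidate filter decisions for all candidates.
#' @export
filterNCO <- function(candidates, x, fullSites = NULL, indels = NULL,
                      indelPad = 10, clusterWindow = 30, clusterMax = 3,
                      deviantWindow = 5000, deviantMax = 2,
                      minAlleleFrac = 0.25) {
  if (nrow(candidates) == 0) {
    out <- cbind(candidates,
                 data.frame(convertedFrom = character(),
                            convertedTo = character(),
                            direction = character(),
                            filterTrace = character()))
    attr(out, "trace") <- out
    return(out)
  }
  if (is.null(fullSites)) fullSites <- granges(rowRanges(x))
  gr <- rowRanges(x)
  key <- paste(as.character(seqnames(gr)), start(gr))
  ri <- match(paste(candidates$chrom, candidates$pos), key)
  if (anyNA(ri))
    stop("candidate site(s) absent from the genotype container")

  pass <- matrix(TRUE, nrow(candidates), length(ncoFilterNames),
                 dimnames = list(NULL, ncoFilterNames))
  noAD <- rep(FALSE, nrow(candidates))

  m <- mcols(gr)
  pass[, "tranche90"] <- m$tranche90[ri]

  if (!is.null(indels) && length(indels) > 0) {
    cgr <- GRanges(candidates$chrom, IRanges(candidates$pos,
                                             candidates$pos))
    pass[, "indel"] <- countOverlaps(cgr, indels + indelPad) == 0
  }

  half <- clusterWindow / 2
  fsChrom <- as.character(seqnames(fullSites)); fsPos <- start(fullSites)
  nNear <- vapply(seq_len(nrow(candidates)), function(i)
    sum(fsChrom == candidates$chrom[i] &
          abs(fsPos - candidates$pos[i]) <= half), 0L)
  pass[, "cluster30"] <- nNear <= clusterMax

  dhalf <- deviantWindow / 2
  ckey <- paste(candidates$offspring, candidates$side, candidates$chrom)
  nDev <- vapply(seq_len(nrow(candidates)), function(i)
    sum(ckey == ckey[i] &
          abs(candidates$pos - candidates$pos[i]) <= dhalf), 0L)
  pass[, "deviant5k"] <- nDev <= deviantMax

  ADOTH <- assay(x, "ADOTH")[ri, , drop = FALSE]
  pass[, "third_allele"] <- rowSums(ADOTH > 0, na.rm = TRUE) == 0

  A1 <- assay(x, "A1")[ri, , drop = FALSE]
  A2 <- assay(x, "A2")[ri, , drop = FALSE]
  ADR <- assay(x, "ADREF")[ri, , drop = FALSE]
  ADA <- assay(x, "ADALT")[ri, , drop = FALSE]
  het <- isHet(A1, A2)
  noAD <- rowSums(het & (is.na(ADR) | is.na(ADA))) > 0
  tot <- ADR + ADA
  frac <- pmin(ADR, ADA) / ifelse(tot > 0, tot, NA)
  bad <- het & !is.na(frac) & frac < minAlleleFrac
  badZero <- het & !is.na(tot) & tot == 0
  pass[, "allele_balance"] <- rowSums(bad | badZero, na.rm = TRUE) == 0 &
    !noAD

  fem <- colData(x)$sex == "F"
  homRef <- !is.na(A1) & A1 == 0L & (is.na(A2) | A2 == 0L)
  wpat <- rowSums(het[, fem, drop = FALSE]) == sum(fem) &
    rowSums(homRef[, !fem, drop = FALSE]) == sum(!fem)
  pass[, "w_contamination"] <- !wpat

  trace <- apply(pass, 1, function(p)
    paste(paste0(ncoFilterNames, "=", ifelse(p, "P", "F")),
          collapse = ";"))
  trace[noAD] <- paste0(trace[noAD], ";no_ad")
  keep <- rowSums(!pass) == 0

  refA <- m$REF[ri]; altA <- m$ALT[ri]
  focal <- candidates$focalAllele
  if (is.null(focal)) focal <- rep(NA_integer_, nrow(candidates))
  transB <- ifelse(focal == 0L, refA, altA)
  fromB <- ifelse(focal == 0L, altA, refA)
  dir <- rep(NA_character_, nrow(candidates))
  known <- !is.na(focal)
  if (any(known))
    dir[known] <- classifyDirection(transB[known], fromB[known])
  allc <- cbind(candidates,
                data.frame(refAllele = refA, altAllele = altA,
                           convertedFrom = fromB, convertedTo = transB,
                           direction = dir, filterTrace = trace))
  out <- allc[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trace") <- allc
  out
}

#' Classify the weak/strong direction of a conversion
#'
#' "Weak" (W) alleles are A or T; "strong" (S) alleles are G or C. A
#' conversion is W>S when a weak allele was converted by (replaced with) a
#' strong allele — transmitted allele strong, untransmitted weak — and
#' S>W in the symmetric case; conversions between two weak or two strong
#' alleles are "neither".
#'
#' @param transmitted,untransmitted single bases (vectorized), A/C/G/T.
#' @return character vector: "W>S", "S>W" or "neither".
#' @examples
#' classifyDirection("G", "A")  # W>S
#' classifyDirection("T", "C")  # S>W
#' classifyDirection("T", "A")  # neither
#' @export
classifyDirection <- function(transmitted, untransmitted) {
  okBase <- function(b) b %in% c("A", "C", "G", "T")
  if (!all(okBase(transmitted) & okBase(untransmitted)))
    stop("alleles must be A, C, G or T")
  ifelse(isStrong(transmitted) & isWeak(untransmitted), "W>S",
         ifelse(isWeak(transmitted) & isStrong(untransmitted), "S>W",
                "neither"))
}
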