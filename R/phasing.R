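# Grandparent-of-origin phasing of F1 transmissions.
#
# A site is phase-informative for one parental side when the transmitting F1
# is heterozygous and its parents' genotypes differ so that each F1 allele
# is attributable to exactly one grandparent. Transmission to an offspring
# is traceable unless the F1's partner and the offspring are both
# heterozygous. Origin labels are small integer codes with a fixed legend:
# 1 = grandfather of the side, 2 = grandmother of the side.

#' @export
ORIGIN_GRANDFATHER <- 1L
#' @export
ORIGIN_GRANDMOTHER <- 2L

#' Classify a site as phase-informative for one parental side
#'
#' @param gf,gm,f1 genotypes of the side's grandfather, grandmother and F1
#'   parent as integer allele vectors (length 2, or length 1 for haploid
#'   calls), allele codes 0/1.
#' @return \code{NULL} when the site is not phasable; otherwise a list with
#'   \code{alleleGF} and \code{alleleGM}, the allele codes attributable to
#'   the side's grandfather and grandmother.
#' @examples
#' classifyInformative(c(0, 0), c(1, 1), c(0, 1))  # 0 -> GF, 1 -> GM
#' classifyInformative(c(0, 0), c(0, 1), c(0, 1))  # 1 -> GM, hence 0 -> GF
#' classifyInformative(c(0, 1), c(0, 1), c(0, 1))  # ambiguous -> NULL
#' @export
classifyInformative <- function(gf, gm, f1) {
  if (anyNA(gf) || anyNA(gm) || anyNA(f1)) return(NULL)
  if (length(f1) != 2 || f1[1] == f1[2]) return(NULL)   # F1 must be het 0/1
  has <- function(g, al) al %in% g
  validA <- has(gf, 0L) && has(gm, 1L)   # 0 from GF, 1 from GM
  validB <- has(gf, 1L) && has(gm, 0L)   # 1 from GF, 0 from GM
  if (validA == validB) return(NULL)     # neither, or both (ambiguous)
  if (validA) list(alleleGF = 0L, alleleGM = 1L)
  else list(alleleGF = 1L, alleleGM = 0L)
}

#' Trace an offspring's focal-side allele back to a grandparent
#'
#' Determines which allele the offspring received from the focal F1 parent
#' and maps it to a grandparent via the site's allele mapping. Untraceable
#' when partner and offspring are both heterozygous. A haploid offspring
#' call (female on the non-PAR Z) is paternally inherited, so it is resolved
#' directly on the paternal side and is untraceable on the maternal side.
#'
#' @param mapping result of [classifyInformative()].
#' @param partner genotype of the F1's partner (integer allele vector).
#' @param offspring genotype of the F2 offspring.
#' @param side "paternal" or "maternal" (used for haploid offspring calls).
#' @return \code{ORIGIN_GRANDFATHER}, \code{ORIGIN_GRANDMOTHER}, or
#'   \code{NA} (untraceable).
#' @export
assignOrigin <- function(mapping, partner, offspring, side = "paternal") {
  if (is.null(mapping) || anyNA(offspring)) return(NA_integer_)
  lab <- function(al) {
    if (al == mapping$alleleGF) ORIGIN_GRANDFATHER
    else if (al == mapping$alleleGM) ORIGIN_GRANDMOTHER
    else stop("offspring allele not present in either F1 allele")
  }
  if (length(offspring) == 1) {          # haploid: paternal Z transmission
    if (side != "paternal") return(NA_integer_)
    return(lab(offspring[1]))
  }
  offHet <- offspring[1] != offspring[2]
  if (!offHet) {
    if (!anyNA(partner) && !offspring[1] %in% partner)
      stop("offspring allele not present in either parent")
    return(lab(offspring[1]))
  }
  if (anyNA(partner)) return(NA_integer_)
  partnerHet <- length(partner) == 2 && partner[1] != partner[2]
  if (partnerHet) return(NA_integer_)    # both het: untraceable
  p <- partner[1]
  if (!p %in% offspring)
    stop("offspring allele not present in either parent")
  lab(offspring[1] + offspring[2] - p)   # the non-partner allele
}

#' Phase all F2 offspring along every chromosome
#'
#' Emits, per offspring and parental side, the ordered sequence of
#' grandparent-of-origin labels at phase-informative, traceable sites. A
#' site may be informative for both sides; it is then emitted once per side.
#' Untraceable sites are excluded from the sequences but counted.
#'
#' @param x a filtered [PedigreeGenotypes-class].
#' @param sides one or both of "paternal", "maternal".
#' @return data.frame with \code{chrom}, \code{pos}, \code{offspring},
#'   \code{side}, \code{label} (1 = grandfather, 2 = grandmother of the
#'   side) and \code{focalAllele} (transmitted allele code), sorted by
#'   chromosome and position; attribute \code{"untraceable"} holds per
#'   offspring/side counts of informative-but-untraceable sites.
#' @export
phaseOffspring <- function(x, sides = c("paternal", "maternal")) {
  ped <- pedigree(x)
  gr <- rowRanges(x)
  o <- order(match(as.character(seqnames(gr)), unique(as.character(seqnames(gr)))),
             start(gr))
  if (!identical(o, seq_along(gr))) x <- x[o, ]
  gr <- rowRanges(x)
  A1 <- assay(x, "A1"); A2 <- assay(x, "A2")
  chrom <- as.character(seqnames(gr)); pos <- start(gr)

  out <- list(); untr <- list()
  for (side in sides) {
    r <- sideRoles(ped, side)
    gfI <- match(r$gf, ped$id); gmI <- match(r$gm, ped$id)
    f1I <- match(r$f1, ped$id); paI <- match(r$partner, ped$id)
    f1het <- isHet(A1[, f1I], A2[, f1I])
    present <- !is.na(A1[, gfI]) & !is.na(A1[, gmI]) & !is.na(A1[, paI])
    validA <- hasAllele(A1[, gfI], A2[, gfI], 0L) &
      hasAllele(A1[, gmI], A2[, gmI], 1L)
    validB <- hasAllele(A1[, gfI], A2[, gfI], 1L) &
      hasAllele(A1[, gmI], A2[, gmI], 0L)
    phasable <- f1het & present & xor(validA, validB)
    alleleGF <- ifelse(validA, 0L, 1L)

    p1 <- A1[, paI]; p2 <- A2[, paI]
    partnerHet <- isHet(p1, p2)
    pHom <- ifelse(partnerHet, NA_integer_, p1)

    for (offId in r$offspring) {
      oI <- match(offId, ped$id)
      o1 <- A1[, oI]; o2 <- A2[, oI]
      offHap <- !is.na(o1) & is.na(o2)
      offHet <- isHet(o1, o2)
      focal <- rep(NA_integer_, nrow(x))
      # haploid offspring: allele is the paternal Z transmission
      if (side == "paternal") focal[offHap] <- o1[offHap]
      hom <- !is.na(o1) & !is.na(o2) & o1 == o2
      focal[hom] <- o1[hom]
      resolvable <- offHet & !partnerHet & !is.na(pHom) &
        (pHom == o1 | pHom == o2)
      focal[resolvable] <- (o1 + o2 - pHom)[resolvable]
      ok <- phasable & !is.na(focal) & (focal == 0L | focal == 1L)
      lab <- ifelse(focal == alleleGF, ORIGIN_GRANDFATHER,
                    ORIGIN_GRANDMOTHER)
      idx <- which(ok)
      out[[paste(side, offId)]] <- data.frame(
        chrom = chrom[idx], pos = pos[idx],
        offspring = rep(offId, length(idx)),
        side = rep(side, length(idx)),
        label = lab[idx], focalAllele = focal[idx])
      untr[[paste(side, offId)]] <- data.frame(
        offspring = offId, side = side,
        untraceable = sum(phasable & is.na(focal) & !is.na(o1)))
    }
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res <- res[order(match(res$chrom, unique(chrom)), res$pos), ]
  rownames(res) <- NULL
  attr(res, "untraceable") <- do.call(rbind, c(untr,
                                               make.row.names = FALSE))
  res
}
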