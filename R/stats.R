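#' @importFrom stats binom.test fisher.test t.test wilcox.test cor median
#'   pnorm
#' @importFrom GenomicRanges reduce setdiff intersect width pintersect
#' @importFrom IRanges subsetByOverlaps overlapsAny
NULL

#' Genetic map distance from event counts
#'
#' One centiMorgan equals one expected crossover per 100 meioses, so the
#' distance is 100 x events / meioses. Sex-specific maps use the same-sex
#' meioses only (5 in the default pedigree); sex-average per-chromosome
#' values use all 10.
#'
#' @param nEvents crossover count (>= 0).
#' @param nMeioses number of meioses observed (> 0).
#' @return distance in cM.
#' @examples
#' mapDistance(119, 5)  # 2380 cM, a female autosomal map
#' mapDistance(186, 5)  # 3720 cM, a male autosomal map
#' @export
mapDistance <- function(nEvents, nMeioses) {
  if (any(nEvents < 0)) stop("event counts must be >= 0")
  if (any(nMeioses <= 0)) stop("nMeioses must be > 0")
  100 * nEvents / nMeioses
}

#' Recombination rate in cM/Mb
#' @param distanceCM genetic distance, cM.
#' @param lengthMb physical length, Mb (> 0).
#' @examples
#' rateCmPerMb(mapDistance(2, 5), 0.6)  # ~67 cM/Mb, a PAR-like rate
#' @export
rateCmPerMb <- function(distanceCM, lengthMb) {
  if (any(lengthMb <= 0)) stop("lengthMb must be > 0")
  distanceCM / lengthMb
}

#' Per-chromosome genetic map table
#'
#' Tabulates crossover events per chromosome and side and converts counts
#' to distances. The per-chromosome distance is the sex-average
#' 100 x total / (nFemale + nMale); for the Z chromosome the paternal
#' (male-meiosis) events are used over the same denominator, since only
#' male meiosis recombines along the full Z. Maternal events correspond to
#' female meioses, paternal to male.
#'
#' @param events midpoint GRanges ([crossoverMidpoints()]) or data.frame
#'   with chrom and side.
#' @param lengths named chromosome lengths, bp.
#' @param nFemale,nMale numbers of female / male meioses (default 5 each).
#' @param zChrom name(s) of the Z chromosome (optional).
#' @param linkage optional named vector of external linkage map lengths
#'   (cM) per chromosome.
#' @return data.frame: chrom, lengthMb, nTotal, nMaternal, nPaternal,
#'   distanceCM, rateCMperMb and (if given) linkageCM.
#' @export
buildMapTable <- function(events, lengths, nFemale = 5, nMale = 5,
                          zChrom = NULL, linkage = NULL) {
  if (inherits(events, "GRanges"))
    events <- data.frame(chrom = as.character(seqnames(events)),
                         side = mcols(events)$side)
  chroms <- names(lengths)
  tab <- data.frame(chrom = chroms, lengthMb = unname(lengths) / 1e6)
  cnt <- function(sel) vapply(chroms, function(cn)
    sum(events$chrom == cn & sel), 0)
  tab$nMaternal <- cnt(events$side == "maternal")
  tab$nPaternal <- cnt(events$side == "paternal")
  tab$nTotal <- tab$nMaternal + tab$nPaternal
  nAll <- nFemale + nMale
  effective <- ifelse(tab$chrom %in% zChrom, tab$nPaternal, tab$nTotal)
  tab$distanceCM <- mapDistance(effective, nAll)
  tab$rateCMperMb <- rateCmPerMb(tab$distanceCM, tab$lengthMb)
  if (!is.null(linkage)) tab$linkageCM <- unname(linkage[tab$chrom])
  tab
}

#' Correlation between observed and linkage-based map lengths
#'
#' Pearson product-moment correlation between the observed per-chromosome
#' distances (or raw counts — r is invariant to the constant conversion)
#' and external linkage map lengths.
#'
#' @param mapTable data.frame with the two columns.
#' @param distanceCol,linkageCol column names.
#' @return Pearson r.
#' @export
correlateWithLinkage <- function(mapTable, distanceCol = "distanceCM",
                                 linkageCol = "linkageCM") {
  x <- mapTable[[distanceCol]]; y <- mapTable[[linkageCol]]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 chromosomes")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a column")
  cor(x, y)
}

#' Crossover density relative to chromosome ends
#'
#' Computes each event's distance to its nearest chromosome end
#' (min(midpoint, length - midpoint)), bins the distances per sex in
#' \code{windowLarge} windows genome-wide and in \code{windowSmall}
#' windows within the terminal \code{windowLarge}, splits counts by
#' chromosome size class, and compares the per-event terminal distances
#' between sexes with a Wilcoxon rank-sum test (z from the normal
#' approximation; the one-sided p tests male events lying closer to ends).
#'
#' @param events midpoint GRanges with side metadata, or data.frame with
#'   chrom, pos, side.
#' @param lengths named chromosome lengths, bp.
#' @param windowLarge,windowSmall bin widths (10 Mb, 1 Mb).
#' @param sizeClasses breaks (bp) for chromosome size classes.
#' @return list: \code{distances} per-event data.frame (sex, distance),
#'   \code{histLarge}, \code{histTerminal} count tables (bin x sex),
#'   \code{test} = list(z, pOneSided, pTwoSided).
#' @export
endDistanceProfile <- function(events, lengths, windowLarge = 10e6,
                               windowSmall = 1e6,
                               sizeClasses = c(50e6, 100e6)) {
  if (inherits(events, "GRanges"))
    events <- data.frame(chrom = as.character(seqnames(events)),
                         pos = start(events),
                         side = mcols(events)$side)
  L <- lengths[events$chrom]
  if (anyNA(L)) stop("event on chromosome with unknown length")
  if (any(events$pos > L | events$pos < 1))
    stop("event beyond chromosome length")
  d <- pmin(events$pos, L - events$pos)
  sex <- ifelse(events$side == "maternal", "F", "M")
  sizeClass <- cut(as.numeric(L), c(0, sizeClasses, Inf))
  binL <- floor(d / windowLarge)
  histLarge <- table(bin = binL, sex = sex)
  term <- d < windowLarge
  histTerminal <- table(bin = floor(d[term] / windowSmall),
                        sex = sex[term])
  test <- list(z = NA_real_, pOneSided = NA_real_, pTwoSided = NA_real_)
  if (length(unique(sex)) == 2) {
    dm <- d[sex == "M"]; df <- d[sex == "F"]
    w <- suppressWarnings(wilcox.test(df, dm))
    # normal approximation with tie correction for the z score
    nm <- length(dm); nf <- length(df)
    r <- rank(c(df, dm))
    W <- sum(r[seq_len(nf)]) - nf * (nf + 1) / 2
    mu <- nf * nm / 2
    ties <- table(r)
    sig <- sqrt(nf * nm / 12 *
                  (nf + nm + 1 - sum(ties^3 - ties) /
                     ((nf + nm) * (nf + nm - 1))))
    z <- (W - mu) / sig
    test <- list(z = z, pOneSided = pnorm(z, lower.tail = FALSE),
                 pTwoSided = w$p.value)
  }
  list(distances = data.frame(chrom = events$chrom, sex = sex,
                              distance = unname(d),
                              sizeClass = sizeClass),
       histLarge = histLarge, histTerminal = histTerminal, test = test)
}

#' Coefficient of coincidence profile
#'
#' Tiles every chromosome with windows of \code{window} bp and, for each
#' pair of windows at a given separation, counts meioses with a crossover
#' in both windows (observed doubles) against the product of the windows'
#' marginal crossover probabilities summed over pairs (expected doubles).
#' CoC(d) = observed/expected aggregated over all window pairs at
#' separation d, genome-wide. CoC < 1 at short separations indicates
#' positive interference.
#'
#' @param events midpoint GRanges with meiosis metadata, or data.frame
#'   with chrom, pos, meiosis.
#' @param lengths named chromosome lengths, bp.
#' @param nMeioses total number of meioses observed (meioses without
#'   events count toward the marginals).
#' @param window window size, bp (default 1 Mb).
#' @param maxSepMb maximum separation reported, Mb (default all).
#' @return data.frame: sepMb, observed, expected, coc (NA where the
#'   expectation is zero: undefined, not 0).
#' @export
coincidenceCoefficient <- function(events, lengths, nMeioses,
                                   window = 1e6, maxSepMb = Inf) {
  if (inherits(events, "GRanges"))
    events <- data.frame(chrom = as.character(seqnames(events)),
                         pos = start(events),
                         meiosis = mcols(events)$meiosis)
  if (is.null(events$meiosis)) stop("events must carry meiosis identity")
  meio <- sort(unique(as.character(events$meiosis)))
  acc <- new.env()
  for (cn in names(lengths)) {
    nW <- ceiling(lengths[[cn]] / window)
    if (nW < 2) next
    ev <- events[events$chrom == cn, ]
    inc <- matrix(FALSE, length(meio), nW)
    if (nrow(ev) > 0) {
      wi <- pmin(floor((ev$pos - 1) / window) + 1L, nW)
      mi <- match(as.character(ev$meiosis), meio)
      inc[cbind(mi, wi)] <- TRUE
    }
    p <- colSums(inc) / nMeioses
    obsM <- crossprod(inc)            # meioses with CO in both windows
    maxK <- min(nW - 1L, ceiling(maxSepMb * 1e6 / window))
    for (k in seq_len(maxK)) {
      i <- seq_len(nW - k)
      o <- sum(obsM[cbind(i, i + k)])
      e <- sum(p[i] * p[i + k]) * nMeioses
      keyk <- as.character(k)
      prev <- if (is.null(acc[[keyk]])) c(0, 0) else acc[[keyk]]
      acc[[keyk]] <- prev + c(o, e)
    }
  }
  ks <- sort(as.integer(ls(acc)))
  if (length(ks) == 0)
    return(data.frame(sepMb = numeric(), observed = numeric(),
                      expected = numeric(), coc = numeric()))
  obs <- vapply(ks, function(k) acc[[as.character(k)]][1], 0)
  expd <- vapply(ks, function(k) acc[[as.character(k)]][2], 0)
  data.frame(sepMb = ks * window / 1e6, observed = obs, expected = expd,
             coc = ifelse(expd > 0, obs / expd, NA_real_))
}

# Unordered event pairs within `d` bp on one chromosome, total and within
# the same meiosis, via a sorted two-pointer scan.
countClosePairs <- function(pos, d) {
  if (length(pos) < 2) return(0L)
  s <- sort.int(pos, method = "quick")
  sum(findInterval(s + d, s) - seq_along(s))
}

countCrossMeiosisPairs <- function(pos, meiosis, d, groups = NULL) {
  tot <- countClosePairs(pos, d)
  # only meioses contributing >= 2 events can form same-meiosis pairs
  if (is.null(groups)) {
    sp <- split(seq_along(pos), meiosis)
    groups <- sp[vapply(sp, length, 0L) >= 2]
  }
  for (g in groups) tot <- tot - countClosePairs(pos[g], d)
  tot
}

#' Hot-spot test by randomizing event placement
#'
#' The statistic is the number of unordered pairs of crossover events from
#' independent meioses located within \code{pairDistance} on the same
#' chromosome. Each permutation replicate redraws every event's midpoint
#' uniformly on its own chromosome, preserving per-chromosome and
#' per-meiosis event counts; p = (1 + #replicates >= observed) /
#' (1 + nPerm).
#'
#' @param events midpoint GRanges with meiosis metadata, or data.frame
#'   with chrom, pos, meiosis.
#' @param lengths named chromosome lengths, bp.
#' @param pairDistance co-localization distance, bp (default 100 kb).
#' @param nPerm number of permutation replicates (>= 1000).
#' @param seed optional integer seed.
#' @return list: observed pair count, pValue, permCounts.
#' @export
hotspotRandomization <- function(events, lengths, pairDistance = 1e5,
                                 nPerm = 1000, seed = NULL) {
  if (nPerm < 1000) stop("nPerm must be >= 1000")
  if (inherits(events, "GRanges"))
    events <- data.frame(chrom = as.character(seqnames(events)),
                         pos = start(events),
                         meiosis = as.character(mcols(events)$meiosis))
  if (nrow(events) == 0)
    return(list(observed = 0L, pValue = 1, permCounts = integer(0)))
  byChrom <- split(seq_len(nrow(events)), events$chrom)
  observed <- sum(vapply(byChrom, function(i)
    countCrossMeiosisPairs(events$pos[i], events$meiosis[i], pairDistance),
    0L))
  chromLen <- lengths[names(byChrom)]
  nByChrom <- vapply(byChrom, length, 0L)
  # same-meiosis index groups are invariant under position permutation
  grpByChrom <- lapply(byChrom, function(i) {
    sp <- split(seq_along(i), events$meiosis[i])
    sp[vapply(sp, length, 0L) >= 2]
  })
  withSeed(seed, {
    permCounts <- vapply(seq_len(nPerm), function(b) {
      tot <- 0L
      for (ci in seq_along(byChrom)) {
        p <- ceiling(runif(nByChrom[ci]) * chromLen[ci])
        tot <- tot + countCrossMeiosisPairs(p, NULL, pairDistance,
                                            groups = grpByChrom[[ci]])
      }
      tot
    }, 0L)
    list(observed = observed,
         pValue = (1 + sum(permCounts >= observed)) / (1 + nPerm),
         permCounts = permCounts)
  })
}

## ------------------------------------------------------------------------
## Genomic-feature association
## ------------------------------------------------------------------------

#' Disjoint genomic category map from a transcript annotation
#'
#' Splits the genome into promoter (\code{promoterBp} upstream of the TSS,
#' strand-aware), first exon, first intron, other exons, other introns and
#' intergenic DNA. Overlaps between categories (from overlapping genes)
#' are resolved by that precedence order.
#'
#' @param exonsByTx GRangesList of exons grouped by transcript, each
#'   element on one strand (strand "*" is an error: promoters cannot be
#'   derived).
#' @param lengths named chromosome lengths, bp.
#' @param promoterBp promoter size upstream of the TSS (default 2000).
#' @return named GRangesList of the six disjoint category range sets.
#' @export
genomicCategories <- function(exonsByTx, lengths, promoterBp = 2000) {
  allEx <- unlist(exonsByTx, use.names = FALSE)
  if ("*" %in% as.character(GenomicRanges::strand(allEx)))
    stop("annotation must be stranded to derive promoters")
  firstExon <- GRanges(); otherExons <- GRanges()
  firstIntron <- GRanges(); otherIntrons <- GRanges()
  promoter <- GRanges()
  for (ti in seq_along(exonsByTx)) {
    tx <- GenomicRanges::sort(exonsByTx[[ti]])
    minus <- as.character(GenomicRanges::strand(tx))[1] == "-"
    n <- length(tx)
    ord <- if (minus) rev(seq_len(n)) else seq_len(n)
    ex <- tx[ord]                     # transcription order
    firstExon <- c(firstExon, granges(ex[1]))
    if (n > 1) otherExons <- c(otherExons, granges(ex[-1]))
    if (n > 1) {
      gaps <- GRanges(seqnames(tx)[1],
                      IRanges(end(tx)[-n] + 1, start(tx)[-1] - 1),
                      strand = GenomicRanges::strand(tx)[1])
      gaps <- gaps[width(gaps) > 0]
      gord <- if (minus) rev(seq_along(gaps)) else seq_along(gaps)
      gaps <- gaps[gord]
      if (length(gaps) > 0) {
        firstIntron <- c(firstIntron, granges(gaps[1]))
        if (length(gaps) > 1)
          otherIntrons <- c(otherIntrons, granges(gaps[-1]))
      }
    }
    tss <- if (minus) end(tx)[n] else start(tx)[1]
    pr <- if (minus) IRanges(tss + 1, tss + promoterBp)
          else IRanges(max(1, tss - promoterBp), tss - 1)
    if (start(pr) <= end(pr))
      promoter <- c(promoter, GRanges(seqnames(tx)[1], pr))
  }
  genome <- GRanges(names(lengths), IRanges(1, unname(lengths)))
  cats <- list(promoter = promoter, first_exon = firstExon,
               first_intron = firstIntron, other_exons = otherExons,
               other_introns = otherIntrons)
  cats <- lapply(cats, function(g) {
    g <- reduce(granges(g), ignore.strand = TRUE)
    if (length(g) == 0) return(g)
    ln <- unname(lengths[as.character(seqnames(g))])
    gs <- pmax(start(g), 1); ge <- pmin(end(g), ln)
    keep <- gs <= ge
    GRanges(seqnames(g)[keep], IRanges(gs[keep], ge[keep]))
  })
  taken <- GRanges()
  out <- list()
  for (nm in names(cats)) {
    out[[nm]] <- GenomicRanges::setdiff(cats[[nm]], taken,
                                        ignore.strand = TRUE)
    taken <- reduce(c(taken, out[[nm]]), ignore.strand = TRUE)
  }
  out$intergenic <- GenomicRanges::setdiff(genome, taken,
                                           ignore.strand = TRUE)
  out
}

#' Event density per genomic category
#'
#' Each event interval contributes weight = overlap/interval length to
#' every category it overlaps; the per-category density is the summed
#' weight divided by the category's bp. Pairwise Fisher's exact tests
#' compare each genic category against intergenic DNA on the 2x2 table of
#' (rounded event weights) x (category kb, rounded), as event-vs-bp
#' contingency requires integer margins.
#'
#' @param events CO-interval GRanges (typically restricted to events with
#'   resolution below 5 kb) or NCO point GRanges.
#' @param exonsByTx GRangesList of exons grouped by transcript.
#' @param lengths named chromosome lengths.
#' @param promoterBp promoter size, bp.
#' @return data.frame per category: bp, eventWeight, density (events/bp),
#'   and for genic categories the Fisher OR and p vs intergenic.
#' @export
featureAssignment <- function(events, exonsByTx, lengths,
                              promoterBp = 2000) {
  cats <- genomicCategories(exonsByTx, lengths, promoterBp)
  evW <- width(events)
  res <- data.frame(category = names(cats),
                    bp = vapply(cats, function(g) sum(as.numeric(width(g))),
                                0))
  res$eventWeight <- vapply(cats, function(g) {
    if (length(events) == 0) return(0)
    hits <- findOverlaps(events, g)
    if (length(hits) == 0) return(0)
    ow <- width(pintersect(events[queryHits(hits)], g[subjectHits(hits)]))
    sum(ow / evW[queryHits(hits)])
  }, 0)
  res$density <- res$eventWeight / res$bp
  inter <- res[res$category == "intergenic", ]
  res$fisherOR <- NA_real_; res$fisherP <- NA_real_
  for (i in which(res$category != "intergenic")) {
    tab <- rbind(c(round(res$eventWeight[i]), round(inter$eventWeight)),
                 c(round(res$bp[i] / 1000), round(inter$bp / 1000)))
    if (all(rowSums(tab) > 0)) {
      ft <- fisher.test(tab)
      res$fisherOR[i] <- unname(ft$estimate)
      res$fisherP[i] <- ft$p.value
    }
  }
  rownames(res) <- NULL
  res
}

#' Overlap of events with a region set
#'
#' Counts events whose midpoint (point position for NCOs) falls inside the
#' merged regions and tests enrichment/depletion against the genomic
#' background with Fisher's exact test on (events in/out) x (region kb,
#' non-region kb).
#'
#' @param events point GRanges (midpoints).
#' @param regions region GRanges (merged internally).
#' @param genomeBp total genome size, bp.
#' @return list: nIn, nOut, regionBp, oddsRatio (conditional MLE), pValue,
#'   expectedFraction.
#' @export
regionOverlapTest <- function(events, regions, genomeBp) {
  regions <- reduce(granges(regions), ignore.strand = TRUE)
  regionBp <- sum(as.numeric(width(regions)))
  if (regionBp <= 0 || regionBp >= genomeBp)
    stop("regions must cover more than 0% and less than 100% of the genome")
  nIn <- sum(overlapsAny(events, regions))
  nOut <- length(events) - nIn
  tab <- rbind(c(nIn, nOut),
               c(round(regionBp / 1000),
                 round((genomeBp - regionBp) / 1000)))
  ft <- fisher.test(tab)
  list(nIn = nIn, nOut = nOut, regionBp = regionBp,
       oddsRatio = unname(ft$estimate), pValue = ft$p.value,
       expectedFraction = regionBp / genomeBp)
}

#' GC content of crossover regions versus chromosome background
#'
#' Pairs, per chromosome with at least one event, the mean GC fraction of
#' the event intervals with the chromosome's background GC, and applies a
#' paired t-test. Chromosomes without events are dropped and counted. With
#' identical pairs everywhere (all differences zero) the t statistic is
#' undefined and p = 1 is returned explicitly.
#'
#' @param events interval GRanges.
#' @param genome a \code{DNAStringSet} (names = chromosomes) or a
#'   data.frame with chrom, gcEvents, gcBackground pairs (one row per
#'   chromosome) for precomputed GC.
#' @return list: pairs data.frame, t, pValue, nDropped.
#' @export
gcContentComparison <- function(events, genome) {
  if (is.data.frame(genome)) {
    pairs <- genome
  } else {
    chroms <- unique(as.character(seqnames(events)))
    gc <- function(s) {
      f <- Biostrings::letterFrequency(s, c("G", "C", "A", "T"))
      tot <- sum(f)
      if (tot == 0) NA_real_ else sum(f[, c("G", "C")]) / tot
    }
    pairs <- do.call(rbind, lapply(chroms, function(cn) {
      ev <- events[as.character(seqnames(events)) == cn]
      sq <- genome[[cn]]
      evSeq <- Biostrings::DNAStringSet(sq, start = start(ev),
                                        end = pmin(end(ev), length(sq)))
      f <- Biostrings::letterFrequency(evSeq, c("G", "C", "A", "T"))
      data.frame(chrom = cn,
                 gcEvents = sum(f[, c("G", "C")]) / sum(f),
                 gcBackground = gc(Biostrings::DNAStringSet(sq)))
    }))
  }
  nDropped <- sum(is.na(pairs$gcEvents) | is.na(pairs$gcBackground))
  pairs <- pairs[!is.na(pairs$gcEvents) & !is.na(pairs$gcBackground), ]
  dif <- pairs$gcEvents - pairs$gcBackground
  if (length(dif) < 2)
    return(list(pairs = pairs, t = NA_real_, pValue = NA_real_,
                nDropped = nDropped))
  if (stats::sd(dif) == 0) {
    # degenerate: all differences equal; zero difference is the null itself
    return(list(pairs = pairs, t = if (mean(dif) == 0) NA_real_ else Inf,
                pValue = if (mean(dif) == 0) 1 else 0,
                nDropped = nDropped))
  }
  tt <- t.test(pairs$gcEvents, pairs$gcBackground, paired = TRUE)
  list(pairs = pairs, t = unname(tt$statistic), pValue = tt$p.value,
       nDropped = nDropped)
}

#' GC-biased gene conversion transmission test
#'
#' Counts weak-to-strong (W>S) and strong-to-weak (S>W) conversions among
#' direction-classified NCO events ("neither" events are excluded), tests
#' the strong-transmission probability against 0.5 with an exact two-sided
#' binomial test, reports the Clopper-Pearson 95% CI, and converts the
#' estimate to the transmission distortion c = 2p - 1 (the strong allele
#' is transmitted with probability (1 + c)/2).
#'
#' @param directions character vector of directions ("W>S", "S>W",
#'   "neither"), e.g. the \code{direction} column of [filterNCO()] output
#'   or of [ncoConversions()].
#' @return list of class \code{TransmissionBias}: nWS, nSW, pHat, ciLow,
#'   ciHigh, c, pValue.
#' @examples
#' transmissionBias(c(rep("W>S", 135), rep("S>W", 94)))
#' @export
transmissionBias <- function(directions) {
  nWS <- sum(directions == "W>S", na.rm = TRUE)
  nSW <- sum(directions == "S>W", na.rm = TRUE)
  if (nWS + nSW == 0) stop("no weak:strong conversion events")
  bt <- binom.test(nWS, nWS + nSW, p = 0.5)
  out <- list(nWS = nWS, nSW = nSW, pHat = nWS / (nWS + nSW),
              ciLow = bt$conf.int[1], ciHigh = bt$conf.int[2],
              c = 2 * nWS / (nWS + nSW) - 1, pValue = bt$p.value)
  class(out) <- "TransmissionBias"
  out
}

#' @export
print.TransmissionBias <- function(x, ...) {
  cat(sprintf(paste0("Transmission bias: %d W>S vs %d S>W, p_hat = %.3f ",
                     "(95%% CI %.3f-%.3f), c = %.3f, binomial p = %.4g\n"),
              x$nWS, x$nSW, x$pHat, x$ciLow, x$ciHigh, x$c, x$pValue))
  invisible(x)
}
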