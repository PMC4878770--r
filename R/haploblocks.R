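# Haploblock construction, error pruning and crossover calling.

#' Group phased sites into haploblocks
#'
#' Maximal runs of identical grandparent-of-origin labels along each
#' (offspring, side, chromosome) become blocks.
#'
#' @param phased data.frame from [phaseOffspring()] (chrom, pos, offspring,
#'   side, label), sorted by position within chromosome.
#' @return data.frame of blocks: offspring, side, chrom, start, end (first /
#'   last informative-site positions, 1-based), label, nSites.
#' @export
buildHaploblocks <- function(phased) {
  if (nrow(phased) == 0)
    return(data.frame(offspring = character(), side = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), label = integer(),
                      nSites = integer()))
  key <- paste(phased$offspring, phased$side, phased$chrom, sep = "\r")
  out <- lapply(split(seq_len(nrow(phased)), key), function(i) {
    p <- phased[i, ]
    if (is.unsorted(p$pos)) stop("phased sites must be sorted by position")
    r <- rle(p$label)
    endIdx <- cumsum(r$lengths)
    startIdx <- endIdx - r$lengths + 1L
    data.frame(offspring = p$offspring[1], side = p$side[1],
               chrom = p$chrom[1], start = p$pos[startIdx],
               end = p$pos[endIdx], label = r$values,
               nSites = r$lengths)
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$offspring, res$side, res$chrom, res$start), ]
}

# Prune one group (single offspring/side/chromosome) to its fixed point:
# repeatedly remove the leftmost interior block that is shorter than
# minSites and whose two implied label switches fall within maxSwitchWindow.
# A switch is localized between two markers; its expected position is the
# marker-interval midpoint, so the switch distance for a block is measured
# midpoint-to-midpoint (for a single-site block: half the flanking marker
# gap). Same-label flanks merge after each removal.
pruneGroup <- function(b, minSites, maxSwitchWindow) {
  removed <- b[0, ]
  repeat {
    k <- nrow(b)
    if (k < 3) break
    interior <- 2:(k - 1)
    m1 <- (b$end[interior - 1L] + b$start[interior]) / 2
    m2 <- (b$end[interior] + b$start[interior + 1L]) / 2
    viol <- interior[b$nSites[interior] < minSites &
                       (m2 - m1) < maxSwitchWindow]
    if (length(viol) == 0) break
    i <- viol[1]
    removed <- rbind(removed, b[i, ])
    if (b$label[i - 1] == b$label[i + 1]) {
      b$end[i - 1] <- b$end[i + 1]
      b$nSites[i - 1] <- b$nSites[i - 1] + b$nSites[i + 1]
      b <- b[-c(i, i + 1), ]
    } else {
      b <- b[-i, ]
    }
    rownames(b) <- NULL
  }
  list(blocks = b, removed = removed)
}

#' Prune error-like short haploblocks
#'
#' Under the assumption of at most one recombination event per Mb, an
#' interior block that would imply two label switches within
#' \code{maxSwitchWindow} and that contains fewer than \code{minSites}
#' sites is treated as a phasing/genotyping artifact and removed; flanking
#' same-label blocks then merge, and the rule is re-applied until a fixed
#' point. Each switch is localized between two informative markers; the
#' distance between the block's two switches is measured between the
#' expected switch positions (marker-interval midpoints). Removed
#' single-site blocks are emitted as non-crossover candidates; removed
#' multi-site blocks are logged as suspects.
#'
#' @param blocks data.frame from [buildHaploblocks()].
#' @param minSites minimum sites for such a block to survive (default 3).
#' @param maxSwitchWindow bp window of the one-event-per-Mb rule
#'   (default 1e6).
#' @param phased optional phased-site data.frame; when given, candidates
#'   carry the transmitted allele (\code{focalAllele}) needed for
#'   weak/strong direction classification.
#' @return list with \code{blocks} (pruned), \code{ncoCandidates}
#'   (offspring, side, chrom, pos, label, surroundLabel[, focalAllele]) and
#'   \code{suspects} (removed multi-site blocks).
#' @export
pruneBlocks <- function(blocks, minSites = 3, maxSwitchWindow = 1e6,
                        phased = NULL) {
  if (minSites < 1) stop("minSites must be >= 1")
  empty <- blocks[0, ]
  if (nrow(blocks) == 0)
    return(list(blocks = blocks,
                ncoCandidates = data.frame(offspring = character(),
                                           side = character(),
                                           chrom = character(),
                                           pos = numeric(),
                                           label = integer(),
                                           surroundLabel = integer()),
                suspects = empty))
  key <- paste(blocks$offspring, blocks$side, blocks$chrom, sep = "\r")
  keep <- list(); cand <- list(); susp <- list()
  for (g in split(seq_len(nrow(blocks)), key)) {
    pr <- pruneGroup(blocks[g, ], minSites, maxSwitchWindow)
    keep[[length(keep) + 1L]] <- pr$blocks
    if (nrow(pr$removed) > 0) {
      single <- pr$removed$nSites == 1L
      if (any(single)) {
        r <- pr$removed[single, ]
        cand[[length(cand) + 1L]] <- data.frame(
          offspring = r$offspring, side = r$side, chrom = r$chrom,
          pos = r$start, label = r$label,
          surroundLabel = 3L - r$label)
      }
      if (any(!single)) susp[[length(susp) + 1L]] <- pr$removed[!single, ]
    }
  }
  blocksOut <- do.call(rbind, c(keep, make.row.names = FALSE))
  blocksOut <- blocksOut[order(blocksOut$offspring, blocksOut$side,
                               blocksOut$chrom, blocksOut$start), ]
  rownames(blocksOut) <- NULL
  candOut <- if (length(cand))
    do.call(rbind, c(cand, make.row.names = FALSE))
  else data.frame(offspring = character(), side = character(),
                  chrom = character(), pos = numeric(), label = integer(),
                  surroundLabel = integer())
  if (!is.null(phased) && nrow(candOut) > 0) {
    mi <- match(paste(candOut$offspring, candOut$side, candOut$chrom,
                      candOut$pos),
                paste(phased$offspring, phased$side, phased$chrom,
                      phased$pos))
    candOut$focalAllele <- phased$focalAllele[mi]
  }
  list(blocks = blocksOut, ncoCandidates = candOut,
       suspects = if (length(susp))
         do.call(rbind, c(susp, make.row.names = FALSE)) else empty)
}

#' Call crossover events from pruned haploblocks
#'
#' Each pair of adjacent blocks with different labels yields one crossover,
#' localized to the half-open interval (last site of the left block, first
#' site of the right block] in 1-based bp. Interval length (= resolution)
#' is right - left. Intervals overlapping assembly gaps are flagged and
#' excluded from the gap-free median.
#'
#' @param blocks pruned block data.frame ([pruneBlocks()]).
#' @param gaps assembly-gap GRanges (optional).
#' @param cutoffs resolution class cutoffs in bp (default 5 kb / 10 kb).
#' @return list with \code{events}, a GRanges spanning (left, right] with
#'   mcols offspring, side, left, right, length, overlapsGap, class; and
#'   \code{summary}: event count, median resolution with and without
#'   gap-overlapping intervals, and fractions below each cutoff.
#' @export
callCrossovers <- function(blocks, gaps = NULL, cutoffs = c(5000, 10000)) {
  ev <- list()
  if (nrow(blocks) > 0) {
    key <- paste(blocks$offspring, blocks$side, blocks$chrom, sep = "\r")
    for (g in split(seq_len(nrow(blocks)), key)) {
      b <- blocks[g, ]
      if (nrow(b) < 2) next
      i <- seq_len(nrow(b) - 1L)
      diffLab <- b$label[i] != b$label[i + 1L]
      if (!any(diffLab)) next
      i <- i[diffLab]
      ev[[length(ev) + 1L]] <- data.frame(
        offspring = b$offspring[1], side = b$side[1], chrom = b$chrom[1],
        left = b$end[i], right = b$start[i + 1L])
    }
  }
  if (length(ev) == 0) {
    events <- GRanges()
    mcols(events) <- DataFrame(offspring = character(), side = character(),
                               left = numeric(), right = numeric(),
                               length = numeric(), overlapsGap = logical(),
                               class = character())
    return(list(events = events,
                summary = list(n = 0L, medianResolution = NA_real_,
                               medianResolutionNoGap = NA_real_,
                               fracBelow = setNames(rep(NA_real_,
                                                        length(cutoffs)),
                                                    paste0("<", cutoffs)))))
  }
  d <- do.call(rbind, c(ev, make.row.names = FALSE))
  d$length <- d$right - d$left
  stopifnot(all(d$length > 0))
  events <- GRanges(d$chrom, IRanges(d$left + 1, d$right))
  ovl <- if (!is.null(gaps) && length(gaps) > 0)
    countOverlaps(events, gaps) > 0 else rep(FALSE, nrow(d))
  cls <- rep(paste0(">=", cutoffs[length(cutoffs)]), nrow(d))
  for (ci in rev(seq_along(cutoffs)))
    cls[d$length < cutoffs[ci]] <- paste0("<", cutoffs[ci])
  mcols(events) <- DataFrame(offspring = d$offspring, side = d$side,
                             left = d$left, right = d$right,
                             length = d$length, overlapsGap = ovl,
                             class = cls)
  list(events = events,
       summary = list(
         n = length(events),
         medianResolution = stats::median(d$length),
         medianResolutionNoGap = if (all(ovl)) NA_real_
           else stats::median(d$length[!ovl]),
         fracBelow = setNames(vapply(cutoffs,
                                     function(co) mean(d$length < co), 0),
                              paste0("<", cutoffs))))
}

#' Crossover event midpoints as a point GRanges
#'
#' Convenience for the downstream point statistics (hot-spot tests, distance
#' profiles, interference): represents each CO event by its interval
#' midpoint, keeping offspring/side metadata and a meiosis identifier.
#'
#' @param events GRanges from [callCrossovers()].
#' @return GRanges of width-1 midpoints with mcols offspring, side, meiosis.
#' @export
crossoverMidpoints <- function(events) {
  if (length(events) == 0) {
    g <- GRanges()
    mcols(g) <- DataFrame(offspring = character(), side = character(),
                          meiosis = character())
    return(g)
  }
  mid <- floor((mcols(events)$left + mcols(events)$right) / 2)
  g <- GRanges(seqnames(events), IRanges(mid, mid))
  mcols(g) <- DataFrame(offspring = mcols(events)$offspring,
                        side = mcols(events)$side,
                        meiosis = paste(mcols(events)$offspring,
                                        mcols(events)$side, sep = ":"))
  GenomeInfoDb::seqlevels(g) <- GenomeInfoDb::seqlevels(events)
  suppressWarnings(GenomeInfoDb::seqlengths(g) <-
                     GenomeInfoDb::seqlengths(events))
  g
}
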