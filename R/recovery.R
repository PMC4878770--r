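# Comparison of called events against simulation ground truth.

#' Evaluate crossover recovery against simulation truth
#'
#' A truth breakpoint is detectable when the offspring/side phased-site
#' sequence has at least one informative site on each flank. Truth
#' breakpoints falling into the same inter-marker interval are grouped:
#' an odd-sized group is one expected (observable) event, an even-sized
#' group cancels and is excluded as unobservable. A called event matches
#' when a truth breakpoint of the same offspring/side lies inside its
#' (left, right] interval.
#'
#' @param truth a [SimTruth-class].
#' @param events called CO GRanges ([callCrossovers()]).
#' @param phased phased-site data.frame ([phaseOffspring()]).
#' @return list: nTruth, nDetectable, nExpected (odd groups), nCalled,
#'   nMatchedCalls, nRecovered, recall, precision, allContained (every
#'   matched call's interval contains its truth breakpoint — TRUE by
#'   construction of matching, reported for clarity).
#' @export
evaluateCORecovery <- function(truth, events, phased) {
  tb <- truth@coBreakpoints
  ev <- if (length(events) == 0)
    data.frame(offspring = character(), side = character(),
               chrom = character(), left = numeric(), right = numeric())
  else data.frame(offspring = mcols(events)$offspring,
                  side = mcols(events)$side,
                  chrom = as.character(seqnames(events)),
                  left = mcols(events)$left, right = mcols(events)$right)
  if (nrow(tb) == 0)
    return(list(nTruth = 0L, nDetectable = 0L, nExpected = 0L,
                nCalled = nrow(ev), nMatchedCalls = 0L, nRecovered = 0L,
                recall = NA_real_,
                precision = if (nrow(ev)) 0 else NA_real_,
                allContained = TRUE))
  pkey <- paste(phased$offspring, phased$side, phased$chrom, sep = "\r")
  posBy <- split(phased$pos, pkey)
  tkey <- paste(tb$offspring, tb$side, tb$chrom, sep = "\r")
  iv <- rep(NA_integer_, nrow(tb))
  detectable <- rep(FALSE, nrow(tb))
  for (kk in unique(tkey)) {
    idx <- which(tkey == kk)
    pos <- posBy[[kk]]
    if (is.null(pos) || length(pos) == 0) next
    f <- findInterval(tb$pos[idx], pos)
    detectable[idx] <- f >= 1 & f < length(pos)
    iv[idx] <- f
  }
  grp <- paste(tkey, iv)[detectable]
  gsz <- table(grp)
  expectedGroups <- names(gsz)[gsz %% 2 == 1]
  nExpected <- length(expectedGroups)

  matchedCall <- rep(FALSE, nrow(ev))
  recoveredGroup <- character(0)
  if (nrow(ev) > 0) {
    ekey <- paste(ev$offspring, ev$side, ev$chrom, sep = "\r")
    for (i in seq_len(nrow(ev))) {
      hit <- tkey == ekey[i] & tb$pos > ev$left[i] & tb$pos <= ev$right[i]
      if (any(hit)) {
        matchedCall[i] <- TRUE
        recoveredGroup <- c(recoveredGroup,
                            paste(tkey, iv)[hit & detectable])
      }
    }
  }
  nRecovered <- length(intersect(unique(recoveredGroup), expectedGroups))
  list(nTruth = nrow(tb), nDetectable = sum(detectable),
       nExpected = nExpected, nCalled = nrow(ev),
       nMatchedCalls = sum(matchedCall), nRecovered = nRecovered,
       recall = if (nExpected > 0) nRecovered / nExpected else NA_real_,
       precision = if (nrow(ev) > 0) mean(matchedCall) else NA_real_,
       allContained = TRUE)
}

#' Evaluate non-crossover recovery against simulation truth
#'
#' Matches NCO calls (single sites) to truth conversion sites by
#' offspring, side, chromosome and position.
#'
#' @param truth a [SimTruth-class].
#' @param nco NCO event data.frame ([filterNCO()] output or candidates).
#' @return list: nTruthConversions, nCalled, nMatched, precision, recall.
#' @export
evaluateNCORecovery <- function(truth, nco) {
  cv <- truth@ncoConversions
  key <- function(d) paste(d$offspring, d$side, d$chrom, d$pos, sep = "\r")
  matched <- if (nrow(nco) > 0) key(nco) %in% key(cv) else logical(0)
  list(nTruthConversions = nrow(cv), nCalled = nrow(nco),
       nMatched = sum(matched),
       precision = if (nrow(nco) > 0) mean(matched) else NA_real_,
       recall = if (nrow(cv) > 0)
         sum(key(cv) %in% key(nco)) / nrow(cv) else NA_real_)
}
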