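#' @importFrom stats rbinom rpois rgamma rgeom runif setNames
NULL

## ------------------------------------------------------------------------
## Founder haplotypes
## ------------------------------------------------------------------------

#' Founder haplotype set
#'
#' Segregating sites and phased founder haplotypes produced by
#' [simulateFounders()]. Haplotype matrices have one row per site and two
#' columns (allele codes 0/1); for females on the Z the second column is the
#' W chromosome and is \code{NA} outside the PAR.
#'
#' @slot layout the [GenomeLayout-class] used.
#' @slot sites named list (per chromosome) of data.frames with \code{pos},
#'   \code{ref}, \code{alt}.
#' @slot haplotypes named list (per founder id) of named lists (per
#'   chromosome) of site-by-2 integer matrices.
#' @export
setClass("FounderHaplotypes",
  representation(layout = "GenomeLayout", sites = "list",
                 haplotypes = "list"))

#' @rdname FounderHaplotypes-class
#' @param object a \code{FounderHaplotypes}.
#' @export
setMethod("show", "FounderHaplotypes", function(object) {
  ns <- vapply(object@sites, nrow, 0L)
  cat("FounderHaplotypes:", length(object@haplotypes), "founders,",
      sum(ns), "segregating sites on", length(ns), "chromosome(s)\n")
})

#' @rdname FounderHaplotypes-class
#' @param x a \code{FounderHaplotypes}.
#' @export
founderSites <- function(x) x@sites

#' @rdname FounderHaplotypes-class
#' @export
founderHaplotypes <- function(x) x@haplotypes

#' Simulate founder haplotypes
#'
#' Places segregating biallelic SNPs along each chromosome (Poisson site
#' counts at the layout's density, uniform positions) and assigns random
#' alleles to the four founders' haplotypes. Reference and alternative bases
#' are drawn uniformly from distinct A/C/G/T pairs, so both weak:strong
#' (A/T vs G/C) and weak:weak / strong:strong site types occur.
#'
#' @param layout a [GenomeLayout-class]; requires density x length >= 1 for
#'   every chromosome.
#' @param seed integer seed; identical seeds give identical site lists and
#'   alleles.
#' @param pedigree pedigree table; the P generation defines the founders.
#' @return A [FounderHaplotypes-class] object.
#' @export
simulateFounders <- function(layout, seed = NULL,
                             pedigree = flycatcherPedigree()) {
  checkPedigree(pedigree)
  ch <- layout@chromosomes
  if (layout@snpDensity <= 0 || any(layout@snpDensity * ch$length < 1))
    stop("snpDensity x length must be >= 1 for every chromosome")
  founders <- pedigree[pedigree$generation == "P", ]
  withSeed(seed, {
    bases <- c("A", "C", "G", "T")
    sites <- list()
    for (i in seq_len(nrow(ch))) {
      n <- rpois(1, layout@snpDensity * ch$length[i])
      n <- max(n, 1L)
      pos <- sort(sample.int(ch$length[i], n))
      ref <- sample(bases, n, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
      sites[[ch$chrom[i]]] <- data.frame(pos = pos, ref = ref, alt = alt,
                                         row.names = NULL)
    }
    haps <- list()
    for (j in seq_len(nrow(founders))) {
      hl <- list()
      for (i in seq_len(nrow(ch))) {
        n <- nrow(sites[[ch$chrom[i]]])
        m <- matrix(rbinom(2L * n, 1L, 0.5), n, 2)
        if (ch$isZ[i] && founders$sex[j] == "F") {
          # column 2 is the W chromosome: alleles exist only in the PAR
          inPar <- if (!is.na(ch$parStart[i]))
            sites[[ch$chrom[i]]]$pos >= ch$parStart[i] &
              sites[[ch$chrom[i]]]$pos <= ch$parEnd[i] else rep(FALSE, n)
          m[!inPar, 2] <- NA_integer_
        }
        hl[[ch$chrom[i]]] <- m
      }
      haps[[founders$id[j]]] <- hl
    }
    new("FounderHaplotypes", layout = layout, sites = sites,
        haplotypes = haps)
  })
}

## ------------------------------------------------------------------------
## Crossover placement: stationary gamma-renewal process
## ------------------------------------------------------------------------

# CO positions on (0, L] from a stationary gamma-renewal process with shape
# nu and intensity lambda (events per bp). Stationarity is achieved by
# starting the process 10 mean spacings before the origin. With nu = 1 this
# is a homogeneous Poisson process. If obligate, rejection-resample until at
# least one event falls on the chromosome.
sampleRenewalCOs <- function(L, lambda, shape, obligate = FALSE) {
  if (lambda <= 0 || L <= 0) return(numeric(0))
  mu <- 1 / lambda
  burnin <- 10 * mu
  draw <- function() {
    tot <- 0; t0 <- -burnin; out <- numeric(0)
    expn <- ceiling((L + burnin) * lambda) + 10L
    repeat {
      n <- expn + ceiling(4 * sqrt(expn))
      gaps <- rgamma(n, shape = shape, rate = shape * lambda)
      t <- t0 + cumsum(gaps)
      out <- c(out, t)
      if (t[length(t)] > L) break
      t0 <- t[length(t)]
    }
    out[out > 0 & out <= L]
  }
  repeat {
    ev <- draw()
    if (!obligate || length(ev) > 0) return(ev)
  }
}

## ------------------------------------------------------------------------
## Single meiosis
## ------------------------------------------------------------------------

#' Simulate one meiosis
#'
#' Generates one transmitted gamete from a parent's haplotype pair, together
#' with the ground-truth crossover breakpoints and non-crossover conversion
#' tracts of that meiosis. Female meiosis on the Z places crossovers (and
#' conversion tracts) only inside the PAR, at the model's PAR rate; the
#' transmitted product is the Z- or W-carrying chromatid as requested.
#'
#' @param haplotypes named list (per chromosome) of site-by-2 allele
#'   matrices, e.g. one element of [founderHaplotypes()].
#' @param sex parent sex, "F" or "M".
#' @param model a [MeiosisModel-class].
#' @param layout the [GenomeLayout-class] (chromosome set must match).
#' @param sites named list of site tables (pos/ref/alt), as in
#'   [founderSites()].
#' @param seed optional integer seed.
#' @param zProduct for female meiosis on the Z: transmit the Z-carrying
#'   ("Z", for sons) or W-carrying ("W", for daughters) product.
#' @return list with \code{gamete} (per-chromosome allele vectors),
#'   \code{co} (data.frame chrom/pos), \code{ncoTracts} (chrom/start/end) and
#'   \code{conversions} (chrom/pos/fromAllele/toAllele/direction).
#' @export
simulateMeiosis <- function(haplotypes, sex, model, layout, sites,
                            seed = NULL, zProduct = c("Z", "W")) {
  if (!sex %in% c("F", "M")) stop("unknown sex label: ", sex)
  zProduct <- match.arg(zProduct)
  ch <- layout@chromosomes
  if (!all(ch$chrom %in% names(haplotypes)))
    stop("parent haplotypes must cover all layout chromosomes")
  withSeed(seed, {
    gam <- list()
    coL <- list(); trL <- list(); cvL <- list()
    for (i in seq_len(nrow(ch))) {
      cname <- ch$chrom[i]
      st <- sites[[cname]]
      hp <- haplotypes[[cname]]
      femZ <- ch$isZ[i] && sex == "F"
      if (femZ) {
        hasPar <- !is.na(ch$parStart[i])
        regStart <- if (hasPar) ch$parStart[i] else NA
        regEnd <- if (hasPar) ch$parEnd[i] else NA
        regLen <- if (hasPar) regEnd - regStart + 1 else 0
        rate <- model@rateParFemale
        co <- if (regLen > 0)
          regStart - 1 + sampleRenewalCOs(regLen, rate / 1e8,
                                          model@interferenceShape,
                                          obligate = FALSE)
        else numeric(0)
        # product identity fixed outside the PAR: column 1 = Z, 2 = W.
        baseCol <- if (zProduct == "Z") 1L else 2L
        nSwAfter <- length(co) - findInterval(st$pos, co)
        hapIdx <- ((baseCol - 1L) + nSwAfter %% 2L) %% 2L + 1L
      } else {
        rate <- if (ch$isZ[i]) model@rateMale
                else if (sex == "F") model@rateFemale else model@rateMale
        co <- sampleRenewalCOs(ch$length[i], rate / 1e8,
                               model@interferenceShape,
                               obligate = model@obligateCO)
        startCol <- sample(1:2, 1)
        hapIdx <- ((startCol - 1L) + findInterval(st$pos, co) %% 2L) %% 2L + 1L
      }
      allele <- hp[cbind(seq_len(nrow(st)), hapIdx)]

      ## NCO tracts within the pairing region
      if (femZ) {
        pairStart <- if (!is.na(ch$parStart[i])) ch$parStart[i] else NA
        pairEnd <- if (!is.na(ch$parEnd[i])) ch$parEnd[i] else NA
      } else {
        pairStart <- 1; pairEnd <- ch$length[i]
      }
      tr <- data.frame(start = numeric(0), end = numeric(0))
      cv <- data.frame(pos = numeric(0), fromAllele = character(0),
                       toAllele = character(0), direction = character(0))
      if (!is.na(pairStart) && model@ncoRatePerMb > 0) {
        pairLen <- pairEnd - pairStart + 1
        nT <- rpois(1, model@ncoRatePerMb * pairLen / 1e6)
        if (nT > 0) {
          s <- pairStart - 1 + ceiling(runif(nT) * pairLen)
          len <- rgeom(nT, 1 / model@tractLengthMean) + 1L
          e <- pmin(s + len - 1, pairEnd)
          # keep tracts clear of this meiosis's CO breakpoints (1 bp margin)
          keep <- vapply(seq_len(nT), function(k)
            !any(co >= s[k] - 1 & co <= e[k] + 1), TRUE)
          s <- s[keep]; e <- e[keep]
          if (length(s) > 0) {
            tr <- data.frame(start = s, end = e)
            inTract <- rep(FALSE, nrow(st))
            for (k in seq_along(s))
              inTract <- inTract | (st$pos >= s[k] & st$pos <= e[k])
            idx <- which(inTract & !is.na(hp[, 1]) & !is.na(hp[, 2]) &
                           hp[, 1] != hp[, 2])
            if (length(idx) > 0) {
              b0 <- st$ref[idx]; b1 <- st$alt[idx]  # base of allele 0 / 1
              ws <- (isStrong(b0) & isWeak(b1)) | (isWeak(b0) & isStrong(b1))
              # transmitted allele code at each heterozygous tract site
              pStrong <- (1 + model@gbgcC) / 2
              strongAllele <- ifelse(isStrong(b1), 1L, 0L)
              u <- runif(length(idx))
              transWS <- ifelse(u < pStrong, strongAllele, 1L - strongAllele)
              transNeutral <- ifelse(u < 0.5, 0L, 1L)
              trans <- ifelse(ws, transWS, transNeutral)
              bg <- allele[idx]
              conv <- !is.na(bg) & trans != bg
              if (any(conv)) {
                ci <- idx[conv]
                fromB <- ifelse(bg[conv] == 0L, st$ref[ci], st$alt[ci])
                toB <- ifelse(trans[conv] == 0L, st$ref[ci], st$alt[ci])
                cv <- data.frame(pos = st$pos[ci], fromAllele = fromB,
                                 toAllele = toB,
                                 direction = classifyDirection(toB, fromB))
                allele[ci] <- trans[conv]
              }
            }
          }
        }
      }
      gam[[cname]] <- allele
      if (length(co) > 0) coL[[cname]] <- data.frame(chrom = cname, pos = co)
      if (nrow(tr) > 0) trL[[cname]] <- data.frame(chrom = cname, tr)
      if (nrow(cv) > 0) cvL[[cname]] <- data.frame(chrom = cname, cv)
    }
    list(gamete = gam,
         co = if (length(coL)) do.call(rbind, c(coL, make.row.names = FALSE))
              else data.frame(chrom = character(), pos = numeric()),
         ncoTracts = if (length(trL))
           do.call(rbind, c(trL, make.row.names = FALSE))
           else data.frame(chrom = character(), start = numeric(),
                           end = numeric()),
         conversions = if (length(cvL))
           do.call(rbind, c(cvL, make.row.names = FALSE))
           else data.frame(chrom = character(), pos = numeric(),
                           fromAllele = character(), toAllele = character(),
                           direction = character()))
  })
}

## ------------------------------------------------------------------------
## Whole-pedigree simulation
## ------------------------------------------------------------------------

#' Simulate a full three-generation pedigree with ground truth
#'
#' Simulates founder haplotypes, founder-to-F1 meioses (whose crossovers are
#' invisible to grandparent-of-origin phasing and are not part of the
#' observable truth), and the ten observable F1-to-F2 meioses, then emits
#' genotypes under an error model. Sex-chromosome inheritance follows the ZW
#' system: sons receive the mother's Z-carrying product, the daughter the
#' W-carrying product, and females are haploid on the non-PAR Z.
#'
#' @param layout a [GenomeLayout-class].
#' @param model a [MeiosisModel-class].
#' @param error an [ErrorModel-class]; use [cleanErrorModel()] for
#'   deterministic error-free output.
#' @param seed integer seed; identical seeds give byte-identical genotypes
#'   and truth tables.
#' @param pedigree pedigree table, default [flycatcherPedigree()].
#' @return list with \code{genotypes} ([PedigreeGenotypes-class]),
#'   \code{truth} ([SimTruth-class]) and \code{founders}
#'   ([FounderHaplotypes-class]).
#' @examples
#' sim <- simulatePedigree(defaultGenomeLayout(), seed = 1,
#'                         error = cleanErrorModel())
#' sim$genotypes
#' sim$truth
#' @export
simulatePedigree <- function(layout, model = MeiosisModel(),
                             error = ErrorModel(), seed = NULL,
                             pedigree = flycatcherPedigree()) {
  checkPedigree(pedigree)
  withSeed(seed, {
    fh <- simulateFounders(layout, seed = NULL, pedigree = pedigree)
    sites <- fh@sites
    ch <- layout@chromosomes

    haps <- fh@haplotypes  # will grow to cover all 11 individuals
    f1 <- pedigree[pedigree$generation == "F1", ]
    for (j in seq_len(nrow(f1))) {
      fa <- f1$father[j]; mo <- f1$mother[j]
      isFemale <- f1$sex[j] == "F"
      gp <- simulateMeiosis(haps[[fa]], "M", model, layout, sites)
      gm <- simulateMeiosis(haps[[mo]], "F", model, layout, sites,
                            zProduct = if (isFemale) "W" else "Z")
      haps[[f1$id[j]]] <- setNames(lapply(ch$chrom, function(cn)
        cbind(gp$gamete[[cn]], gm$gamete[[cn]])), ch$chrom)
    }

    f2 <- pedigree[pedigree$generation == "F2", ]
    coL <- list(); trL <- list(); cvL <- list()
    for (j in seq_len(nrow(f2))) {
      fa <- f2$father[j]; mo <- f2$mother[j]
      isFemale <- f2$sex[j] == "F"
      gp <- simulateMeiosis(haps[[fa]], "M", model, layout, sites)
      gm <- simulateMeiosis(haps[[mo]], "F", model, layout, sites,
                            zProduct = if (isFemale) "W" else "Z")
      haps[[f2$id[j]]] <- setNames(lapply(ch$chrom, function(cn)
        cbind(gp$gamete[[cn]], gm$gamete[[cn]])), ch$chrom)
      for (side in c("paternal", "maternal")) {
        g <- if (side == "paternal") gp else gm
        if (nrow(g$co))
          coL[[length(coL) + 1L]] <- data.frame(offspring = f2$id[j],
                                                side = side, g$co)
        if (nrow(g$ncoTracts))
          trL[[length(trL) + 1L]] <- data.frame(offspring = f2$id[j],
                                                side = side, g$ncoTracts)
        if (nrow(g$conversions))
          cvL[[length(cvL) + 1L]] <- data.frame(offspring = f2$id[j],
                                                side = side, g$conversions)
      }
    }
    truth <- emptyTruth()
    if (length(coL)) truth@coBreakpoints <-
      do.call(rbind, c(coL, make.row.names = FALSE))
    if (length(trL)) truth@ncoTracts <-
      do.call(rbind, c(trL, make.row.names = FALSE))
    if (length(cvL)) truth@ncoConversions <-
      do.call(rbind, c(cvL, make.row.names = FALSE))

    em <- emitGenotypes(haps, sites, layout, pedigree, error)
    truth@artifacts <- em$artifacts
    list(genotypes = em$genotypes, truth = truth, founders = fh)
  })
}

# Assemble the site-by-individual assay matrices and inject error channels.
emitGenotypes <- function(haps, sites, layout, pedigree, error) {
  ch <- layout@chromosomes
  ids <- pedigree$id
  k <- length(ids)
  perChrom <- vapply(ch$chrom, function(cn) nrow(sites[[cn]]), 0L)
  n <- sum(perChrom)
  A1 <- matrix(NA_integer_, n, k); A2 <- matrix(NA_integer_, n, k)
  off <- 0L
  grl <- list()
  for (i in seq_len(nrow(ch))) {
    cn <- ch$chrom[i]
    idx <- off + seq_len(perChrom[i])
    for (j in seq_len(k)) {
      m <- haps[[ids[j]]][[cn]]
      A1[idx, j] <- m[, 1]
      A2[idx, j] <- m[, 2]
    }
    st <- sites[[cn]]
    grl[[i]] <- GRanges(cn, IRanges(st$pos, st$pos), REF = st$ref,
                        ALT = st$alt)
    off <- off + perChrom[i]
  }
  gr <- suppressWarnings(do.call(c, grl))
  GenomeInfoDb::seqlengths(gr) <- setNames(ch$length, ch$chrom)

  clean <- isCleanErrorModel(error)
  artifacts <- data.frame(chrom = character(), pos = numeric())
  chromOf <- rep(ch$chrom, perChrom)
  isZrow <- rep(ch$isZ, perChrom)

  if (!clean && error@wContamRate > 0) {
    cand <- which(!isZrow)
    sel <- cand[runif(length(cand)) < error@wContamRate]
    if (length(sel) > 0) {
      fem <- pedigree$sex == "F"
      A1[sel, ] <- 0L
      A2[sel, fem] <- 1L
      A2[sel, !fem] <- 0L
      artifacts <- data.frame(chrom = chromOf[sel], pos = start(gr)[sel])
    }
  }
  if (!clean && error@genotypeErrorRate > 0) {
    err <- which(matrix(runif(n * k), n, k) < error@genotypeErrorRate &
                   !is.na(A1))
    if (length(err) > 0) {
      hap <- is.na(A2[err])
      gsum <- A1[err] + ifelse(hap, 0L, A2[err])
      # haploid: flip; diploid: one of the two other genotype classes
      newg <- ifelse(hap, 1L - A1[err],
                     (gsum + sample(1:2, length(err), replace = TRUE)) %% 3L)
      A1[err] <- ifelse(hap, newg, ifelse(newg >= 1L, ifelse(newg == 2L, 1L,
                                                             0L), 0L))
      A2[err] <- ifelse(hap, NA_integer_, ifelse(newg >= 1L, 1L, 0L))
    }
  }
  if (!clean && error@missingRate > 0) {
    mis <- matrix(runif(n * k), n, k) < error@missingRate
    A1[mis] <- NA_integer_; A2[mis] <- NA_integer_
  }
  if (clean) {
    DP <- matrix(as.integer(round(error@depthMean)), n, k)
    GQ <- matrix(99L, n, k)
    ad <- genotypeToAD(A1, A2, DP)
    ADREF <- ad$ADREF; ADALT <- ad$ADALT
  } else {
    DP <- matrix(rpois(n * k, error@depthMean), n, k)
    GQ <- matrix(sample(40:99, n * k, replace = TRUE), n, k)
    if (error@gqFloorFraction > 0) {
      lo <- matrix(runif(n * k), n, k) < error@gqFloorFraction
      GQ[lo] <- sample(10:29, sum(lo), replace = TRUE)
    }
    ADREF <- matrix(0L, n, k); ADALT <- matrix(0L, n, k)
    het <- isHet(A1, A2)
    ADALT[het] <- rbinom(sum(het), DP[het], 0.5)
    ADREF[het] <- DP[het] - ADALT[het]
    homr <- !is.na(A1) & A1 == 0L & (is.na(A2) | A2 == 0L)
    homa <- !is.na(A1) & A1 == 1L & (is.na(A2) | A2 == 1L)
    ADREF[homr] <- DP[homr]
    ADALT[homa] <- DP[homa]
  }
  pg <- PedigreeGenotypes(gr, pedigree, A1, A2, DP = DP, GQ = GQ,
                          ADREF = ADREF, ADALT = ADALT)
  metadata(pg)$layout <- layout
  list(genotypes = pg, artifacts = artifacts)
}

## ------------------------------------------------------------------------
## CO-only simulation (for interference / hot-spot nulls)
## ------------------------------------------------------------------------

#' Simulate crossover truth only
#'
#' Draws CO positions for a set of meioses without simulating sites or
#' genotypes — orders of magnitude faster than [simulatePedigree()] and
#' sufficient for interference and placement-null studies.
#'
#' @param layout a [GenomeLayout-class].
#' @param model a [MeiosisModel-class].
#' @param nFemale,nMale number of female / male meioses.
#' @param seed optional integer seed.
#' @return data.frame with \code{meiosis}, \code{sex}, \code{chrom},
#'   \code{pos}.
#' @export
simulateCOTruth <- function(layout, model = MeiosisModel(), nFemale = 5,
                            nMale = 5, seed = NULL) {
  ch <- layout@chromosomes
  withSeed(seed, {
    out <- list()
    sexes <- c(rep("F", nFemale), rep("M", nMale))
    for (m in seq_along(sexes)) {
      sx <- sexes[m]
      for (i in seq_len(nrow(ch))) {
        if (ch$isZ[i] && sx == "F") {
          if (is.na(ch$parStart[i])) next
          L <- ch$parEnd[i] - ch$parStart[i] + 1
          co <- ch$parStart[i] - 1 +
            sampleRenewalCOs(L, model@rateParFemale / 1e8,
                             model@interferenceShape, FALSE)
        } else {
          rate <- if (sx == "F" && !ch$isZ[i]) model@rateFemale
                  else model@rateMale
          co <- sampleRenewalCOs(ch$length[i], rate / 1e8,
                                 model@interferenceShape, model@obligateCO)
        }
        if (length(co) > 0)
          out[[length(out) + 1L]] <- data.frame(
            meiosis = sprintf("m%02d", m), sex = sx, chrom = ch$chrom[i],
            pos = co)
      }
    }
    if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
    else data.frame(meiosis = character(), sex = character(),
                    chrom = character(), pos = numeric())
  })
}
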