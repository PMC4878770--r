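suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(SummarizedExperiment)
  library(S4Vectors)
})

# Cache expensive shared simulations across test files.
.simCache <- new.env(parent = emptyenv())

cleanSim <- function(seed = 1) {
  key <- paste0("clean", seed)
  if (is.null(.simCache[[key]]))
    .simCache[[key]] <- simulatePedigree(defaultGenomeLayout(), seed = seed,
                                         error = cleanErrorModel())
  .simCache[[key]]
}

# Full detection chain on a simulation; error model selectable.
runChain <- function(sim, meanCoverage = 42, minSites = 3) {
  zs <- applyZSemantics(sim$genotypes)
  fl <- filterSites(zs$genotypes, meanCoverage = meanCoverage)
  ph <- phaseOffspring(fl$genotypes)
  pr <- pruneBlocks(buildHaploblocks(ph), minSites = minSites, phased = ph)
  co <- callCrossovers(pr$blocks)
  list(filtered = fl, phased = ph, pruned = pr, co = co)
}

# Toy genotype container: `gts` is a data.frame with columns chrom, pos,
# ref, alt and one character column per pedigree individual holding
# genotype strings ("0/0", "0/1", "1/1", "0", "1" or NA).
makePG <- function(gts, pedigree = flycatcherPedigree(), ...) {
  parse <- function(s, i) {
    if (is.na(s)) return(NA_integer_)
    a <- strsplit(s, "/")[[1]]
    if (i > length(a)) NA_integer_ else as.integer(a[i])
  }
  ids <- pedigree$id
  A1 <- sapply(ids, function(id) vapply(gts[[id]], parse, 0L, i = 1L))
  A2 <- sapply(ids, function(id) vapply(gts[[id]], parse, 0L, i = 2L))
  if (nrow(gts) == 1) { A1 <- rbind(A1); A2 <- rbind(A2) }
  gr <- GRanges(gts$chrom, IRanges(gts$pos, gts$pos),
                REF = gts$ref, ALT = gts$alt)
  PedigreeGenotypes(gr, pedigree, A1, A2, ...)
}

# A fully Mendelian-consistent autosomal site where the paternal side is
# informative (pgf 0/0, pgm 1/1, father 0/1) and the maternal side is not.
baseSite <- function(chrom = "chr1", pos = 1000, ref = "A", alt = "G",
                     off = c("0/1", "0/1", "0/1", "0/1", "0/1")) {
  d <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                  pgf = "0/0", pgm = "1/1", mgf = "0/0", mgm = "0/0",
                  father = "0/1", mother = "0/0",
                  stringsAsFactors = FALSE)
  for (i in 1:5) d[[paste0("off", i)]] <- off[i]
  d
}

# Independent (naive, per-site) reimplementation of the haploblock pruning
# rule, used as an oracle: operates on a site-label vector, recomputes runs
# from scratch each iteration, removes the leftmost violating interior run.
prunedLabelsOracle <- function(pos, labels, minSites = 3, win = 1e6) {
  keepPos <- pos; keepLab <- labels
  repeat {
    if (length(keepLab) == 0) break
    runs <- list(); cur <- 1
    for (i in seq_along(keepLab)[-1]) {
      if (keepLab[i] != keepLab[i - 1]) { runs[[length(runs) + 1]] <- cur:(i - 1); cur <- i }
    }
    runs[[length(runs) + 1]] <- cur:length(keepLab)
    if (length(runs) < 3) break
    removed <- FALSE
    for (ri in 2:(length(runs) - 1)) {
      idx <- runs[[ri]]
      nxt <- runs[[ri + 1]][1]; prv <- runs[[ri - 1]][length(runs[[ri - 1]])]
      mid1 <- (keepPos[prv] + keepPos[idx[1]]) / 2
      mid2 <- (keepPos[idx[length(idx)]] + keepPos[nxt]) / 2
      if (length(idx) < minSites && (mid2 - mid1) < win) {
        keepPos <- keepPos[-idx]; keepLab <- keepLab[-idx]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  list(pos = keepPos, labels = keepLab)
}

# Brute-force coefficient of coincidence on one chromosome: explicit loops
# over window pairs and meioses.
cocOracle <- function(pos, meiosis, chromLen, nMeioses, window = 1e6) {
  meio <- sort(unique(meiosis))
  nW <- ceiling(chromLen / window)
  has <- matrix(FALSE, nMeioses, nW)
  for (i in seq_along(pos)) {
    w <- min(floor((pos[i] - 1) / window) + 1, nW)
    has[match(meiosis[i], meio), w] <- TRUE
  }
  out <- list()
  for (a in 1:(nW - 1)) for (b in (a + 1):nW) {
    d <- b - a
    obs <- 0
    for (m in 1:nMeioses) if (m <= length(meio) && has[m, a] && has[m, b])
      obs <- obs + 1
    pA <- sum(has[, a]) / nMeioses; pB <- sum(has[, b]) / nMeioses
    k <- as.character(d)
    prev <- if (is.null(out[[k]])) c(0, 0) else out[[k]]
    out[[k]] <- prev + c(obs, pA * pB * nMeioses)
  }
  ks <- sort(as.integer(names(out)))
  data.frame(sepMb = ks * window / 1e6,
             observed = sapply(as.character(ks), function(k) out[[k]][1]),
             expected = sapply(as.character(ks), function(k) out[[k]][2]))
}
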