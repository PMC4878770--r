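# Synthetic gene annotation and mask generation for desk-scale runs.

#' Simulate a simple gene annotation
#'
#' Places non-overlapping multi-exon genes with random strands along each
#' chromosome — enough structure (promoter, first exon/intron, other
#' exons/introns, intergenic) to exercise the feature-association
#' statistics on synthetic data. Not a model of real gene architecture.
#'
#' @param layout a [GenomeLayout-class].
#' @param genesPerMb expected gene density (default 0.5 per Mb).
#' @param seed optional integer seed.
#' @return GRangesList of exons grouped by transcript, strand set.
#' @export
simulateGeneAnnotation <- function(layout, genesPerMb = 0.5, seed = NULL) {
  ch <- layout@chromosomes
  withSeed(seed, {
    txs <- list()
    for (i in seq_len(nrow(ch))) {
      nG <- rpois(1, genesPerMb * ch$length[i] / 1e6)
      if (nG == 0) next
      cursor <- 1
      for (g in seq_len(nG)) {
        gapLen <- ceiling(runif(1, 5e3, ch$length[i] / max(nG, 1)))
        startG <- cursor + gapLen
        nEx <- sample(3:8, 1)
        exLen <- sample(150:300, nEx, replace = TRUE)
        inLen <- sample(500:3000, nEx - 1, replace = TRUE)
        starts <- startG + cumsum(c(0, exLen[-nEx] + inLen))
        ends <- starts + exLen - 1
        if (ends[nEx] > ch$length[i]) break
        strand <- sample(c("+", "-"), 1)
        txs[[sprintf("%s_g%03d", ch$chrom[i], g)]] <-
          GRanges(ch$chrom[i], IRanges(starts, ends), strand = strand)
        cursor <- ends[nEx]
      }
    }
    GenomicRanges::GRangesList(txs)
  })
}

#' Simulate mask and region BED-style range sets
#'
#' Draws a set of non-adjacent intervals covering approximately
#' \code{coverFraction} of the genome — usable as repeat/gap masks,
#' CpG-island stand-ins, or differentiation-island region sets in
#' synthetic analyses.
#'
#' @param layout a [GenomeLayout-class].
#' @param coverFraction fraction of the genome to cover.
#' @param meanLength mean interval length, bp.
#' @param seed optional integer seed.
#' @return GRanges of merged intervals.
#' @export
simulateRegions <- function(layout, coverFraction = 0.07,
                            meanLength = 50e3, seed = NULL) {
  ch <- layout@chromosomes
  withSeed(seed, {
    chrom <- character(0); st <- numeric(0); en <- numeric(0)
    for (i in seq_len(nrow(ch))) {
      n <- max(1L, round(coverFraction * ch$length[i] / meanLength))
      s <- sort(sample.int(ch$length[i], n))
      len <- pmax(1, round(stats::rexp(n, 1 / meanLength)))
      chrom <- c(chrom, rep(ch$chrom[i], n))
      st <- c(st, s); en <- c(en, pmin(s + len - 1, ch$length[i]))
    }
    reduce(GRanges(chrom, IRanges(st, en)))
  })
}
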