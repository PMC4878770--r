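# Internal helpers shared across modules.

# Deterministic allele depths consistent with a called genotype: hets get an
# even split of DP, homozygotes/haploids put all reads on the called allele.
genotypeToAD <- function(A1, A2, DP) {
  n <- nrow(A1); k <- ncol(A1)
  ADREF <- matrix(0L, n, k); ADALT <- matrix(0L, n, k)
  het <- !is.na(A1) & !is.na(A2) & A1 != A2
  homr <- !is.na(A1) & A1 == 0L & (is.na(A2) | A2 == 0L)
  homa <- !is.na(A1) & A1 == 1L & (is.na(A2) | A2 == 1L)
  ADREF[het] <- DP[het] %/% 2L
  ADALT[het] <- DP[het] - ADREF[het]
  ADREF[homr] <- DP[homr]
  ADALT[homa] <- DP[homa]
  list(ADREF = ADREF, ADALT = ADALT)
}

# TRUE where the call is heterozygous (haploid and missing are FALSE).
isHet <- function(A1, A2) !is.na(A1) & !is.na(A2) & A1 != A2

# TRUE where individual carries allele `al` (haploid counts its one allele).
hasAllele <- function(A1, A2, al) {
  (!is.na(A1) & A1 == al) | (!is.na(A2) & A2 == al)
}

# Sub-seed derivation: spread a user seed into independent stage seeds while
# staying below .Machine$integer.max.
deriveSeed <- function(seed, tag) {
  (as.numeric(seed) * 48271 + sum(utf8ToInt(tag)) * 7919) %% 2147483629 + 1
}

withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                            envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(expr)
}

# Weak (A/T) / strong (G/C) classification of a base.
isStrong <- function(base) base %in% c("G", "C")
isWeak <- function(base) base %in% c("A", "T")
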