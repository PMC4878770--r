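# VCF 4.2 and truth-table input/output.

#' Write a PedigreeGenotypes container as a multi-sample VCF
#'
#' Emits one VCF 4.2 record per site with FORMAT GT:DP:GQ:AD (AD =
#' ref,alt reads). Haploid calls (females on the non-PAR Z) are written
#' with single-allele GT. Site flags are carried in INFO
#' (TRANCHE90/TRANCHE999) and FILTER is PASS.
#'
#' @param x a [PedigreeGenotypes-class].
#' @param path output path (plain text; use .vcf).
#' @return invisibly, the path.
#' @export
writePedigreeVCF <- function(x, path) {
  gr <- rowRanges(x)
  m <- mcols(gr)
  ids <- colnames(x)
  con <- file(path, "w")
  on.exit(close(con))
  sl <- GenomeInfoDb::seqlengths(gr)
  writeLines(c("##fileformat=VCFv4.2",
               "##source=pedrecomb-simulator",
               if (length(sl) && !all(is.na(sl)))
                 sprintf("##contig=<ID=%s,length=%d>", names(sl), sl),
               "##INFO=<ID=TRANCHE90,Number=0,Type=Flag,Description=\"Passes 90% tranche\">",
               "##INFO=<ID=TRANCHE999,Number=0,Type=Flag,Description=\"Passes 99.9% tranche\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids), collapse = "\t")),
             con)
  A1 <- assay(x, "A1"); A2 <- assay(x, "A2")
  DP <- assay(x, "DP"); GQ <- assay(x, "GQ")
  ADR <- assay(x, "ADREF"); ADA <- assay(x, "ADALT")
  gt <- matrix("./.", nrow(x), ncol(x))
  dip <- !is.na(A1) & !is.na(A2)
  gt[dip] <- paste0(A1[dip], "/", A2[dip])
  hap <- !is.na(A1) & is.na(A2)
  gt[hap] <- as.character(A1[hap])
  cell <- matrix(paste0(gt, ":", DP, ":", GQ, ":", ADR, ",", ADA),
                 nrow(x), ncol(x))
  info <- paste0(ifelse(m$tranche90, "TRANCHE90;", ""),
                 ifelse(m$tranche999, "TRANCHE999", ""))
  info[info == ""] <- "."
  info <- sub(";$", "", info)
  lines <- paste(as.character(seqnames(gr)), start(gr), ".", m$REF, m$ALT,
                 ".", "PASS", info, "GT:DP:GQ:AD",
                 apply(cell, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a multi-sample VCF into a PedigreeGenotypes container
#'
#' Reads GT/DP/GQ/AD via \code{VariantAnnotation::readVcf}. Multi-allelic
#' records are kept but flagged (\code{multiallelic}) for removal by
#' [filterSites()]. Tranche flags are taken from INFO TRANCHE90/TRANCHE999
#' when present, else assumed passing.
#'
#' @param path VCF path.
#' @param pedigree pedigree table whose ids must match the VCF samples.
#' @return a [PedigreeGenotypes-class].
#' @export
readPedigreeVCF <- function(path, pedigree = flycatcherPedigree()) {
  if (!file.exists(path)) stop("no such VCF file: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  if (!all(pedigree$id %in% colnames(vcf)))
    stop("VCF is missing pedigree sample(s): ",
         paste(setdiff(pedigree$id, colnames(vcf)), collapse = ", "))
  vcf <- vcf[, pedigree$id]
  gr <- granges(SummarizedExperiment::rowRanges(vcf))
  names(gr) <- NULL
  ref <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  nAlt <- lengths(altL)
  alt <- rep(NA_character_, length(gr))
  alt[nAlt >= 1] <- as.character(unlist(altL)[cumsum(nAlt)[nAlt >= 1] -
                                                nAlt[nAlt >= 1] + 1L])
  info <- VariantAnnotation::info(vcf)
  getFlag <- function(nm) if (nm %in% names(info)) info[[nm]]
                          else rep(TRUE, length(gr))
  mcols(gr) <- DataFrame(REF = ref, ALT = alt,
                         inRepeat = FALSE, inGap = FALSE, nearIndel = FALSE,
                         tranche90 = getFlag("TRANCHE90"),
                         tranche999 = getFlag("TRANCHE999"),
                         multiallelic = nAlt > 1)
  g <- VariantAnnotation::geno(vcf)
  gt <- g$GT
  uq <- unique(as.vector(gt))
  parse1 <- function(s, which) {
    a <- strsplit(s, "[/|]")[[1]]
    if (which > length(a)) return(NA_integer_)
    suppressWarnings(as.integer(a[which]))
  }
  lut1 <- vapply(uq, parse1, 0L, which = 1L)
  lut2 <- vapply(uq, parse1, 0L, which = 2L)
  A1 <- matrix(lut1[match(gt, uq)], nrow(gt), ncol(gt))
  A2 <- matrix(lut2[match(gt, uq)], nrow(gt), ncol(gt))
  asMat <- function(a, default) {
    if (is.null(a)) matrix(default, length(gr), ncol(gt))
    else { storage.mode(a) <- "integer"; a }
  }
  DP <- asMat(g$DP, NA_integer_); GQ <- asMat(g$GQ, NA_integer_)
  ad <- g$AD
  n <- length(gr); k <- ncol(gt)
  ADREF <- matrix(0L, n, k); ADALT <- matrix(0L, n, k)
  ADOTH <- matrix(0L, n, k)
  if (!is.null(ad)) {
    if (is.list(ad)) {
      adr <- vapply(ad, function(v) if (length(v) >= 1) v[1] else NA_integer_,
                    0L)
      ada <- vapply(ad, function(v) if (length(v) >= 2) v[2] else 0L, 0L)
      ado <- vapply(ad, function(v) if (length(v) >= 3)
        sum(v[-(1:2)], na.rm = TRUE) else 0L, 0L)
      ADREF <- matrix(adr, n, k); ADALT <- matrix(ada, n, k)
      ADOTH <- matrix(as.integer(ado), n, k)
    } else if (length(dim(ad)) == 3) {
      ADREF <- matrix(as.integer(ad[, , 1]), n, k)
      ADALT <- matrix(as.integer(ad[, , 2]), n, k)
      if (dim(ad)[3] > 2)
        ADOTH <- matrix(as.integer(apply(ad[, , -(1:2), drop = FALSE],
                                         c(1, 2), sum, na.rm = TRUE)), n, k)
    }
  }
  ADREF[is.na(ADREF)] <- 0L; ADALT[is.na(ADALT)] <- 0L
  PedigreeGenotypes(gr, pedigree, A1, A2, DP = DP, GQ = GQ,
                    ADREF = ADREF, ADALT = ADALT, ADOTH = ADOTH)
}

#' Write simulation truth tables as TSV
#'
#' @param truth a [SimTruth-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
writeTruthTables <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(d, f) {
    p <- file.path(dir, f)
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  invisible(c(w(truth@coBreakpoints, "co_breakpoints.tsv"),
              w(truth@ncoTracts, "nco_tracts.tsv"),
              w(truth@ncoConversions, "nco_conversions.tsv"),
              w(truth@artifacts, "artifact_sites.tsv")))
}
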