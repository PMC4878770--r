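# Bundled reference tables from the collared flycatcher pedigree study.

#' Published per-chromosome recombination map table
#'
#' The per-chromosome recombination distances (cM, sex-average from 10
#' meioses; the Z row is a male map length), rates (cM/Mb) and external
#' sex-average linkage map lengths (cM) for the collared flycatcher
#' pedigree. Useful as a worked example for [correlateWithLinkage()] and
#' the map arithmetic, and used by the acceptance script.
#'
#' @return data.frame: chrom, distanceCM, rateCMperMb, linkageCM.
#' @examples
#' tab <- flycatcherMapTable()
#' sum(tab$distanceCM[tab$chrom != "Z"])   # autosomal total, cM
#' correlateWithLinkage(tab)
#' @export
flycatcherMapTable <- function() {
  utils::read.delim(system.file("extdata", "flycatcher_map_table.tsv",
                                package = "pedrecomb"),
                    colClasses = c("character", "numeric", "numeric",
                                   "numeric"))
}

#' Published pedigree event counts
#'
#' Headline crossover / non-crossover counts and rates of the flycatcher
#' pedigree study (119 maternal and 186 paternal autosomal crossovers over
#' 5 meioses each, 2 maternal PAR events, 229 weak:strong non-crossover
#' sites with 59\% strong transmission, ...), as a named list.
#'
#' @return named list of numeric values.
#' @export
flycatcherEventCounts <- function() {
  d <- utils::read.delim(system.file("extdata",
                                     "flycatcher_event_counts.tsv",
                                     package = "pedrecomb"))
  stats::setNames(as.list(as.numeric(d$value)), d$key)
}
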