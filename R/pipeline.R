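# End-to-end orchestration: simulate (or read) -> filter -> phase ->
# detect CO -> detect NCO -> statistics, with a single validated config.

#' Default pipeline configuration
#'
#' All thresholds default to the published constants: DP in [15, 2x mean
#' autosomal coverage], GQ >= 30, haploblock pruning with min 3 sites under
#' the one-event-per-Mb rule, resolution classes at 5/10 kb, NCO filters
#' (10 bp indel pad, >3 SNPs/30 bp, >2 deviating sites/5 kb, 25% allele
#' balance), 2 kb promoters, 100 kb hot-spot pairing, 1 Mb coincidence
#' windows. The config is a plain list and can be stored as YAML
#' ([readRunConfig()]).
#'
#' @param seed integer seed for the whole run.
#' @return config list.
#' @export
defaultRunConfig <- function(seed = 1) {
  list(
    seed = seed,
    input = NULL,                       # NULL = simulate; else list(vcf=...)
    layout = list(snpDensity = 1e-4, chromosomes = NULL),  # NULL = default
    meiosis = list(rateFemale = 2.28, rateMale = 3.56, rateParFemale = 67,
                   obligateCO = FALSE, interferenceShape = 5,
                   ncoRatePerMb = 0.1, tractLengthMean = 500, gbgcC = 0.18),
    error = list(genotypeErrorRate = 1e-3, missingRate = 0.01,
                 depthMean = 42, gqFloorFraction = 0.02, wContamRate = 0),
    thresholds = list(minDP = 15, maxDPFactor = 2, minGQ = 30,
                      minSites = 3, maxSwitchWindow = 1e6,
                      resolutionCutoffs = c(5000, 10000),
                      indelPad = 10, clusterWindow = 30, clusterMax = 3,
                      deviantWindow = 5000, deviantMax = 2,
                      minAlleleFrac = 0.25, promoterBp = 2000,
                      hotspotPairDistance = 1e5, cocWindow = 1e6),
    stats = list(nPerm = 1000, genesPerMb = 0.5),
    outDir = NULL
  )
}

#' Validate a pipeline configuration
#'
#' @param config config list (missing entries filled from
#'   [defaultRunConfig()]).
#' @return the completed config, invisibly; stops with a message on
#'   invalid values.
#' @export
validateRunConfig <- function(config) {
  def <- defaultRunConfig()
  config <- utils::modifyList(def, config)
  th <- config$thresholds
  for (nm in names(def$thresholds))
    if (any(!is.numeric(th[[nm]]) | th[[nm]] <= 0))
      stop("threshold '", nm, "' must be positive")
  er <- config$error
  for (nm in c("genotypeErrorRate", "missingRate", "gqFloorFraction",
               "wContamRate"))
    if (er[[nm]] < 0 || er[[nm]] > 1)
      stop("error rate '", nm, "' must lie in [0, 1]")
  if (!is.null(config$input) && !is.null(config$input$vcf) &&
      !file.exists(config$input$vcf))
    stop("input VCF does not exist: ", config$input$vcf)
  invisible(config)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  validateRunConfig(yaml::read_yaml(path))
}

configLayout <- function(config) {
  if (is.null(config$layout$chromosomes))
    defaultGenomeLayout(snpDensity = config$layout$snpDensity)
  else
    GenomeLayout(do.call(rbind, lapply(config$layout$chromosomes,
                                       as.data.frame)),
                 snpDensity = config$layout$snpDensity)
}

#' Run the full pipeline
#'
#' Stages in order: simulate (or read the configured VCF), Z-semantics +
#' site filtering, phasing, haploblock building/pruning, crossover
#' calling, non-crossover filtering, and the downstream statistics
#' (genetic map with linkage correlation against the model-implied
#' expectations, end-distance profile, coincidence coefficient, hot-spot
#' randomization, feature association on a synthetic annotation, and the
#' transmission-bias test). Identical configs (and seeds) give identical
#' reports.
#'
#' @param config config list ([defaultRunConfig()]); validated first.
#' @return list with \code{report} (nested list of counts and statistics)
#'   and \code{objects} (the intermediate data: genotypes, truth, phased
#'   sites, blocks, events, ...). If \code{config$outDir} is set, event
#'   TSVs and \code{report.json} are written there.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  config <- validateRunConfig(config)
  th <- config$thresholds
  layout <- configLayout(config)
  lens <- chromLengths(layout)
  zc <- layout@chromosomes$chrom[layout@chromosomes$isZ]

  ## stage 1: data
  truth <- NULL
  if (is.null(config$input)) {
    sim <- simulatePedigree(layout,
                            model = do.call(MeiosisModel, config$meiosis),
                            error = do.call(ErrorModel, config$error),
                            seed = config$seed)
    pg <- sim$genotypes
    truth <- sim$truth
  } else {
    pg <- readPedigreeVCF(config$input$vcf)
    metadata(pg)$layout <- layout
  }
  nInput <- nrow(pg)

  ## stage 2: filtering
  zs <- applyZSemantics(pg)
  fl <- filterSites(zs$genotypes, meanCoverage = config$error$depthMean,
                    minDP = th$minDP, maxDPFactor = th$maxDPFactor,
                    minGQ = th$minGQ)

  ## stage 3: phasing
  phased <- phaseOffspring(fl$genotypes)

  ## stage 4: crossovers
  blocks <- buildHaploblocks(phased)
  pruned <- pruneBlocks(blocks, minSites = th$minSites,
                        maxSwitchWindow = th$maxSwitchWindow,
                        phased = phased)
  co <- callCrossovers(pruned$blocks, cutoffs = th$resolutionCutoffs)
  mids <- crossoverMidpoints(co$events)

  ## stage 5: non-crossovers
  nco <- filterNCO(collectCandidates(pruned), fl$genotypes,
                   indelPad = th$indelPad,
                   clusterWindow = th$clusterWindow,
                   clusterMax = th$clusterMax,
                   deviantWindow = th$deviantWindow,
                   deviantMax = th$deviantMax,
                   minAlleleFrac = th$minAlleleFrac)

  ## stage 6: statistics
  nF <- sum(pedigree(pg)$generation == "F2")
  # model-implied expected map lengths as the external linkage column
  expCM <- vapply(seq_along(lens), function(i) {
    cn <- names(lens)[i]
    # Z convention counts paternal events over all meioses, hence rate/2
    if (cn %in% zc) config$meiosis$rateMale * lens[[i]] / 1e6 / 2
    else (config$meiosis$rateFemale + config$meiosis$rateMale) / 2 *
      lens[[i]] / 1e6
  }, 0)
  names(expCM) <- names(lens)
  mapTab <- buildMapTable(mids, lens, nFemale = nF, nMale = nF,
                          zChrom = zc, linkage = expCM)
  rLink <- tryCatch(correlateWithLinkage(mapTab), error = function(e)
    NA_real_)
  endProf <- if (length(mids) > 0)
    endDistanceProfile(mids, lens, sizeClasses = c(10e6, 15e6))
  else NULL
  coc <- coincidenceCoefficient(mids, lens, nMeioses = 2 * nF,
                                window = th$cocWindow)
  hot <- hotspotRandomization(mids, lens,
                              pairDistance = th$hotspotPairDistance,
                              nPerm = config$stats$nPerm,
                              seed = deriveSeed(config$seed, "hotspot"))
  genes <- simulateGeneAnnotation(layout,
                                  genesPerMb = config$stats$genesPerMb,
                                  seed = deriveSeed(config$seed, "genes"))
  feat <- if (length(genes) > 0 && length(co$events) > 0)
    featureAssignment(co$events[mcols(co$events)$length <
                                  th$resolutionCutoffs[1]],
                      genes, lens, promoterBp = th$promoterBp)
  else NULL
  tb <- if (nrow(nco) > 0 && any(nco$direction %in% c("W>S", "S>W")))
    transmissionBias(nco$direction) else NULL

  report <- list(
    config = list(seed = config$seed,
                  simulated = is.null(config$input)),
    counts = list(
      sitesInput = nInput,
      sitesZRemoved = zs$nRemoved,
      filterReport = fl$report,
      sitesSurviving = attr(fl$report, "surviving"),
      informativeSites = nrow(phased),
      haploblocks = nrow(pruned$blocks),
      suspectBlocks = nrow(pruned$suspects),
      coEvents = co$summary$n,
      ncoCandidates = nrow(collectCandidates(pruned)),
      ncoEvents = nrow(nco)),
    crossovers = co$summary,
    map = list(table = mapTab,
               totalCM = sum(mapTab$distanceCM),
               maternalCM = mapDistance(sum(mapTab$nMaternal), nF),
               paternalCM = mapDistance(sum(mapTab$nPaternal), nF),
               linkageR = rLink),
    interference = coc,
    hotspots = list(observed = hot$observed, pValue = hot$pValue),
    endProfile = if (!is.null(endProf)) endProf$test else NULL,
    features = feat,
    transmissionBias = if (!is.null(tb)) unclass(tb) else NULL)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(as.data.frame(mcols(co$events)),
                       file.path(config$outDir, "co_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(nco, file.path(config$outDir, "nco_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(truth)) writeTruthTables(truth, config$outDir)
    writeRunReport(report, file.path(config$outDir, "report.json"))
  }
  list(report = report,
       objects = list(genotypes = pg, truth = truth,
                      filtered = fl$genotypes, phased = phased,
                      blocks = pruned, coEvents = co$events,
                      midpoints = mids, ncoEvents = nco,
                      mapTable = mapTab))
}

#' Write a pipeline report as JSON
#' @param report report list from [runPipeline()].
#' @param path output path.
#' @export
writeRunReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  invisible(path)
}
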