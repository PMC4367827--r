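## Pipeline configuration and the end-to-end driver over synthetic data.
## Every tunable named across the package is a keyed default here; the YAML
## round-trip rejects unknown keys so configs stay honest.

#' Default pipeline configuration
#'
#' All thresholds default to the values the analyses were designed around:
#' 18-mers for discovery/abundance and 12-mers for spacing, q > 20 general /
#' q < 30 initial-exclusion / q = 55 unique-mapping filters, depth >= 10 and
#' >= 90% allele frequency for fixed differences, > 10 bp zero-coverage runs
#' with > 20x on all 10 flanking bases for deletions, 200 bp align-and-extend
#' flanks at a 60% column consensus, 80% identity / 80 bp repeat hits with
#' 1000 bp flanks and 1000 permutations for the association test, and 1.5 kb
#' merge distance for composite transposon elements.
#'
#' @return nested named list (class `"PipelineConfig"`).
#' @export
defaultConfig <- function() {
  structure(list(
    seed = 1L,
    genome = list(length = 3e5, satelliteMonomer = 166L,
                  satelliteCopies = 120L, satelliteArrays = 1L,
                  transposonLength = 1500L, transposonCopies = 12L,
                  fragmentation = 0.4, geneCount = 24L,
                  geneLengthRange = c(1000L, 2500L)),
    sibling = list(rateExon = 0.003, rateIntron = 0.006, rateUtr5 = 0.0036,
                   rateUtr3 = 0.0026, rateNoncoding = 0.007, deletions = 8L,
                   jitterProb = 0.5, jitterMagnitude = 50L),
    reads = list(depth = 40, readLen = 100L, errorRate = 0.002,
                 paired = TRUE, insertMean = 300, insertSd = 30),
    kmer = list(k = 18L, spacingK = 12L, topN = 50000L, minExtension = 50L),
    mapping = list(seedLen = 19L, minQ = 20L, minQInitial = 30L,
                   minQUnique = 55L, gapPad = 150L),
    variants = list(minDepth = 10L, homozygousFreq = 0.9),
    satellite = list(maxMismatch = 1L, tandemFraction = 0.9),
    genomeSize = list(lowCov = 10, highCov = 60, maxAed = 0.2, flank = 100L),
    deletions = list(minLen = 10L, flankLen = 10L, flankMinCov = 20L,
                     maxRawCov = 5),
    association = list(nPerm = 1000L, identity = 0.8, minHit = 80L,
                       flank = 1000L),
    spans = list(mergeDist = 1500L, canonicalLen = 1500L, flank = 1000L)
  ), class = "PipelineConfig")
}

#' Read / write / validate a pipeline configuration
#'
#' YAML round-trip with strict key checking: unknown keys are rejected,
#' missing keys fall back to [defaultConfig()].
#'
#' @param path YAML file path.
#' @param config a configuration list.
#' @return `readConfig`: a validated `"PipelineConfig"`.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  validateConfig(user)
}

#' @rdname readConfig
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname readConfig
#' @export
validateConfig <- function(config) {
  def <- defaultConfig()
  bad <- setdiff(names(config), names(def))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (sec in names(config)) {
    if (is.list(def[[sec]])) {
      badk <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(badk))
        stop("unknown config key(s) in '", sec, "': ",
             paste(badk, collapse = ", "))
      def[[sec]][names(config[[sec]])] <- config[[sec]]
    } else {
      def[[sec]] <- config[[sec]]
    }
  }
  def
}

#' Run the full pipeline on synthetic data
#'
#' Simulate -> count k-mers -> discover repeats -> satellite statistics ->
#' genome size (both estimators) -> fixed differences by region ->
#' deletions (+ repeat association) -> transposon spans.  A single global
#' seed fans out to per-stage seeds at fixed offsets, so a fixed seed
#' reproduces the report byte-for-byte.
#'
#' @param config a [defaultConfig()]-shaped configuration.
#' @param outDir optional directory for TSV/JSON reports.
#' @param quiet suppress progress messages.
#' @return report list with one entry per stage.
#' @export
runPipeline <- function(config = defaultConfig(), outDir = NULL,
                        quiet = FALSE) {
  config <- validateConfig(config)
  note <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed
  cg <- config$genome

  note("stage 1/8: building genome + sibling")
  gspec <- genomeSpec(
    length = cg$length,
    satellites = list(list(monomer = cg$satelliteMonomer,
                           arrayCopies = cg$satelliteCopies,
                           arrays = cg$satelliteArrays)),
    transposon = list(length = cg$transposonLength,
                      copies = cg$transposonCopies,
                      fragmentation = cg$fragmentation),
    genes = list(count = cg$geneCount, lengthRange = cg$geneLengthRange),
    seed = seed)
  ref <- buildGenome(gspec)
  cs <- config$sibling
  sspec <- siblingSpec(
    rates = c(exon = cs$rateExon, intron = cs$rateIntron,
              utr5 = cs$rateUtr5, utr3 = cs$rateUtr3,
              noncoding = cs$rateNoncoding),
    deletions = cs$deletions,
    jitter = list(prob = cs$jitterProb, magnitude = cs$jitterMagnitude),
    seed = seed + 1L)
  sib <- deriveSibling(ref$genome, ref$truth, sspec)

  note("stage 2/8: simulating reads")
  cr <- config$reads
  reads <- simulateReads(ref$genome, cr$depth, cr$readLen, cr$errorRate,
                         paired = cr$paired, insertMean = cr$insertMean,
                         insertSd = cr$insertSd, seed = seed + 2L)
  sibReads <- simulateReads(sib$genome, cr$depth, cr$readLen, cr$errorRate,
                            paired = cr$paired, insertMean = cr$insertMean,
                            insertSd = cr$insertSd, seed = seed + 3L)

  note("stage 3/8: k-mer counting and k-mer genome size")
  hist <- kmerHistogram(reads, config$kmer$k, "canonical")
  kmerSizeEst <- genomeSizeFromHistogram(hist)

  note("stage 4/8: k-mer extension repeat discovery")
  tab <- countKmers(reads, config$kmer$k, "as-read")
  extLib <- kmerExtend(tab, topN = min(config$kmer$topN, length(tab)),
                       minExtension = config$kmer$minExtension)

  note("stage 5/8: satellite arrangement and abundance")
  monomer <- truthFeatures(ref$truth, "satellite_array")$monomer[1]
  model <- satelliteModel(monomer, readLen = cr$readLen,
                          k = config$kmer$spacingK)
  arrangement <- arrangementProfile(reads, model,
                                    maxMismatch = config$satellite$maxMismatch,
                                    tandemFraction = config$satellite$tandemFraction)
  abundTab <- countKmers(reads, config$kmer$k, "canonical")
  abundance <- estimateAbundance(abundTab, model, cr$depth, cr$readLen)

  note("stage 6/8: transcript-coverage genome size")
  genes <- truthFeatures(ref$truth, "exon")
  geneIds <- unique(genes$id)
  segs <- vapply(geneIds, function(g) {
    rr <- range(GenomicRanges::ranges(truthFeatures(ref$truth)[
      truthFeatures(ref$truth)$id == g]))
    fl <- config$genomeSize$flank
    substr(ref$genome, max(1L, IRanges::start(rr) - fl),
           min(nchar(ref$genome), IRanges::end(rr) + fl))
  }, character(1))
  segdf <- transcriptSegments(setNames(segs, geneIds),
                              flank = config$genomeSize$flank)
  sizeEst <- tryCatch({
    covTab <- coverageFilterCascade(segdf, reads,
                                    lowCov = config$genomeSize$lowCov,
                                    highCov = config$genomeSize$highCov,
                                    maxAed = config$genomeSize$maxAed,
                                    minQInitial = config$mapping$minQInitial,
                                    minQUnique = config$mapping$minQUnique)
    estimateGenomeSize(covTab, totalBases = sum(nchar(reads)))
  }, error = function(e) list(error = conditionMessage(e)))

  note("stage 7/8: sibling fixed differences and deletions")
  aln <- mapReads(sibReads, ref$genome,
                  seedLen = config$mapping$seedLen,
                  gapPad = config$mapping$gapPad)
  aln <- keepPaired(aln)
  pu <- pileupFromAlignments(aln, ref$genome, minQ = config$mapping$minQ)
  puRaw <- pileupFromAlignments(aln, ref$genome, minQ = -1L)
  calls <- callFixedDifferences(pu, ref$genome,
                                minDepth = config$variants$minDepth,
                                homozygousFreq = config$variants$homozygousFreq)
  partition <- partitionByRegion(calls, ref$truth, pu, ref$genome,
                                 minDepth = config$variants$minDepth)
  cd <- config$deletions
  dels <- findDeletions(list(genome = pileupDepth(pu, 1L)),
                        minLen = cd$minLen, flankLen = cd$flankLen,
                        flankMinCov = cd$flankMinCov,
                        rawCoverage = list(genome = pileupDepth(puRaw, 1L)),
                        maxRawCov = cd$maxRawCov)
  assoc <- if (nrow(dels$calls) && length(extLib)) {
    ca <- config$association
    repeatAssociationTest(dels$calls, ref$genome, extLib,
                          nPerm = ca$nPerm, identity = ca$identity,
                          minHit = ca$minHit, flank = ca$flank,
                          seed = seed + 4L)
  } else NULL

  note("stage 8/8: transposon span comparison")
  canonical <- attr(ref$truth, "transposonCanonical")
  spansRes <- if (!is.null(canonical)) {
    fr <- .cpp_find_hits(unname(ref$genome), canonical, 12L, 100L, 0.8,
                         100000L)
    frags <- data.frame(scaffold = "genome", start = fr$rstart,
                        end = fr$rend)
    cp <- config$spans
    me <- mergeElements(frags, mergeDist = cp$mergeDist,
                        canonicalLen = cp$canonicalLen, flank = cp$flank,
                        scaffoldLens = nchar(ref$genome))
    if (nrow(me$elements) >= 2L)
      compareSpans(me$elements, ref$genome, sib$genome, flank = cp$flank,
                   seed = seed + 5L)
    else NULL
  } else NULL

  report <- list(
    config = config,
    truth = list(reference = ref$truth, sibling = sib$truth),
    kmerGenomeSize = kmerSizeEst,
    repeats = list(n = length(extLib), info = repeatInfo(extLib)),
    satellite = list(classification = arrangement$classification,
                     fractionExpected = arrangement$fractionExpected,
                     abundance = unclass(abundance)),
    transcriptGenomeSize = if (inherits(sizeEst, "SizeEstimate"))
      unclass(sizeEst) else sizeEst,
    divergence = list(nCalls = nrow(calls), rates = partition$rates,
                      coding = partition$coding[
                        setdiff(names(partition$coding), "effects")]),
    deletions = list(calls = dels$calls,
                     flank_rejected = dels$flank_rejected,
                     ambiguous_rejected = dels$ambiguous_rejected,
                     association = if (!is.null(assoc))
                       assoc[c("observed", "nullMean", "p")] else NULL),
    spans = if (!is.null(spansRes))
      spansRes[c("meanElement", "meanControl", "p", "excluded")] else NULL)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.table(report$divergence$rates,
                file.path(outDir, "substitution_rates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(report$deletions$calls, file.path(outDir, "deletions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    json <- report
    json$truth <- NULL
    json$repeats$info <- NULL
    jsonlite::write_json(json, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
    writeTruthSet(ref$truth, file.path(outDir, "truth_reference.json"))
    writeTruthSet(sib$truth, file.path(outDir, "truth_sibling.json"))
  }
  report
}
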