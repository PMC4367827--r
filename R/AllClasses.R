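## Central S4 containers.  Analysis results that are plain tables are
## returned as data.frames / lists; the classes below hold the substrates
## that several modules share.

#' KmerTable: exact k-mer counts
#'
#' A k-mer -> count map over `{A,C,G,T}^k` with an explicit strand policy.
#' Under the `"as-read"` policy a k-mer and its reverse complement are
#' distinct keys (required by the strand-directional extension walk and the
#' satellite spacing statistic); under `"canonical"` the two are merged under
#' the lexicographically smaller key (used for genome-size and abundance
#' estimation, where reads are unstranded).
#'
#' @slot k k-mer length.
#' @slot kmers character vector of distinct k-mers (sorted).
#' @slot counts numeric vector of counts (>= 1), parallel to `kmers`.
#' @slot strandPolicy `"as-read"` or `"canonical"`.
#' @export
setClass("KmerTable",
  representation(k = "integer", kmers = "character", counts = "numeric",
                 strandPolicy = "character"))

setValidity("KmerTable", function(object) {
  msg <- NULL
  if (!object@strandPolicy %in% c("as-read", "canonical"))
    msg <- c(msg, "strandPolicy must be 'as-read' or 'canonical'")
  if (length(object@kmers) != length(object@counts))
    msg <- c(msg, "kmers and counts lengths differ")
  if (length(object@counts) && any(object@counts < 1))
    msg <- c(msg, "counts must be >= 1")
  ## key hygiene: spot-check (full scan would dominate on large tables)
  probe <- head(object@kmers, 1000L)
  if (length(probe) && (any(nchar(probe) != object@k) ||
                        any(grepl("[^ACGT]", probe))))
    msg <- c(msg, sprintf("keys must be length-%d strings over ACGT", object@k))
  if (is.null(msg)) TRUE else msg
})

#' @describeIn KmerTable number of distinct k-mers
#' @param x,object a `KmerTable`.
#' @export
setMethod("length", "KmerTable", function(x) length(x@kmers))

#' Accessors for KmerTable
#' @param x a `KmerTable`.
#' @return `kmerSize`: the k-mer length; `kmerCounts`: a named numeric vector
#'   of counts; `strandPolicy`: the strand policy string.
#' @export
kmerSize <- function(x) x@k

#' @rdname kmerSize
#' @export
kmerCounts <- function(x) setNames(x@counts, x@kmers)

#' @rdname kmerSize
#' @export
strandPolicy <- function(x) x@strandPolicy

setMethod("show", "KmerTable", function(object) {
  cat(sprintf("KmerTable: %d distinct %d-mers (%s), %.0f total\n",
              length(object@kmers), object@k, object@strandPolicy,
              sum(object@counts)))
})

#' KmerHistogram: multiplicity spectrum of a k-mer table
#'
#' @slot k k-mer length.
#' @slot multiplicity observed multiplicities (sorted).
#' @slot nKmers number of distinct k-mers at each multiplicity.
#' @slot totalKmers total k-mer instances (`sum(multiplicity * nKmers)`).
#' @slot strandPolicy strand policy the histogram was built under.
#' @export
setClass("KmerHistogram",
  representation(k = "integer", multiplicity = "numeric", nKmers = "numeric",
                 totalKmers = "numeric", strandPolicy = "character"))

setValidity("KmerHistogram", function(object) {
  if (length(object@multiplicity) != length(object@nKmers))
    return("multiplicity and nKmers lengths differ")
  if (length(object@multiplicity) &&
      abs(sum(object@multiplicity * object@nKmers) - object@totalKmers) > 0.5)
    return("totalKmers does not match the spectrum")
  TRUE
})

setMethod("show", "KmerHistogram", function(object) {
  cat(sprintf("KmerHistogram: k=%d (%s), %.0f distinct k-mers, %.0f total\n",
              object@k, object@strandPolicy, sum(object@nKmers),
              object@totalKmers))
})

#' @rdname kmerSize
#' @export
totalKmers <- function(x) x@totalKmers

#' Pileup: per-base allele counts over reference sequences
#'
#' Built from alignments passing a mapping-quality floor.  Depth at a site is
#' the sum of base counts there; a read whose deletion operation spans a site
#' contributes deletion evidence but no base, so the site's depth excludes it.
#'
#' @slot refnames reference sequence names.
#' @slot reflens reference lengths.
#' @slot data per-reference list: `depth`, `counts` (4 x L matrix, rows
#'   A/C/G/T), `del`, `ins`, `ins_len`.
#' @slot minQ the mapping-quality floor used (alignments with `mapq > minQ`
#'   contribute).
#' @export
setClass("Pileup",
  representation(refnames = "character", reflens = "integer", data = "list",
                 minQ = "integer"))

setValidity("Pileup", function(object) {
  if (length(object@refnames) != length(object@data))
    return("one data entry per reference required")
  for (i in seq_along(object@data)) {
    d <- object@data[[i]]
    if (!all(c("depth", "counts", "del", "ins", "ins_len") %in% names(d)))
      return("pileup entries need depth/counts/del/ins/ins_len")
    if (!isTRUE(all.equal(unname(colSums(d$counts)), as.numeric(d$depth))))
      return("depth must equal the column sums of counts")
  }
  TRUE
})

setMethod("show", "Pileup", function(object) {
  cat(sprintf("Pileup over %d reference(s), %d bp total, mapq > %d\n",
              length(object@refnames), sum(object@reflens), object@minQ))
})

#' Pileup accessors
#'
#' @param x a `Pileup`.
#' @param ref reference name or index (default: first).
#' @return `pileupDepth`: integer depth vector; `baseCounts`: 4 x L count
#'   matrix with rows A, C, G, T; `indelEvidence`: data.frame of per-site
#'   deletion/insertion read support.
#' @export
pileupDepth <- function(x, ref = 1L) x@data[[.refIdx(x, ref)]]$depth

#' @rdname pileupDepth
#' @export
baseCounts <- function(x, ref = 1L) {
  m <- x@data[[.refIdx(x, ref)]]$counts
  rownames(m) <- DNA_BASES
  m
}

#' @rdname pileupDepth
#' @export
indelEvidence <- function(x, ref = 1L) {
  d <- x@data[[.refIdx(x, ref)]]
  data.frame(pos = seq_along(d$del) - 1L, del = d$del, ins = d$ins,
             ins_len = d$ins_len)
}

.refIdx <- function(x, ref) {
  if (is.character(ref)) ref <- match(ref, x@refnames)
  if (is.na(ref) || ref < 1L || ref > length(x@refnames))
    stop("unknown reference sequence")
  as.integer(ref)
}

#' TruthSet: exact record of planted features and edits
#'
#' Coordinates are 0-based half-open internally; the `features` GRanges uses
#' the usual 1-based closed convention of GenomicRanges (conversion happens
#' at construction).  Sufficient to score recall and precision of every
#' downstream caller.
#'
#' @slot genomeLength length of the genome the features live on.
#' @slot features GRanges of planted features (`type`, `id`, and for CDS a
#'   `phase` column).
#' @slot editCounts named numeric: realized substitution count per region
#'   class (sibling truth only).
#' @slot deletions GRanges of planted deletions in reference coordinates.
#' @slot jitter data.frame of per-transposon insert-size changes.
#' @export
setClass("TruthSet",
  representation(genomeLength = "numeric", features = "GRanges",
                 editCounts = "numeric", deletions = "GRanges",
                 jitter = "data.frame"))

setValidity("TruthSet", function(object) {
  if (length(object@features) &&
      max(GenomicRanges::end(object@features)) > object@genomeLength)
    return("features extend past the genome end")
  TRUE
})

setMethod("show", "TruthSet", function(object) {
  cat(sprintf("TruthSet: %.0f bp genome, %d features, %d deletions\n",
              object@genomeLength, length(object@features),
              length(object@deletions)))
  if (length(object@editCounts)) {
    cat("  realized substitutions:",
        paste(names(object@editCounts), object@editCounts, sep = "=",
              collapse = ", "), "\n")
  }
})

#' @rdname truthFeatures
#' @export
genomeLength <- function(x) x@genomeLength

#' TruthSet accessors
#' @param x a `TruthSet`.
#' @param type optional feature type filter.
#' @return `truthFeatures`: GRanges; `truthDeletions`: GRanges;
#'   `truthEditCounts`: named numeric; `genomeLength`: numeric.
#' @export
truthFeatures <- function(x, type = NULL) {
  gr <- x@features
  if (!is.null(type)) gr <- gr[gr$type %in% type]
  gr
}

#' @rdname truthFeatures
#' @export
truthDeletions <- function(x) x@deletions

#' @rdname truthFeatures
#' @export
truthEditCounts <- function(x) x@editCounts

#' RepeatLibrary: a curated set of repeat consensus sequences
#'
#' @slot sequences named character vector of consensus sequences.
#' @slot info data.frame with one row per entry: `id`, `class` (LINE / LTR /
#'   DNA transposon / satellite / unclassified), `length`, and, once
#'   finalized, `mapped_fraction` and `mean_nm` support statistics.
#' @export
setClass("RepeatLibrary",
  representation(sequences = "character", info = "data.frame"))

setValidity("RepeatLibrary", function(object) {
  if (length(object@sequences) != nrow(object@info))
    return("info must have one row per sequence")
  if (length(object@sequences) &&
      !identical(names(object@sequences), object@info$id))
    return("sequence names must match info$id")
  TRUE
})

setMethod("show", "RepeatLibrary", function(object) {
  cat(sprintf("RepeatLibrary: %d entries", length(object@sequences)))
  if (length(object@sequences))
    cat(sprintf(", %d-%d bp", min(nchar(object@sequences)),
                max(nchar(object@sequences))))
  cat("\n")
})

#' @describeIn RepeatLibrary number of library entries
#' @param x,object a `RepeatLibrary`.
#' @export
setMethod("length", "RepeatLibrary", function(x) length(x@sequences))

#' RepeatLibrary accessors
#' @param x a `RepeatLibrary`.
#' @return `repeatSequences`: named character vector; `repeatInfo`: the
#'   per-entry data.frame.
#' @export
repeatSequences <- function(x) x@sequences

#' @rdname repeatSequences
#' @export
repeatInfo <- function(x) x@info

#' Construct a RepeatLibrary
#'
#' @param sequences named character vector of consensus sequences.
#' @param class class labels (recycled); classification by homology is out of
#'   scope here, so entries default to `"unclassified"`.
#' @param info optional pre-built info data.frame.
#' @return a `RepeatLibrary`.
#' @export
repeatLibrary <- function(sequences, class = "unclassified", info = NULL) {
  sequences <- vapply(sequences, toupper, character(1))
  if (is.null(names(sequences)) || anyNA(names(sequences)))
    names(sequences) <- sprintf("rep%03d", seq_along(sequences))
  if (is.null(info)) {
    info <- data.frame(id = names(sequences),
                       class = rep_len(class, length(sequences)),
                       length = nchar(sequences),
                       stringsAsFactors = FALSE)
  }
  rownames(info) <- NULL
  new("RepeatLibrary", sequences = sequences, info = info)
}
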