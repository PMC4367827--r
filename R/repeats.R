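## Repeat discovery: the greedy k-mer extension walk over raw-read k-mer
## counts, the automated align-and-extend consensus builder, consensus
## finalization against reads, redundancy culling and species-specific
## variant libraries.

#' Greedy k-mer extension repeat discovery
#'
#' Starting from the most abundant k-mer, the walk repeatedly appends the
#' final base of the highest-count k-mer overlapping the current end by
#' k - 1 bases, first rightwards then leftwards, stopping in a direction
#' when no overlapping k-mer exists in the table or when the chosen k-mer
#' has already been used.  No k-mer is used more than once; seeds already
#' consumed by a previous extension are skipped (but still count toward
#' `topN`).  Only sequences extending beyond `minExtension` bp are retained.
#' Tandem satellite monomers show up as walks of length about monomer + k - 1
#' that stop on re-meeting their own starting k-mer.
#'
#' @param table a [KmerTable] built with the `"as-read"` policy (extension is
#'   strand-directional; canonical merging would corrupt the overlaps).
#' @param topN number of top-count seeds to process before terminating.
#' @param minExtension retain sequences of final length >= k + minExtension.
#' @return a [RepeatLibrary] (class `"unclassified"`) whose info records the
#'   seed k-mer, its count and the stop reasons (`"reused"` when the walk met
#'   an already-used k-mer, `"exhausted"` when no overlap existed).
#' @export
kmerExtend <- function(table, topN = 50000L, minExtension = 50L) {
  stopifnot(is(table, "KmerTable"))
  if (table@strandPolicy != "as-read")
    stop("kmerExtend needs an as-read KmerTable")
  if (topN < 1) stop("topN must be >= 1")
  res <- .cpp_kmer_extend(table@kmers, table@counts, table@k,
                          as.integer(topN),
                          as.integer(table@k + minExtension))
  if (!length(res$sequence)) {
    return(repeatLibrary(character(0)))
  }
  seqs <- as.character(res$sequence)
  names(seqs) <- sprintf("ext%04d", seq_along(seqs))
  lib <- repeatLibrary(seqs)
  lib@info$seed <- as.character(res$seed)
  lib@info$seed_count <- as.numeric(res$seed_count)
  lib@info$stop_right <- as.character(res$stop_right)
  lib@info$stop_left <- as.character(res$stop_left)
  lib
}

#' Lexicographically minimal rotation
#'
#' Tandem-derived circular extensions of a satellite monomer are arbitrary
#' rotations of each other; reporting the minimal rotation makes them
#' comparable.
#'
#' @param x a single sequence.
#' @return the rotation of `x` that is lexicographically smallest.
#' @export
minimalRotation <- function(x) {
  n <- nchar(x)
  if (n <= 1) return(x)
  dd <- paste0(x, x)
  rots <- substring(dd, seq_len(n), seq_len(n) + n - 1L)
  min(rots)
}

#' Best identity between two sequences over all rotations
#'
#' Used to score recovery of a planted satellite monomer, whose phase in an
#' extension product is arbitrary.  Also checks the reverse complement.
#'
#' @param x,y sequences of equal length.
#' @return maximal per-base identity over all rotations/orientations of `x`.
#' @export
rotationIdentity <- function(x, y) {
  n <- nchar(y)
  if (nchar(x) != n) stop("sequences must have equal length")
  yv <- strsplit(y, "")[[1]]
  best <- 0
  for (cand in c(x, revComp(x))) {
    dd <- strsplit(paste0(cand, cand), "")[[1]]
    for (r in 0:(n - 1L)) {
      id <- mean(dd[r + seq_len(n)] == yv)
      if (id > best) best <- id
    }
  }
  best
}

#' Iterative align-and-extend consensus construction
#'
#' Finds all assembly matches of the working consensus at >=`minIdentity`,
#' extracts each matched genomic segment with up to `flank` bp of flanking
#' sequence, stacks the segments in consensus coordinates, and extends the
#' consensus outward column by column wherever at least `consensusThreshold`
#' of the covering segments (and at least `minSupport` of them) agree.
#' Iterates until no further extension.  Segments are stacked positionally
#' (substitution-aware matching): at the scale this package operates on the
#' flanks are indel-free, which makes column stacking equivalent to a full
#' multiple alignment.
#'
#' @param seed starting consensus (>= 50 bp).
#' @param assembly named character vector of assembly scaffolds.
#' @param flank flanking bp extracted beyond each match (default 200).
#' @param consensusThreshold column agreement fraction required (default
#'   0.60).
#' @param minIdentity match identity floor (default 0.80).
#' @param minSupport minimum number of aligned segments; below this the
#'   process stops ("too few aligned genomic segments").
#' @param maxIter safety cap on iterations.
#' @return list with `sequence` (the final consensus), `support` (number of
#'   segments in the last round), `iterations`, and `extended` (bp added).
#' @export
alignAndExtend <- function(seed, assembly, flank = 200L,
                           consensusThreshold = 0.60, minIdentity = 0.80,
                           minSupport = 3L, maxIter = 20L) {
  seed <- toupper(unname(seed[1]))
  if (nchar(seed) < 50) stop("seed must be at least 50 bp")
  assembly <- vapply(assembly, toupper, character(1))
  cons <- seed
  startLen <- nchar(seed)
  iter <- 0L
  support <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > maxIter) break
    hits <- .cpp_find_hits(unname(assembly), cons, 12L,
                           as.integer(max(40L, floor(nchar(cons) * 0.5))),
                           minIdentity, 10000L)
    ## demand matches covering most of the consensus
    hits <- hits[(hits$qend - hits$qstart) >= 0.8 * nchar(cons), , drop = FALSE]
    if (nrow(hits) == 0L) {
      if (iter == 1L) warning("no assembly matches; seed returned unchanged")
      break
    }
    support <- nrow(hits)
    if (support < minSupport) break
    L <- nchar(cons)
    width <- L + 2L * flank
    ## stack segments: column j (1-based) corresponds to consensus
    ## coordinate j - flank - 1 (0-based)
    mat <- matrix(NA_character_, nrow = support, ncol = width)
    for (i in seq_len(support)) {
      h <- hits[i, ]
      rseq <- assembly[[h$rid]]
      if (h$strand == 1L) {
        ## ref position of consensus coordinate 0:
        anchor <- h$rstart - h$qstart
        from <- anchor - flank
        seg <- .safeSub(rseq, from, width)
      } else {
        ## reverse strand: consensus coord 0 maps near rend + qstart
        anchor <- h$rend + h$qstart  # one past coord 0 base, reversed
        from <- anchor - (L + flank)
        seg <- .safeSub(rseq, from, width)
        seg$seq <- revComp(seg$seq)
        seg <- list(seq = seg$seq,
                    padLeft = seg$padRight, padRight = seg$padLeft)
      }
      chars <- strsplit(seg$seq, "")[[1]]
      if (length(chars))
        mat[i, seg$padLeft + seq_along(chars)] <- chars
    }
    colBase <- function(j) {
      col <- mat[, j]
      col <- col[!is.na(col)]
      if (length(col) < minSupport) return(NA_character_)
      tab <- sort(table(col), decreasing = TRUE)
      if (tab[1] / length(col) >= consensusThreshold) names(tab)[1]
      else NA_character_
    }
    leftAdd <- character(0)
    j <- flank
    while (j >= 1L) {
      b <- colBase(j)
      if (is.na(b)) break
      leftAdd <- c(b, leftAdd)
      j <- j - 1L
    }
    rightAdd <- character(0)
    j <- flank + L + 1L
    while (j <= width) {
      b <- colBase(j)
      if (is.na(b)) break
      rightAdd <- c(rightAdd, b)
      j <- j + 1L
    }
    if (!length(leftAdd) && !length(rightAdd)) break
    cons <- paste0(paste(leftAdd, collapse = ""), cons,
                   paste(rightAdd, collapse = ""))
  }
  list(sequence = cons, support = support, iterations = iter,
       extended = nchar(cons) - startLen)
}

## substring with out-of-range padding bookkeeping (0-based from)
.safeSub <- function(seq, from, width) {
  L <- nchar(seq)
  s <- max(0L, from)
  e <- min(L, from + width)
  list(seq = if (e > s) substr(seq, s + 1L, e) else "",
       padLeft = s - from, padRight = (from + width) - e)
}

#' Finalize a repeat library against raw reads
#'
#' Maps the reads to the library, installs the majority base at every
#' covered position, culls entries with more than `identityCull` identity to
#' a longer entry, and reports the mapped-read fraction and mean mismatch
#' count (NM) over alignments passing the mapping-quality floor.
#'
#' @param lib a [RepeatLibrary] or named character vector.
#' @param reads named character vector of reads.
#' @param minQ mapping-quality floor (strict >).
#' @param identityCull pairwise identity above which the shorter entry is
#'   removed (default 0.80).
#' @return a [RepeatLibrary] with updated sequences and info columns
#'   `mapped_fraction` (of all reads, over the whole library) and `mean_nm`.
#' @export
finalizeConsensus <- function(lib, reads, minQ = 20L, identityCull = 0.80) {
  seqs <- if (is(lib, "RepeatLibrary")) repeatSequences(lib) else
    vapply(lib, toupper, character(1))
  if (!length(seqs)) stop("empty library")
  aln <- mapReads(reads, seqs)
  pu <- pileupFromAlignments(aln, seqs, minQ = minQ)
  for (i in seq_along(seqs)) {
    cnt <- baseCounts(pu, i)
    depth <- pileupDepth(pu, i)
    maj <- DNA_BASES[max.col(t(cnt), ties.method = "first")]
    chars <- strsplit(seqs[[i]], "")[[1]]
    upd <- depth > 0 & maj != chars
    if (any(upd)) chars[upd] <- maj[upd]
    seqs[[i]] <- paste(chars, collapse = "")
  }
  ## redundancy culling: keep the longer of any >identityCull pair
  ord <- order(-nchar(seqs), names(seqs))
  keep <- character(0)
  for (id in names(seqs)[ord]) {
    redundant <- FALSE
    for (kid in keep) {
      if (.pairIdentity(seqs[[kid]], seqs[[id]]) > identityCull) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) keep <- c(keep, id)
  }
  keep <- names(seqs)[names(seqs) %in% keep]  # original order
  seqs <- seqs[keep]
  ## support statistics against the culled (non-redundant) library: mapping
  ## against a library still containing duplicates would tie those reads at
  ## q = 0 and understate the mapped fraction
  aln2 <- mapReads(reads, seqs)
  ok <- aln2$mapq > minQ
  mappedFraction <- sum(ok) / length(reads)
  meanNM <- if (any(ok)) mean(aln2$nm[ok]) else NA_real_
  out <- repeatLibrary(seqs)
  out@info$mapped_fraction <- mappedFraction
  out@info$mean_nm <- meanNM
  out
}

## identity of the shorter sequence against the longer via local hits
.pairIdentity <- function(a, b) {
  if (nchar(b) > nchar(a)) { tmp <- a; a <- b; b <- tmp }
  hits <- .cpp_find_hits(a, b, 12L, 30L, 0.5, 10000L)
  if (!nrow(hits)) return(0)
  cov <- IRanges::reduce(IRanges::IRanges(hits$qstart + 1L, hits$qend))
  covered <- sum(IRanges::width(cov))
  idw <- sum((hits$qend - hits$qstart) * hits$identity) /
    sum(hits$qend - hits$qstart)
  (covered / nchar(b)) * idw
}

#' Derive a species-specific variant library
#'
#' Maps a sibling species' reads to the reference repeat library and
#' substitutes every site where the sibling majority allele differs from the
#' library base at a frequency strictly above `freq`; 1 bp deletions
#' passing the same rule are removed likewise.  Entries with zero coverage
#' are left unchanged and flagged.
#'
#' @param lib a [RepeatLibrary] or named character vector.
#' @param siblingReads named character vector of sibling reads.
#' @param minQ mapping-quality floor.
#' @param freq frequency threshold (strict >; a site at exactly 50% is left
#'   unchanged).
#' @return a [RepeatLibrary] with a `species_tag` and `flagged` info column.
#' @export
speciesSpecificVariants <- function(lib, siblingReads, minQ = 20L,
                                    freq = 0.5) {
  seqs <- if (is(lib, "RepeatLibrary")) repeatSequences(lib) else
    vapply(lib, toupper, character(1))
  aln <- mapReads(siblingReads, seqs)
  pu <- pileupFromAlignments(aln, seqs, minQ = minQ)
  flagged <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    depth <- pileupDepth(pu, i)
    if (all(depth == 0)) {
      flagged[i] <- TRUE
      next
    }
    cnt <- baseCounts(pu, i)
    ind <- indelEvidence(pu, i)
    chars <- strsplit(seqs[[i]], "")[[1]]
    maj <- DNA_BASES[max.col(t(cnt), ties.method = "first")]
    majN <- cnt[cbind(match(maj, DNA_BASES), seq_along(chars))]
    subst <- depth > 0 & maj != chars & (majN / depth) > freq
    chars[subst] <- maj[subst]
    delFrac <- ind$del / pmax(1L, depth + ind$del)
    drop <- which(delFrac > freq & ind$del > 0)
    if (length(drop)) chars <- chars[-drop]
    seqs[[i]] <- paste(chars, collapse = "")
  }
  out <- repeatLibrary(seqs)
  out@info$species_tag <- "sibling"
  out@info$flagged <- flagged
  out
}
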