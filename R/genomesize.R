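## Genome-size estimation from the coverage of putative single-copy
## transcript segments, with the full filter cascade: initial q filter, the
## 10x/60x coverage bands, the median-50% rank filter, N-run and annotation
## quality filters, and a final unique-mapping (q = 55) re-estimate using
## per-segment *median* coverage excluding the 100 bp flanks.

#' Build transcript segment records
#'
#' @param seqs named character vector: genomic segments corresponding to
#'   transcripts, including `flank` bp on each side.
#' @param aed per-segment annotation quality score in `[0, 1]` (lower is
#'   better-supported; treated as an input column, e.g. from an annotation
#'   pipeline or a truth set).
#' @param flank flanking bp included on each side (excluded from coverage
#'   summaries).
#' @return data.frame of class `"TranscriptSegments"` with columns `id`,
#'   `seq`, `aed`, `flank`, `n_run` (>= 5 consecutive Ns present).
#' @export
transcriptSegments <- function(seqs, aed = 0, flank = 100L) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("tx%04d", seq_along(seqs))
  df <- data.frame(id = ids, seq = toupper(unname(unlist(seqs))),
                   aed = rep_len(aed, length(seqs)),
                   flank = as.integer(flank),
                   stringsAsFactors = FALSE)
  df$n_run <- grepl("N{5,}", df$seq)
  class(df) <- c("TranscriptSegments", class(df))
  df
}

## per-segment median coverage excluding flanks
.segmentMedians <- function(segments, reads, minQ) {
  seqs <- setNames(segments$seq, segments$id)
  aln <- mapReads(reads, seqs)
  pu <- pileupFromAlignments(aln, seqs, minQ = minQ)
  vapply(seq_len(nrow(segments)), function(i) {
    depth <- pileupDepth(pu, i)
    fl <- segments$flank[i]
    core <- depth[(fl + 1L):(length(depth) - fl)]
    stats::median(core)
  }, numeric(1))
}

#' Coverage filter cascade for single-copy segment selection
#'
#' Reads are mapped to all segments excluding low-quality placements
#' (`mapq < minQInitial`); segments in the low (`< lowCov`) and high
#' (`> highCov`, repeat-dominated) coverage bands are dropped, the median
#' 50% of the remainder ranked by coverage is kept (ties broken by id),
#' segments with runs of five or more Ns or with quality score
#' `aed > maxAed` are removed, and the survivors are re-mapped under the
#' unique-mapping filter (`mapq >= minQUnique`).
#'
#' @param segments a [transcriptSegments()] data.frame.
#' @param reads named character vector of reads.
#' @param lowCov,highCov coverage band cut-offs (defaults 10 and 60).
#' @param maxAed annotation-quality ceiling (default 0.2).
#' @param minQInitial initial mapping-quality exclusion (`q < 30` dropped).
#' @param minQUnique unique-mapping filter for the final estimate (q = 55).
#' @return data.frame with columns `id`, `median_coverage` (final, q-unique,
#'   flanks excluded) for the retained segments; dropped segments and
#'   reasons in `attr(, "dropped")`.
#' @export
coverageFilterCascade <- function(segments, reads, lowCov = 10, highCov = 60,
                                  maxAed = 0.2, minQInitial = 30L,
                                  minQUnique = 55L) {
  med0 <- .segmentMedians(segments, reads, minQ = minQInitial - 1L)
  reason <- rep(NA_character_, nrow(segments))
  reason[med0 < lowCov] <- "low_coverage"
  reason[med0 > highCov] <- "high_coverage"
  ## median 50% by coverage rank among the remaining
  inBand <- which(is.na(reason))
  ord <- inBand[order(med0[inBand], segments$id[inBand])]
  nDrop <- floor(length(ord) / 4)
  if (nDrop > 0) {
    reason[ord[seq_len(nDrop)]] <- "below_median_band"
    reason[ord[(length(ord) - nDrop + 1L):length(ord)]] <- "above_median_band"
  }
  reason[is.na(reason) & segments$n_run] <- "n_run"
  reason[is.na(reason) & segments$aed > maxAed] <- "aed"
  keep <- which(is.na(reason))
  if (length(keep) < 10)
    stop("insufficient single-copy set: only ", length(keep),
         " segments retained")
  retained <- segments[keep, , drop = FALSE]
  med <- .segmentMedians(retained, reads, minQ = minQUnique - 1L)
  out <- data.frame(id = retained$id, median_coverage = med,
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- data.frame(id = segments$id[!is.na(reason)],
                                     reason = reason[!is.na(reason)])
  out
}

#' Genome size from single-copy segment coverage
#'
#' The peak of the per-segment median-coverage distribution (histogram with
#' bin width 1, reported at the bin centre, hence the half-integer
#' resolution) converts total sequenced bases into genome size:
#' size = total bases / peak coverage.
#'
#' @param segmentCoverage a [coverageFilterCascade()] result, or a numeric
#'   vector of per-segment median coverages.
#' @param totalBases total sequenced bases in the read set.
#' @return list of class `"SizeEstimate"`: `peak`, `totalBases`, `size`
#'   (bp), `retained`.
#' @export
estimateGenomeSize <- function(segmentCoverage, totalBases) {
  cov <- if (is.data.frame(segmentCoverage)) segmentCoverage$median_coverage
    else as.numeric(segmentCoverage)
  if (!length(cov)) stop("no retained segments")
  bins <- floor(cov)
  tab <- table(bins)
  top <- which(tab == max(tab))
  if (length(top) > 1)
    stop("no dominant coverage peak; candidates: ",
         paste(names(tab)[top], collapse = ", "))
  peak <- as.numeric(names(tab)[top]) + 0.5
  structure(list(peak = peak, totalBases = totalBases,
                 size = totalBases / peak, retained = length(cov)),
            class = "SizeEstimate")
}

#' @export
print.SizeEstimate <- function(x, ...) {
  cat(sprintf(
    "Genome size estimate: %.1f Mbp (peak coverage %.1f, %.3g bases, %d segments)\n",
    x$size / 1e6, x$peak, x$totalBases, x$retained))
  invisible(x)
}
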