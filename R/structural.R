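## Structural divergence: zero-coverage deletion detection with flank
## filters, the repeat-association permutation test, and the transposon
## insert-span comparison with matched random controls.

#' Detect deletions as zero-coverage intervals with well-covered flanks
#'
#' Maximal zero-coverage runs longer than `minLen` are reported when every
#' one of the `flankLen` bases immediately bordering the run on both sides
#' exceeds `flankMinCov` (minimum, not mean: the strictest reading of
#' requiring high coverage for *all* bordering bases).  Runs touching a
#' scaffold edge lack a full flank and are rejected but counted.  When a
#' raw (quality-unfiltered) coverage track is supplied, intervals that are
#' covered in it are rejected as mappability artifacts rather than
#' deletions: zero q-filtered coverage over a repeat interior reflects
#' mapping ambiguity, not missing sequence.
#'
#' @param coverage named list of per-scaffold integer depth vectors (built
#'   from paired, q > 20, gapped alignments), or a single vector.
#' @param minLen report runs strictly longer than this (default 10 bp).
#' @param flankLen flank width examined on each side (default 10 bp).
#' @param flankMinCov strict lower bound for every flank base (default 20).
#' @param rawCoverage optional matching track built without the mapping
#'   quality filter; intervals with mean raw coverage above `maxRawCov` are
#'   rejected as ambiguity artifacts.
#' @param maxRawCov see `rawCoverage` (default 5).
#' @param noiseFloor isolated bases with coverage at or below this count as
#'   uncovered for run detection (default 2).  A sequencing error at a
#'   read's junction-adjacent base that coincides with the deleted sequence
#'   places that single read one base into a real deletion; such
#'   one-off placements should not split or veto a zero-coverage run.
#'   Flank bases are still held to the full `flankMinCov`.
#' @return list with `calls` (data.frame: scaffold, start, end, length,
#'   left_min, right_min; 0-based half-open, sorted), and the counts
#'   `edge_rejected`, `flank_rejected`, `ambiguous_rejected`.
#' @export
findDeletions <- function(coverage, minLen = 10L, flankLen = 10L,
                          flankMinCov = 20L, rawCoverage = NULL,
                          maxRawCov = 5, noiseFloor = 2L) {
  if (!is.list(coverage)) coverage <- list(scaffold = coverage)
  if (is.null(names(coverage)))
    names(coverage) <- sprintf("scaffold%d", seq_along(coverage))
  calls <- list()
  edge <- flank <- ambig <- 0L
  for (sc in names(coverage)) {
    cov <- coverage[[sc]]
    r <- rle(cov <= noiseFloor)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    zi <- which(r$values & r$lengths > minLen)
    for (j in zi) {
      s <- starts[j]; e <- ends[j]  # 1-based inclusive
      if (s - flankLen < 1L || e + flankLen > length(cov)) {
        edge <- edge + 1L
        next
      }
      lmin <- min(cov[(s - flankLen):(s - 1L)])
      rmin <- min(cov[(e + 1L):(e + flankLen)])
      if (lmin <= flankMinCov || rmin <= flankMinCov) {
        flank <- flank + 1L
        next
      }
      if (!is.null(rawCoverage)) {
        raw <- if (is.list(rawCoverage)) rawCoverage[[sc]] else rawCoverage
        if (mean(raw[s:e]) > maxRawCov) {
          ambig <- ambig + 1L
          next
        }
      }
      calls[[length(calls) + 1L]] <- data.frame(
        scaffold = sc, start = s - 1L, end = e, length = e - s + 1L,
        left_min = lmin, right_min = rmin, stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(scaffold = character(0), start = integer(0), end = integer(0),
               length = integer(0), left_min = integer(0),
               right_min = integer(0))
  calls <- calls[order(calls$scaffold, calls$start), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls, edge_rejected = edge, flank_rejected = flank,
       ambiguous_rejected = ambig)
}

#' Repeat-association permutation test for deletion flanks
#'
#' Are deletions preferentially adjacent to repetitive sequence?  The
#' observed statistic is the fraction of the `flank`-bp segments bordering
#' each deletion that contain a repeat-library hit (>= `identity` over
#' >= `minHit` bp; hits are located once on the assembly, so a flank
#' "contains a repeat" when it overlaps a library occurrence by at least
#' `minHit` bp).  The null distribution re-draws, `nPerm` times, one random
#' genomic position per deletion and extracts the same paired flanks
#' separated by that deletion's length (positions drawn uniformly with
#' replacement, so control windows may overlap); p is one-sided with
#' add-one correction.
#'
#' @param calls deletion calls data.frame (from [findDeletions()]).
#' @param assembly named character vector (single scaffold per name).
#' @param repeatLib a [RepeatLibrary] or named character vector.
#' @param nPerm permutation count (default 1000).
#' @param identity,minHit repeat-hit thresholds (defaults 0.80 / 80 bp).
#' @param flank flank width in bp (default 1000).
#' @param seed optional seed for the permutation draws.
#' @return list: `observed` (fraction of flanks with a hit), `nullMean`,
#'   `p`, `nFlanks`, `truncated` (flanks clipped at scaffold ends).
#' @export
repeatAssociationTest <- function(calls, assembly, repeatLib, nPerm = 1000L,
                                  identity = 0.80, minHit = 80L,
                                  flank = 1000L, seed = NULL) {
  if (nrow(calls) == 0L) stop("nothing to test: no deletion calls")
  if (!is.null(seed)) set.seed(seed)
  seqs <- if (is(repeatLib, "RepeatLibrary")) repeatSequences(repeatLib)
    else repeatLib
  if (!length(seqs)) stop("empty repeat library")
  assembly <- vapply(assembly, toupper, character(1))
  ## occurrences of the library on the assembly (computed once)
  hits <- .cpp_find_hits(unname(assembly), unname(seqs), 12L,
                         as.integer(minHit), identity, 100000L)
  occ <- lapply(seq_along(assembly), function(ri) {
    h <- hits[hits$rid == ri, , drop = FALSE]
    if (!nrow(h)) IRanges::IRanges() else
      IRanges::reduce(IRanges::IRanges(h$rstart + 1L, h$rend))
  })
  names(occ) <- names(assembly)
  scafLen <- nchar(assembly)

  flankRanges <- function(starts, ends, scaffold) {
    L <- scafLen[[scaffold]]
    lf <- cbind(pmax(0L, starts - flank), starts)
    rf <- cbind(ends, pmin(L, ends + flank))
    rbind(lf, rf)
  }
  fracWithHit <- function(fr, scaffold) {
    if (!nrow(fr)) return(NA_real_)
    ir <- IRanges::IRanges(fr[, 1] + 1L, fr[, 2])
    ov <- IRanges::findOverlaps(ir, occ[[scaffold]], minoverlap = minHit)
    mean(seq_len(nrow(fr)) %in% S4Vectors::queryHits(ov))
  }
  ## observed
  byScaf <- split(calls, calls$scaffold)
  obsNum <- 0; obsDen <- 0; trunc <- 0L
  for (sc in names(byScaf)) {
    cc <- byScaf[[sc]]
    fr <- flankRanges(cc$start, cc$end, sc)
    trunc <- trunc + sum((fr[, 2] - fr[, 1]) < flank)
    obsNum <- obsNum + fracWithHit(fr, sc) * nrow(fr)
    obsDen <- obsDen + nrow(fr)
  }
  observed <- obsNum / obsDen
  ## null: per permutation, one independent random placement per deletion,
  ## keeping each pair of flanks separated by that deletion's length
  nullStat <- numeric(nPerm)
  lens <- calls$end - calls$start
  scafOf <- calls$scaffold
  for (b in seq_len(nPerm)) {
    num <- 0
    for (sc in names(byScaf)) {
      sel <- which(scafOf == sc)
      L <- scafLen[[sc]]
      hi <- pmax(1L, L - lens[sel] - 2L * flank)
      s <- flank + floor(runif(length(sel)) * hi)
      fr <- flankRanges(s, s + lens[sel], sc)
      num <- num + fracWithHit(fr, sc) * nrow(fr)
    }
    nullStat[b] <- num / obsDen
  }
  p <- (1 + sum(nullStat >= observed)) / (nPerm + 1)
  list(observed = observed, nullMean = mean(nullStat), p = p,
       nFlanks = obsDen, truncated = trunc, null = nullStat)
}

#' Merge transposon fragment hits into composite elements
#'
#' Fragments within `mergeDist` of each other (the canonical element length)
#' are transitively merged; a merged extent covering at least twice the
#' canonical length is split at its largest internal gap.  Elements whose
#' `flank`-bp flanking segments would run off the scaffold are dropped and
#' counted.
#'
#' @param fragments data.frame: `scaffold`, `start`, `end` (0-based
#'   half-open fragment hits, e.g. from matching a canonical transposon
#'   against the assembly).
#' @param mergeDist merge distance in bp (default 1500).
#' @param canonicalLen canonical element length in bp (default 1500).
#' @param flank flank width that must be available (default 1000).
#' @param scaffoldLens named lengths of the scaffolds.
#' @return list with `elements` (data.frame: element, scaffold, start, end,
#'   span, n_fragments) and `dropped_no_flank`.
#' @export
mergeElements <- function(fragments, mergeDist = 1500L, canonicalLen = 1500L,
                          flank = 1000L, scaffoldLens = NULL) {
  stopifnot(all(c("scaffold", "start", "end") %in% names(fragments)))
  out <- list()
  dropped <- 0L
  splitGroup <- function(st, en) {
    ## st/en sorted fragment intervals of one transitive group
    if (max(en) - min(st) < 2L * canonicalLen || length(st) == 1L)
      return(list(seq_along(st)))
    gaps <- st[-1] - en[-length(en)]
    cut <- which.max(gaps)
    c(splitGroup(st[seq_len(cut)], en[seq_len(cut)]),
      lapply(splitGroup(st[-seq_len(cut)], en[-seq_len(cut)]),
             function(ix) ix + cut))
  }
  ei <- 0L
  for (sc in unique(fragments$scaffold)) {
    f <- fragments[fragments$scaffold == sc, , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    ## transitive grouping by gap <= mergeDist
    grp <- cumsum(c(1L, as.integer(f$start[-1] - cummax(f$end[-nrow(f)]) >
                                   mergeDist)))
    for (g in unique(grp)) {
      sel <- which(grp == g)
      for (ix in splitGroup(f$start[sel], f$end[sel])) {
        rows <- sel[ix]
        s <- min(f$start[rows]); e <- max(f$end[rows])
        if (!is.null(scaffoldLens) &&
            (s - flank < 0L || e + flank > scaffoldLens[[sc]])) {
          dropped <- dropped + 1L
          next
        }
        ei <- ei + 1L
        out[[ei]] <- data.frame(element = sprintf("el%03d", ei),
                                scaffold = sc, start = s, end = e,
                                span = e - s, n_fragments = length(rows),
                                stringsAsFactors = FALSE)
      }
    }
  }
  elements <- if (length(out)) do.call(rbind, out) else
    data.frame(element = character(0), scaffold = character(0),
               start = integer(0), end = integer(0), span = integer(0),
               n_fragments = integer(0))
  list(elements = elements, dropped_no_flank = dropped)
}

## locate a flank sequence in sibling contigs; returns the best hit row, or
## NULL when absent or ambiguous (a second placement nearly as good, e.g. a
## flank lying inside a multi-copy element cannot be located uniquely)
.locateFlank <- function(flankSeq, sibling, minCov = 0.6, minId = 0.85) {
  h <- .cpp_find_hits(unname(sibling), flankSeq, 19L,
                      as.integer(max(60L, floor(nchar(flankSeq) * minCov))),
                      minId, 1000L)
  if (!nrow(h)) return(NULL)
  sc <- (h$qend - h$qstart) * h$identity
  h <- h[order(-sc), , drop = FALSE]
  sc <- sort(sc, decreasing = TRUE)
  if (nrow(h) > 1L && sc[2] >= 0.95 * sc[1] &&
      (h$rid[2] != h$rid[1] || abs(h$rstart[2] - h$rstart[1]) > 50L))
    return(NULL)
  h[1, ]
}

## sibling coordinate of an arbitrary flank offset x (may extrapolate
## beyond the matched part); strand from the hit
.flankCoord <- function(hit, x) {
  if (hit$strand == 1L) hit$rstart + (x - hit$qstart)
  else hit$rend - (x - hit$qstart)
}

#' Compare transposon insert spans between reference and sibling
#'
#' For each merged element, the two `flank`-bp segments bordering it are
#' located in the sibling contigs; where both land on one contig in
#' consistent orientation, the distance between the homologous inner flank
#' edges gives the sibling span, and |sibling span - reference span| the
#' insert-size change.  An equal number of random control pairs with
#' matched insert sizes is measured the same way; a two-tailed Welch t-test
#' compares the two sets of absolute span changes.
#'
#' @param elements [mergeElements()] output data.frame.
#' @param reference named character vector (the scaffolds the elements live
#'   on).
#' @param sibling named character vector of sibling contigs.
#' @param flank flank width (default 1000).
#' @param nControls number of control pairs (default: one per element).
#' @param seed optional seed for control placement.
#' @return list: `spans` (per element: reference span, sibling span,
#'   abs_change), `controls` (same for control pairs), `meanElement`,
#'   `meanControl`, `p` (Welch), `excluded` (elements whose flanks were not
#'   consistently located).
#' @export
compareSpans <- function(elements, reference, sibling, flank = 1000L,
                         nControls = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reference <- vapply(reference, toupper, character(1))
  sibling <- vapply(sibling, toupper, character(1))
  if (is.null(nControls)) nControls <- nrow(elements)
  measure <- function(scaffold, s, e) {
    refseq <- reference[[scaffold]]
    fa <- substr(refseq, s - flank + 1L, s)
    fb <- substr(refseq, e + 1L, e + flank)
    ha <- .locateFlank(fa, sibling)
    hb <- .locateFlank(fb, sibling)
    if (is.null(ha) || is.null(hb)) return(NA_real_)
    if (ha$rid != hb$rid || ha$strand != hb$strand) return(NA_real_)
    innerA <- .flankCoord(ha, nchar(fa))  # one past the last flankA base
    innerB <- .flankCoord(hb, 0L)         # first flankB base
    span <- if (ha$strand == 1L) innerB - innerA else innerA - innerB
    if (is.na(span) || span < 0) return(NA_real_)
    span
  }
  spans <- elements
  spans$sibling_span <- vapply(seq_len(nrow(elements)), function(i)
    measure(elements$scaffold[i], elements$start[i], elements$end[i]),
    numeric(1))
  spans$abs_change <- abs(spans$sibling_span - spans$span)
  excluded <- sum(is.na(spans$sibling_span))
  ## matched controls: random positions, insert sizes equal to element spans
  ctrl <- list()
  scafs <- elements$scaffold[sample.int(nrow(elements), nControls,
                                        replace = TRUE)]
  gaps <- elements$span[sample.int(nrow(elements), nControls,
                                   replace = TRUE)]
  for (i in seq_len(nControls)) {
    L <- nchar(reference[[scafs[i]]])
    lo <- flank
    hi <- L - gaps[i] - flank
    if (hi <= lo) next
    s <- sample(lo:hi, 1L)
    ctrl[[length(ctrl) + 1L]] <- data.frame(
      scaffold = scafs[i], start = s, end = s + gaps[i], span = gaps[i],
      stringsAsFactors = FALSE)
  }
  controls <- do.call(rbind, ctrl)
  controls$sibling_span <- vapply(seq_len(nrow(controls)), function(i)
    measure(controls$scaffold[i], controls$start[i], controls$end[i]),
    numeric(1))
  controls$abs_change <- abs(controls$sibling_span - controls$span)
  a <- spans$abs_change[!is.na(spans$abs_change)]
  b <- controls$abs_change[!is.na(controls$abs_change)]
  p <- if (length(a) > 1 && length(b) > 1) {
    if ((stats::var(a) + stats::var(b)) > 0)
      stats::t.test(a, b, var.equal = FALSE)$p.value
    else if (mean(a) == mean(b)) 1 else 0
  } else NA_real_
  list(spans = spans, controls = controls,
       meanElement = mean(a), meanControl = mean(b), p = p,
       excluded = excluded)
}
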