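## Synthetic-data generator: genomes with satellite arrays, fragmented
## transposons and gene models; sibling derivatives with per-region
## substitution rates, planted deletions and transposon insert-size jitter;
## uniform-coverage reads.  Coordinates are 0-based half-open internally and
## in the TruthSet JSON; GRanges conversion happens at the boundary.

#' Specify a synthetic genome
#'
#' Defaults emulate the composition this package is designed around: a small
#' genome carrying alphoid-style satellite monomers (100-300 bp, typical
#' 154-182 bp) in long head-to-tail tandem arrays, dispersed copies of a
#' ~1.5 kb DNA transposon in various states of fragmentation, and
#' single-copy gene-like segments with UTRs, introns and phased CDS.
#'
#' @param length target genome length in bp (features must fit inside).
#' @param satellites list of satellite models, each a list with `monomer`
#'   (sequence, or a length to draw one at random), `arrayCopies` (monomer
#'   copies per tandem array) and `arrays` (number of arrays).
#' @param transposon list with `sequence` (or `length`), `copies`, and
#'   `fragmentation` (probability that a copy is split into pieces with
#'   intervening random sequence).
#' @param genes list with `count` and `lengthRange` (gene extent in bp).
#' @param seed integer seed; the same spec builds byte-identical genomes.
#' @return a validated spec (list, class `"GenomeSpec"`).
#' @export
genomeSpec <- function(length = 3e5,
                       satellites = list(list(monomer = 166L,
                                              arrayCopies = 120L,
                                              arrays = 1L)),
                       transposon = list(length = 1500L, copies = 12L,
                                         fragmentation = 0.4),
                       genes = list(count = 12L, lengthRange = c(1000L, 2500L)),
                       seed = 1L) {
  spec <- list(length = length, satellites = satellites,
               transposon = transposon, genes = genes, seed = as.integer(seed))
  for (s in spec$satellites) {
    L <- if (is.character(s$monomer)) nchar(s$monomer) else s$monomer
    if (L < 100 || L > 300)
      stop("satellite monomer length must be in [100, 300] bp")
  }
  class(spec) <- "GenomeSpec"
  spec
}

#' Specify a sibling-species derivative
#'
#' @param rates named per-region substitution rates (`exon`, `intron`,
#'   `utr5`, `utr3`, `noncoding`), each in `[0, 0.05]`.  Defaults mirror the
#'   magnitude of divergence between very closely related tephritid siblings
#'   (a few substitutions per kilobase, lowest in exons).
#' @param deletions data.frame with columns `pos` (0-based) and `length`
#'   (> 10 bp), or an integer count to place at random in unique sequence.
#' @param jitter list with `prob` (per transposon copy) and `magnitude`
#'   (bp added or removed inside the element).
#' @param seed integer seed.
#' @return a validated spec (list, class `"SiblingSpec"`).
#' @export
siblingSpec <- function(rates = c(exon = 0.003, intron = 0.006, utr5 = 0.0036,
                                  utr3 = 0.0026, noncoding = 0.007),
                        deletions = 8L,
                        jitter = list(prob = 0.5, magnitude = 50L),
                        seed = 1L) {
  need <- c("exon", "intron", "utr5", "utr3", "noncoding")
  if (!all(need %in% names(rates)))
    stop("rates must name all of: ", paste(need, collapse = ", "))
  if (any(rates < 0 | rates > 0.05))
    stop("substitution rates must be in [0, 0.05]")
  spec <- list(rates = rates[need], deletions = deletions, jitter = jitter,
               seed = as.integer(seed))
  class(spec) <- "SiblingSpec"
  spec
}

## one gene model: 5' UTR | exon1 .. intron .. exonN | 3' UTR, CDS phased,
## ATG start, TAA stop, internal stops avoided. Returns seq + relative
## features (0-based half-open).
.makeGene <- function(targetLen, id, strand) {
  utr5 <- 60L; utr3 <- 60L
  nExon <- sample(2:3, 1L)
  intronLens <- sample(80:200, nExon - 1L, replace = TRUE)
  cdsTotal <- targetLen - utr5 - utr3 - sum(intronLens)
  cdsTotal <- max(150L, (cdsTotal %/% 3L) * 3L)
  nCodon <- cdsTotal %/% 3L
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"])
  body <- sample(setdiff(sense, "ATG"), nCodon - 2L, replace = TRUE)
  cds <- paste(c("ATG", body, "TAA"), collapse = "")
  ## split CDS over exons
  cuts <- sort(sample(seq_len(cdsTotal - 1L), nExon - 1L))
  bounds <- c(0L, cuts, cdsTotal)
  pieces <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])
  seqParts <- character(0)
  feats <- list()
  off <- 0L
  add <- function(type, len, phase = NA_integer_) {
    feats[[length(feats) + 1L]] <<- data.frame(
      start = off, end = off + len, type = type, phase = phase)
    off <<- off + len
  }
  seqParts <- c(seqParts, randomDna(utr5)); add("utr5", utr5)
  cumCds <- 0L
  for (i in seq_len(nExon)) {
    phase <- (3L - (cumCds %% 3L)) %% 3L
    seqParts <- c(seqParts, pieces[i])
    add("exon", nchar(pieces[i]), phase)
    cumCds <- cumCds + nchar(pieces[i])
    if (i < nExon) {
      seqParts <- c(seqParts, randomDna(intronLens[i]))
      add("intron", intronLens[i])
    }
  }
  seqParts <- c(seqParts, randomDna(utr3)); add("utr3", utr3)
  feats <- do.call(rbind, feats)
  seq <- paste(seqParts, collapse = "")
  if (strand == "-") {
    ## mirror: build the gene on the minus strand of the genome
    L <- nchar(seq)
    feats <- data.frame(start = L - feats$end, end = L - feats$start,
                        type = feats$type, phase = feats$phase)
    feats <- feats[order(feats$start), ]
    seq <- revComp(seq)
  }
  feats$id <- id
  feats$strand <- strand
  list(seq = seq, features = feats)
}

#' Build a synthetic genome with an exact truth set
#'
#' Features (satellite arrays, transposon copies, gene models) are placed in
#' random order with random stretches of unique background between them; all
#' coordinates are recorded exactly in the returned [TruthSet].
#'
#' @param spec a [genomeSpec()].
#' @return list with `genome` (single named character string) and `truth`
#'   (a [TruthSet]).
#' @export
buildGenome <- function(spec) {
  stopifnot(inherits(spec, "GenomeSpec"))
  set.seed(spec$seed)
  pieces <- list()  # list of list(seq, features df in 0-based local coords)
  addPiece <- function(seq, feat) {
    pieces[[length(pieces) + 1L]] <<- list(seq = seq, feat = feat)
  }
  ## satellites
  si <- 0L
  for (s in spec$satellites) {
    si <- si + 1L
    monomer <- if (is.character(s$monomer)) toupper(s$monomer)
               else randomDna(s$monomer)
    orient <- if (is.null(s$orientation)) "head-to-tail" else s$orientation
    unit <- switch(orient,
      "head-to-tail" = monomer,
      "head-to-head" = paste0(monomer, revComp(monomer)),
      stop("unknown satellite orientation"))
    reps <- if (orient == "head-to-head") ceiling(s$arrayCopies / 2) else
      s$arrayCopies
    for (a in seq_len(s$arrays)) {
      arr <- strrep(unit, reps)
      addPiece(arr, data.frame(start = 0L, end = nchar(arr),
                               type = "satellite_array",
                               phase = NA_integer_,
                               id = sprintf("sat%d", si), strand = "+",
                               monomer = monomer,
                               stringsAsFactors = FALSE))
    }
  }
  ## transposons
  tp <- spec$transposon
  canonical <- NULL
  if (!is.null(tp) && tp$copies > 0) {
    canonical <- if (is.character(tp$sequence)) toupper(tp$sequence)
                 else randomDna(tp$length)
    for (i in seq_len(tp$copies)) {
      id <- sprintf("te%03d", i)
      if (runif(1) < tp$fragmentation) {
        ## split the canonical into 2-3 ordered pieces with random spacers
        nFrag <- sample(2:3, 1L)
        cuts <- sort(sample(seq(200L, nchar(canonical) - 200L), nFrag - 1L))
        b <- c(0L, cuts, nchar(canonical))
        frags <- substring(canonical, b[-length(b)] + 1L, b[-1L])
        gaps <- sample(100:400, nFrag - 1L, replace = TRUE)
        seq <- frags[1L]
        feat <- data.frame(start = 0L, end = nchar(frags[1L]),
                           type = "transposon_fragment", phase = NA_integer_,
                           id = id, strand = "+", monomer = NA_character_,
                           stringsAsFactors = FALSE)
        for (j in seq_len(nFrag - 1L)) {
          seq <- paste0(seq, randomDna(gaps[j]))
          st <- nchar(seq)
          seq <- paste0(seq, frags[j + 1L])
          feat <- rbind(feat, data.frame(start = st, end = nchar(seq),
                                         type = "transposon_fragment",
                                         phase = NA_integer_, id = id,
                                         strand = "+",
                                         monomer = NA_character_))
        }
        feat <- rbind(feat, data.frame(start = 0L, end = nchar(seq),
                                       type = "transposon_element",
                                       phase = NA_integer_, id = id,
                                       strand = "+", monomer = NA_character_))
        addPiece(seq, feat)
      } else {
        feat <- data.frame(start = c(0L, 0L),
                           end = c(nchar(canonical), nchar(canonical)),
                           type = c("transposon_fragment",
                                    "transposon_element"),
                           phase = NA_integer_, id = id, strand = "+",
                           monomer = NA_character_, stringsAsFactors = FALSE)
        addPiece(canonical, feat)
      }
    }
  }
  ## genes
  gn <- spec$genes
  if (!is.null(gn) && gn$count > 0) {
    for (i in seq_len(gn$count)) {
      len <- sample(gn$lengthRange[1]:gn$lengthRange[2], 1L)
      strand <- sample(c("+", "-"), 1L)
      g <- .makeGene(len, sprintf("gene%03d", i), strand)
      g$features$monomer <- NA_character_
      addPiece(g$seq, g$features)
    }
  }
  featLen <- sum(vapply(pieces, function(p) nchar(p$seq), numeric(1)))
  bgTotal <- spec$length - featLen
  if (bgTotal < length(pieces) + 1L)
    stop("infeasible packing: planted features exceed the genome length")
  pieces <- pieces[sample(length(pieces))]
  ## split background into random chunks around the features
  nGap <- length(pieces) + 1L
  w <- as.vector(stats::rmultinom(1L, bgTotal, rep(1 / nGap, nGap)))
  out <- character(0)
  feats <- list()
  off <- 0L
  for (i in seq_along(pieces)) {
    out <- c(out, randomDna(w[i]))
    off <- off + w[i]
    f <- pieces[[i]]$feat
    f$start <- f$start + off
    f$end <- f$end + off
    feats[[i]] <- f
    out <- c(out, pieces[[i]]$seq)
    off <- off + nchar(pieces[[i]]$seq)
  }
  out <- c(out, randomDna(w[nGap]))
  genome <- paste(out, collapse = "")
  featdf <- if (length(feats)) do.call(rbind, feats) else
    data.frame(start = integer(0), end = integer(0), type = character(0),
               phase = integer(0), id = character(0), strand = character(0),
               monomer = character(0))
  gr <- if (nrow(featdf) == 0L) GenomicRanges::GRanges() else
    GenomicRanges::GRanges(
      seqnames = "genome",
      ranges = IRanges::IRanges(start = featdf$start + 1L, end = featdf$end),
      strand = featdf$strand)
  gr$type <- featdf$type
  gr$id <- featdf$id
  gr$phase <- featdf$phase
  gr$monomer <- featdf$monomer
  truth <- new("TruthSet", genomeLength = nchar(genome), features = gr,
               editCounts = numeric(0),
               deletions = GenomicRanges::GRanges(),
               jitter = data.frame())
  if (!is.null(canonical))
    attr(truth, "transposonCanonical") <- canonical
  list(genome = c(genome = genome), truth = truth)
}

#' Per-base region classes from a truth annotation
#'
#' Precedence where annotations overlap: exon > 5' UTR > 3' UTR > intron;
#' anything unannotated (including repeats) is non-coding.
#'
#' @param truth a [TruthSet] (or a GRanges with a `type` column).
#' @param genomeLength genome length (taken from the TruthSet if missing).
#' @return factor vector of length `genomeLength` with levels
#'   `exon`, `utr5`, `utr3`, `intron`, `noncoding`.
#' @export
regionClasses <- function(truth, genomeLength = NULL) {
  gr <- if (is(truth, "TruthSet")) truthFeatures(truth) else truth
  if (is.null(genomeLength)) genomeLength <- genomeLength(truth)
  cls <- rep("noncoding", genomeLength)
  paint <- function(type) {
    sel <- gr[gr$type == type]
    for (i in seq_along(sel)) {
      cls[GenomicRanges::start(sel)[i]:GenomicRanges::end(sel)[i]] <<- type
    }
  }
  ## paint lowest precedence first so higher classes overwrite
  for (type in c("intron", "utr3", "utr5", "exon")) paint(type)
  factor(cls, levels = c("exon", "utr5", "utr3", "intron", "noncoding"))
}

#' Derive a sibling-species genome
#'
#' Applies per-region substitution rates, planted deletions (> 10 bp,
#' non-overlapping) and transposon insert-size jitter to a reference genome,
#' recording every edit in the returned truth set.
#'
#' @param genome reference sequence (single character string).
#' @param truth the reference [TruthSet] (provides region annotation and
#'   transposon coordinates).
#' @param spec a [siblingSpec()].
#' @return list with `genome` (sibling sequence) and `truth` (a [TruthSet]
#'   whose coordinates refer to the *reference*).
#' @export
deriveSibling <- function(genome, truth, spec) {
  stopifnot(inherits(spec, "SiblingSpec"))
  genome <- unname(genome[1])
  set.seed(spec$seed)
  L <- nchar(genome)
  cls <- regionClasses(truth, L)
  bases <- strsplit(genome, "", fixed = TRUE)[[1]]

  ## substitutions
  rate <- spec$rates[as.character(cls)]
  hit <- which(runif(L) < rate)
  if (length(hit)) {
    old <- bases[hit]
    new <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1L),
                  character(1))
    bases[hit] <- new
  }
  editCounts <- vapply(levels(cls), function(k) sum(cls[hit] == k), numeric(1))

  ## deletions: user-given or placed at random in unannotated sequence
  dels <- spec$deletions
  if (is.numeric(dels) && length(dels) == 1L) {
    n <- as.integer(dels)
    dels <- data.frame(pos = integer(0), length = integer(0))
    if (n > 0) {
      occupied <- IRanges::reduce(IRanges::ranges(truthFeatures(truth)))
      lens <- sample(15:80, n, replace = TRUE)
      pos <- integer(0)
      guard <- 0L
      while (length(pos) < n && guard < 10000L) {
        guard <- guard + 1L
        p <- sample.int(L - 200L, 1L)
        w <- lens[length(pos) + 1L]
        cand <- IRanges::IRanges(p + 1L, p + w)
        clash <- length(IRanges::findOverlaps(cand, occupied)) > 0 ||
          (length(pos) && any(abs(p - pos) < 300L))
        ## avoid breakpoint micro-homology: with identical bases across the
        ## junction the deletion coordinate itself is ambiguous (any aligner
        ## may shift the gap), so exact-coordinate truth would be ill-posed
        homology <- substr(genome, p + 1L, p + 1L) ==
                      substr(genome, p + w + 1L, p + w + 1L) ||
                    substr(genome, p, p) == substr(genome, p + w, p + w)
        ## conserved flanks: a fixed substitution right next to the junction
        ## degrades flank coverage by construction (every read carries it),
        ## so planted deletions sit in substitution-free surroundings
        nearSub <- length(hit) &&
          any((hit - 1L) >= p - 12L & (hit - 1L) <= p + w + 12L)
        if (!clash && !homology && !nearSub) pos <- c(pos, p)
      }
      if (length(pos) < n)
        stop("could not place the requested number of deletions")
      dels <- data.frame(pos = pos, length = lens[seq_along(pos)])
    }
  }
  dels <- dels[order(dels$pos), , drop = FALSE]
  if (nrow(dels)) {
    if (any(dels$length <= 10))
      stop("planted deletions must be longer than 10 bp")
    ends <- dels$pos + dels$length
    if (any(dels$pos[-1] < ends[-length(ends)]))
      stop("deletions overlap")
    if (any(dels$pos < 0) || any(ends > L))
      stop("deletion outside the genome")
  }

  ## transposon jitter: insert or remove bases inside element copies
  jit <- data.frame(id = character(0), delta = integer(0), at = integer(0))
  elts <- truthFeatures(truth, "transposon_element")
  if (length(elts) && !is.null(spec$jitter) && spec$jitter$prob > 0) {
    for (i in seq_along(elts)) {
      if (runif(1) >= spec$jitter$prob) next
      delta <- sample(c(-1L, 1L), 1L) * as.integer(spec$jitter$magnitude)
      s <- GenomicRanges::start(elts)[i] - 1L  # back to 0-based
      e <- GenomicRanges::end(elts)[i]
      at <- s + sample.int(max(1L, (e - s) - abs(delta) - 20L), 1L) + 10L
      jit <- rbind(jit, data.frame(id = elts$id[i], delta = delta, at = at))
    }
  }

  ## apply edits right-to-left so earlier coordinates stay valid
  edits <- rbind(
    if (nrow(dels)) data.frame(at = dels$pos, delta = -dels$length) else NULL,
    if (nrow(jit)) data.frame(at = jit$at, delta = jit$delta) else NULL)
  sib <- bases
  if (!is.null(edits) && nrow(edits)) {
    edits <- edits[order(-edits$at), ]
    for (i in seq_len(nrow(edits))) {
      at <- edits$at[i]
      d <- edits$delta[i]
      if (d < 0) {
        sib <- sib[-((at + 1L):(at - d))]
      } else {
        sib <- append(sib, sample(DNA_BASES, d, replace = TRUE), after = at)
      }
    }
  }
  sibGenome <- paste(sib, collapse = "")

  delGr <- if (nrow(dels)) GenomicRanges::GRanges("genome",
    IRanges::IRanges(start = dels$pos + 1L, width = dels$length)) else
    GenomicRanges::GRanges()
  sibTruth <- new("TruthSet", genomeLength = L,
                  features = truthFeatures(truth),
                  editCounts = editCounts, deletions = delGr, jitter = jit)
  attr(sibTruth, "substitutionPositions") <- hit - 1L  # 0-based
  list(genome = c(sibling = sibGenome), truth = sibTruth)
}

#' Simulate uniform-coverage short reads
#'
#' Read (or fragment) start positions are uniform over the sequence; each
#' read comes from either strand with probability 1/2; sequencing errors are
#' i.i.d. substitutions at `errorRate`.  Qualities are constant placeholders
#' (`"I"`) since nothing downstream is quality-aware.
#'
#' @param sequence template (single character string).
#' @param depth target fold-coverage (> 0).
#' @param readLen read length in bp (default 100).
#' @param errorRate per-base substitution error rate.
#' @param paired simulate read pairs from ~`insertMean` bp fragments.
#' @param insertMean,insertSd fragment length distribution for paired mode.
#' @param seed optional integer seed (calls `set.seed`).
#' @return named character vector of reads (names `r<i>` or `f<i>/1`,
#'   `f<i>/2`), with the simulation metadata in `attr(, "meta")`.
#' @export
simulateReads <- function(sequence, depth, readLen = 100L, errorRate = 0,
                          paired = FALSE, insertMean = 300, insertSd = 30,
                          seed = NULL) {
  sequence <- unname(sequence[1])
  if (!nzchar(sequence)) stop("empty sequence")
  if (depth <= 0) stop("depth must be > 0")
  if (readLen > nchar(sequence)) stop("read length exceeds sequence length")
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(sequence)
  nReads <- max(1L, round(depth * L / readLen))
  if (paired) {
    nFrag <- max(1L, round(nReads / 2))
    sim <- .cpp_simulate_reads(sequence, nFrag, as.integer(readLen),
                               errorRate, TRUE, insertMean, insertSd)
    reads <- as.character(rbind(sim$read1, sim$read2))
    names(reads) <- as.vector(rbind(sprintf("f%06d/1", seq_len(nFrag)),
                                    sprintf("f%06d/2", seq_len(nFrag))))
    meta <- data.frame(fragment = sprintf("f%06d", seq_len(nFrag)),
                       pos = sim$pos, fragment_len = sim$fragment_len,
                       strand = sim$strand)
  } else {
    sim <- .cpp_simulate_reads(sequence, nReads, as.integer(readLen),
                               errorRate, FALSE, insertMean, insertSd)
    reads <- as.character(sim$read1)
    names(reads) <- sprintf("r%06d", seq_len(nReads))
    meta <- data.frame(read = names(reads), pos = sim$pos,
                       strand = sim$strand)
  }
  attr(reads, "meta") <- meta
  reads
}

#' Simulate a multicopy rRNA-like unit with spacer-concentrated variation
#'
#' Emulates a ribosomal repeat unit (18S / ITS1 / 5.8S / 2S / ITS2 / 28S
#' flanked by ETS and an incomplete IGS): a pool of unit copies is derived
#' from one consensus, with a fraction of copies carrying substitutions at
#' `divergence` restricted to the spacer regions (ITS/ETS/IGS), as higher
#' frequency variants concentrate there in real arrays.
#'
#' @param regionLengths named lengths, in unit order.
#' @param nCopies pool size.
#' @param divergentFraction fraction of copies carrying spacer variants.
#' @param divergence per-base substitution rate inside spacers of divergent
#'   copies.
#' @param seed integer seed.
#' @return list: `consensus` (character), `regions` (data.frame `start`,
#'   `end`, `region`, 0-based half-open), `copies` (character vector),
#'   `divergent` (logical per copy).
#' @export
simulateRrnaPool <- function(regionLengths = c(ETS = 700, `18S` = 1900,
                                               ITS1 = 550, `5.8S` = 150,
                                               `2S` = 30, ITS2 = 400,
                                               `28S` = 3900, IGS = 1000),
                             nCopies = 40L, divergentFraction = 0.3,
                             divergence = 0.05, seed = 1L) {
  set.seed(seed)
  consensus <- randomDna(sum(regionLengths))
  ends <- cumsum(regionLengths)
  regions <- data.frame(start = ends - regionLengths, end = ends,
                        region = names(regionLengths),
                        stringsAsFactors = FALSE)
  spacer <- regions$region %in% c("ETS", "ITS1", "ITS2", "IGS")
  spacerMask <- rep(FALSE, nchar(consensus))
  for (i in which(spacer))
    spacerMask[(regions$start[i] + 1L):regions$end[i]] <- TRUE
  divergent <- runif(nCopies) < divergentFraction
  copies <- vapply(seq_len(nCopies), function(i) {
    if (!divergent[i]) return(consensus)
    chars <- strsplit(consensus, "")[[1]]
    hit <- which(spacerMask & runif(length(chars)) < divergence)
    if (length(hit))
      chars[hit] <- vapply(chars[hit], function(b)
        sample(setdiff(DNA_BASES, b), 1L), character(1))
    paste(chars, collapse = "")
  }, character(1))
  list(consensus = consensus, regions = regions, copies = copies,
       divergent = divergent)
}

#' Write / read a TruthSet as JSON
#'
#' Lossless round-trip of planted features (0-based half-open in the file),
#' realized edit counts, deletions and jitter records.
#'
#' @param truth a [TruthSet].
#' @param path file path.
#' @return `readTruthSet` returns a [TruthSet].
#' @export
writeTruthSet <- function(truth, path) {
  gr <- truthFeatures(truth)
  feats <- data.frame(start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      type = gr$type, id = gr$id, phase = gr$phase,
                      monomer = gr$monomer, stringsAsFactors = FALSE)
  dels <- truthDeletions(truth)
  obj <- list(genome_length = genomeLength(truth),
              features = feats,
              edit_counts = as.list(truthEditCounts(truth)),
              deletions = data.frame(
                start = if (length(dels)) GenomicRanges::start(dels) - 1L else integer(0),
                length = if (length(dels)) GenomicRanges::width(dels) else integer(0)),
              jitter = truth@jitter)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeTruthSet
#' @export
readTruthSet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  f <- obj$features
  gr <- if (is.null(f) || !length(f$start)) GenomicRanges::GRanges() else {
    g <- GenomicRanges::GRanges("genome",
      IRanges::IRanges(start = f$start + 1L, end = f$end), strand = f$strand)
    g$type <- f$type; g$id <- f$id
    g$phase <- if (is.null(f$phase)) NA_integer_ else as.integer(f$phase)
    g$monomer <- if (is.null(f$monomer)) NA_character_ else f$monomer
    g
  }
  dels <- obj$deletions
  delGr <- if (is.null(dels) || !length(dels$start)) GenomicRanges::GRanges()
    else GenomicRanges::GRanges("genome",
      IRanges::IRanges(start = dels$start + 1L, width = dels$length))
  jit <- if (is.null(obj$jitter) || !length(obj$jitter)) data.frame() else
    as.data.frame(obj$jitter)
  ec <- unlist(obj$edit_counts)
  if (is.null(ec)) ec <- numeric(0)
  new("TruthSet", genomeLength = obj$genome_length, features = gr,
      editCounts = ec, deletions = delGr, jitter = jit)
}
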