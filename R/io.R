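## Readers/writers for the standard formats touched, plus the alignment /
## pileup contract.  FASTA goes through Biostrings, GFF3 and BED through
## rtracklayer; FASTQ (constant placeholder qualities) and the SAM 1.x text
## subset are written directly.

#' Read / write FASTA
#'
#' Sequences are returned as a plain named character vector, uppercased;
#' mixed-case input triggers a warning.  Use [Biostrings::readDNAStringSet()]
#' directly if an `XStringSet` is wanted.
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @return `readFasta`: named character vector.
#' @export
readFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ## DNAStringSet normalises case on construction, so lowercase (masked)
  ## input is detected on the raw lines
  raw <- readLines(path)
  if (any(grepl("[a-z]", raw[!startsWith(raw, ">")])))
    warning("mixed-case sequence uppercased")
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' @rdname readFasta
#' @export
writeFasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  if (is.null(names(x))) names(x) <- sprintf("seq%d", seq_along(x))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read / write FASTQ
#'
#' Minimal four-line-record FASTQ.  Qualities are not modelled anywhere in
#' this package: the writer emits constant `'I'` and the reader discards the
#' quality line after checking its length.  Malformed records raise an error
#' naming the offending line.
#'
#' @param path file path.
#' @param reads named character vector of reads.
#' @return `readFastq`: named character vector.
#' @export
readFastq <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: ", length(lines), " lines")
  i <- seq(1L, length(lines), by = 4L)
  hdr <- lines[i]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop("malformed FASTQ record header at line ", (bad[1] - 1L) * 4L + 1L)
  plus <- lines[i + 2L]
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ separator at line ", (bad[1] - 1L) * 4L + 3L)
  seqs <- toupper(lines[i + 1L])
  qual <- lines[i + 3L]
  bad <- which(nchar(qual) != nchar(seqs))
  if (length(bad))
    stop("quality length mismatch at line ", (bad[1] - 1L) * 4L + 4L)
  names(seqs) <- sub("\\s.*$", "", substring(hdr, 2L))
  seqs
}

#' @rdname readFastq
#' @export
writeFastq <- function(reads, path) {
  if (is.null(names(reads))) names(reads) <- sprintf("r%06d", seq_along(reads))
  rec <- rbind(paste0("@", names(reads)), reads, "+",
               strrep("I", nchar(reads)))
  writeLines(as.vector(rec), path)
  invisible(path)
}

#' Read / write GFF3
#'
#' Wraps rtracklayer; the phase column survives the round trip (internally
#' 0-based half-open coordinates are converted at this boundary).
#'
#' @param path file path.
#' @param gr a GRanges with `type`, `id` and (for CDS) `phase` columns.
#' @return `readGff3`: a GRanges.
#' @export
readGff3 <- function(path) rtracklayer::import(path, format = "gff3")

#' @rdname readGff3
#' @export
writeGff3 <- function(gr, path) {
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Export a truth annotation as GFF3 gene models
#'
#' Gene sub-features become standard GFF3 types (`five_prime_UTR`, `CDS`,
#' `intron`, `three_prime_UTR`) with CDS phase filled in.
#'
#' @param truth a [TruthSet].
#' @param path output path.
#' @export
truthToGff3 <- function(truth, path) {
  gr <- truthFeatures(truth, c("utr5", "exon", "intron", "utr3"))
  if (!length(gr)) stop("no gene features in this truth set")
  map <- c(utr5 = "five_prime_UTR", exon = "CDS", intron = "intron",
           utr3 = "three_prime_UTR")
  gr$type <- unname(map[gr$type])
  gr$ID <- paste0(gr$id, ":", seq_along(gr))
  gr$Parent <- gr$id
  writeGff3(gr, path)
}

#' Write genomic intervals as BED
#'
#' @param df data.frame with `scaffold`, `start`, `end` (0-based half-open)
#'   plus any extra columns, appended after the first three.
#' @param path output path.
#' @export
writeBed <- function(df, path) {
  stopifnot(all(c("scaffold", "start", "end") %in% names(df)))
  extra <- setdiff(names(df), c("scaffold", "start", "end"))
  out <- df[, c("scaffold", "start", "end", extra), drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Map reads with the internal seed-and-extend mapper
#'
#' Each read is anchored by exact seeds (default 19 bp), evaluated ungapped
#' on the candidate diagonals and, where that fits poorly, re-aligned with a
#' gapped dynamic program so reads spanning reference deletions receive a
#' deletion operation.  Scoring: match +1, mismatch -1, gap open -3, gap
#' extend -1; the best-scoring placement wins and leftmost placement breaks
#' exact ties.  Mapping quality reflects uniqueness: a unique placement gets
#' q = 60, an exact score tie q = 0.
#'
#' @param reads named character vector of reads.
#' @param reference named character vector of reference sequences.
#' @param seedLen exact seed length (reads shorter than this are unmapped).
#' @param maxOcc per-seed occurrence cap in the index.
#' @param maxCand candidate placements evaluated per read.
#' @param gapTriggerMM ungapped mismatch count above which the gapped
#'   alignment is attempted.
#' @param gapPad largest reference deletion spanned by a single read.
#' @param minScoreFrac minimum alignment score as a percentage of read
#'   length; weaker placements are reported unmapped.
#' @return data.frame with one row per mapped read: `qname`, `rname`, `pos`
#'   (0-based), `strand` (+1/-1), `cigar` (M/I/D), `mapq`, `nm`, `score`,
#'   `seq` (read in reference orientation).
#' @export
mapReads <- function(reads, reference, seedLen = 19L, maxOcc = 64L,
                     maxCand = 12L, gapTriggerMM = 5L, gapPad = 150L,
                     minScoreFrac = 30L) {
  reference <- vapply(reference, toupper, character(1))
  if (is.null(names(reference)))
    names(reference) <- sprintf("ref%d", seq_along(reference))
  if (is.null(names(reads))) names(reads) <- sprintf("r%06d", seq_along(reads))
  hit <- .cpp_map_reads(unname(reference), unname(as.character(reads)),
                        as.integer(seedLen), as.integer(maxOcc),
                        as.integer(maxCand), as.integer(gapTriggerMM),
                        as.integer(gapPad), as.integer(minScoreFrac))
  seq <- unname(as.character(reads)[hit$read])
  rc <- hit$strand == -1L
  if (any(rc)) seq[rc] <- revComp(seq[rc])
  data.frame(qname = names(reads)[hit$read], rname = names(reference)[hit$rid],
             rid = hit$rid, pos = hit$pos, strand = hit$strand,
             cigar = hit$cigar, mapq = hit$mapq, nm = hit$nm,
             score = hit$score, seq = seq, stringsAsFactors = FALSE)
}

#' Keep only alignments whose mate also mapped
#'
#' Read pairs are recognised by the `/1` `/2` suffix convention of the
#' simulator; both mates must be present (on any strand) to survive.
#'
#' @param alignments a [mapReads()] data.frame.
#' @return the filtered data.frame.
#' @export
keepPaired <- function(alignments) {
  frag <- sub("/[12]$", "", alignments$qname)
  mate <- table(frag)
  alignments[mate[frag] >= 2L, , drop = FALSE]
}

#' Build a pileup from alignments
#'
#' Only alignments with `mapq > minQ` contribute.  Deletion operations
#' contribute no base at deleted sites (depth there excludes the read);
#' per-site deletion and insertion evidence is kept alongside.
#'
#' @param alignments a [mapReads()] data.frame (or one read from SAM).
#' @param reference named character vector of reference sequences (supplies
#'   names and lengths).
#' @param minQ mapping-quality floor (strict: `mapq > minQ`).
#' @return a [Pileup].
#' @export
pileupFromAlignments <- function(alignments, reference, minQ = 20L) {
  reflens <- as.integer(nchar(reference))
  rid <- if ("rid" %in% names(alignments) && !anyNA(alignments$rid))
    alignments$rid else match(alignments$rname, names(reference))
  res <- .cpp_pileup(as.integer(rid), as.integer(alignments$pos),
                     as.character(alignments$cigar),
                     as.character(alignments$seq),
                     as.integer(alignments$mapq), as.integer(minQ), reflens)
  new("Pileup", refnames = names(reference), reflens = reflens,
      data = lapply(res, function(d) {
        d$depth <- as.integer(d$depth)
        d
      }),
      minQ = as.integer(minQ))
}

## ---- SAM 1.x text subset ---------------------------------------------------

#' Write / read a SAM text subset
#'
#' Supports the fields this package produces: header `@SQ` lines, the FLAG
#' strand bit (16), POS, MAPQ, CIGAR with M/I/D, SEQ, and the `NM:i:` tag.
#' Round-trips [mapReads()] output losslessly (score excepted).  An external
#' mapper's SAM can be imported instead of using the internal one, as all
#' downstream stages depend only on the alignment/pileup contract.
#'
#' @param alignments a [mapReads()] data.frame.
#' @param reference named character vector (for `@SQ` header lines).
#' @param path file path.
#' @return `readSam`: an alignments data.frame.
#' @export
writeSam <- function(alignments, reference, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                     nchar(reference)), con)
  if (nrow(alignments)) {
    flag <- ifelse(alignments$strand == -1L, 16L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                       alignments$qname, flag, alignments$rname,
                       alignments$pos + 1L, alignments$mapq,
                       alignments$cigar, alignments$seq, alignments$nm), con)
  }
  invisible(path)
}

#' @rdname writeSam
#' @export
readSam <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  body <- lines[!startsWith(lines, "@")]
  sq <- lines[startsWith(lines, "@SQ")]
  rnames <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  if (!length(body)) {
    return(data.frame(qname = character(0), rname = character(0),
                      rid = integer(0), pos = integer(0), strand = integer(0),
                      cigar = character(0), mapq = integer(0),
                      nm = integer(0), seq = character(0)))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  if (any(nf < 11L)) {
    bad <- which(nf < 11L)[1]
    stop("malformed SAM record at line ",
         which(!startsWith(lines, "@"))[bad])
  }
  get <- function(i) vapply(parts, `[[`, character(1), i)
  nm <- vapply(parts, function(p) {
    tag <- grep("^NM:i:", p[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("NM:i:", "", tag[1])) else NA_integer_
  }, integer(1))
  rname <- get(3)
  data.frame(qname = get(1), rname = rname,
             rid = match(rname, rnames),
             pos = as.integer(get(4)) - 1L,
             strand = ifelse(bitwAnd(as.integer(get(2)), 16L) > 0L, -1L, 1L),
             cigar = get(6), mapq = as.integer(get(5)), nm = nm,
             seq = get(10), stringsAsFactors = FALSE)
}
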