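test_that("FASTA round-trips and uppercases mixed-case input with a warning", {
  seqs <- c(a = "ACGTACGTAC", b = "TTTTGGGGCC")
  path <- tempfile(fileext = ".fa")
  writeFasta(seqs, path)
  expect_identical(readFasta(path), seqs)
  writeLines(c(">mix", "acgtACGT"), path)
  expect_warning(out <- readFasta(path), "uppercased")
  expect_identical(unname(out), "ACGTACGT")
})

test_that("FASTQ round-trips, tolerates CRLF, errors with line numbers", {
  reads <- setNames(c("ACGTACGTA", "GGGCCCAAA"), c("r1", "r2"))
  path <- tempfile(fileext = ".fq")
  writeFastq(reads, path)
  expect_identical(readFastq(path), reads)
  ## CRLF tolerance
  writeLines(paste0(readLines(path), "\r"), path)
  expect_identical(readFastq(path), reads)
  ## malformed header names the line
  writeLines(c("@ok", "ACGT", "+", "IIII", "bad", "ACGT", "+", "IIII"), path)
  expect_error(readFastq(path), "line 5")
})

test_that("SAM subset round-trips mapReads output", {
  set.seed(21)
  ref <- c(chr = randomDna(5000))
  reads <- simulateReads(ref, depth = 2, errorRate = 0.01, seed = 22)
  aln <- mapReads(reads, ref)
  path <- tempfile(fileext = ".sam")
  writeSam(aln, ref, path)
  back <- readSam(path)
  for (col in c("qname", "rname", "pos", "strand", "cigar", "mapq", "nm",
                "seq")) {
    expect_identical(back[[col]], aln[[col]], label = col)
  }
})

test_that("GFF3 export preserves CDS phase", {
  spec <- genomeSpec(length = 3e4, satellites = list(), transposon = NULL,
                     genes = list(count = 3, lengthRange = c(1200, 1500)),
                     seed = 23)
  g <- buildGenome(spec)
  path <- tempfile(fileext = ".gff3")
  truthToGff3(g$truth, path)
  back <- readGff3(path)
  cds <- back[back$type == "CDS"]
  orig <- truthFeatures(g$truth, "exon")
  expect_equal(length(cds), length(orig))
  expect_equal(as.integer(as.character(cds$phase)), orig$phase)
  expect_equal(GenomicRanges::start(cds), GenomicRanges::start(orig))
})

test_that("BED output is 0-based half-open with extra columns appended", {
  df <- data.frame(scaffold = "s", start = c(10L, 50L), end = c(20L, 70L),
                   score = c(1, 2))
  path <- tempfile(fileext = ".bed")
  writeBed(df, path)
  lines <- readLines(path)
  expect_identical(lines[1], "s\t10\t20\t1")
})

test_that("mapper recovers error-free unique-region reads essentially always", {
  set.seed(24)
  ref <- c(genome = randomDna(6e4))
  reads <- simulateReads(ref, depth = 5, errorRate = 0, seed = 25)
  aln <- mapReads(reads, ref)
  meta <- attr(reads, "meta")
  m <- match(aln$qname, meta$read)
  expect_gte(nrow(aln) / length(reads), 0.999)
  expect_gte(mean(aln$pos == meta$pos[m]), 0.999)
  expect_true(all(aln$nm == 0))
  expect_true(all(aln$mapq == 60))
})

test_that("reads from duplicated regions are flagged ambiguous (q = 0)", {
  set.seed(26)
  dup <- randomDna(3000)
  ref <- c(genome = paste0(randomDna(2000), dup, randomDna(2000), dup,
                           randomDna(2000)))
  rd <- substr(dup, 1001, 1100)
  aln <- mapReads(c(x = rd), ref)
  expect_equal(aln$mapq, 0)
})

test_that("a read spanning a reference deletion receives the deletion op", {
  set.seed(27)
  ref <- c(genome = randomDna(8000))
  rd <- paste0(substr(ref, 3001, 3050), substr(ref, 3071, 3120))
  aln <- mapReads(c(x = rd), ref)
  expect_equal(aln$cigar, "50M20D50M")
  expect_equal(aln$pos, 3000)
  expect_equal(aln$nm, 20)
})

test_that("reads shorter than the seed are unmapped", {
  ref <- c(genome = randomDna(2000))
  aln <- mapReads(c(x = substr(ref, 101, 115)), ref, seedLen = 19)
  expect_equal(nrow(aln), 0)
})

test_that("pileup counts depth and alleles; q filter excludes low-q reads", {
  ref <- c(chr = strrep("ACGT", 50))
  aln <- data.frame(qname = sprintf("r%d", 1:10), rname = "chr", rid = 1L,
                    pos = 40L, strand = 1L, cigar = "20M", mapq = 60L,
                    nm = 0L, seq = unname(substr(ref, 41, 60)),
                    stringsAsFactors = FALSE, row.names = NULL)
  pu <- pileupFromAlignments(aln, ref, minQ = 20)
  expect_equal(pileupDepth(pu)[45], 10L)
  cnt <- baseCounts(pu)
  expect_equal(sum(cnt[, 45] > 0), 1L)  # single allele
  aln$mapq[1:4] <- 10L
  pu2 <- pileupFromAlignments(aln, ref, minQ = 20)
  expect_equal(pileupDepth(pu2)[45], 6L)
})

test_that("a deletion op contributes no base but leaves evidence", {
  ref <- c(chr = randomDna(200))
  seqs <- paste0(substr(ref, 51, 80), substr(ref, 91, 110))
  aln <- data.frame(qname = c("a", "b", "c"), rname = "chr", rid = 1L,
                    pos = c(50L, 50L, 40L), strand = 1L,
                    cigar = c("30M10D20M", "30M10D20M", "50M"), mapq = 60L,
                    nm = c(10L, 10L, 0L),
                    seq = c(seqs, seqs, substr(ref, 41, 90)),
                    stringsAsFactors = FALSE)
  pu <- pileupFromAlignments(aln, ref, minQ = 20)
  expect_equal(pileupDepth(pu)[85], 1L)   # only the 50M read
  expect_equal(indelEvidence(pu)$del[85], 2L)
  expect_equal(pileupDepth(pu)[75], 3L)   # before the deletion
})

test_that("pileup depth equals a brute-force interval-stabbing count", {
  set.seed(28)
  ref <- c(genome = randomDna(4000))
  reads <- simulateReads(ref, depth = 6, errorRate = 0, seed = 29)
  aln <- mapReads(reads, ref)
  pu <- pileupFromAlignments(aln, ref, minQ = 20)
  brute <- integer(4000)
  for (i in seq_len(nrow(aln))) {
    if (aln$mapq[i] <= 20) next
    span <- aln$pos[i] + seq_len(100)  # all alignments here are 100M
    brute[span] <- brute[span] + 1L
  }
  expect_identical(as.integer(pileupDepth(pu, 1)), brute)
})

test_that("keepPaired drops alignments whose mate is unmapped", {
  aln <- data.frame(qname = c("f1/1", "f1/2", "f2/1"), mapq = 60)
  kept <- keepPaired(aln)
  expect_identical(kept$qname, c("f1/1", "f1/2"))
})
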