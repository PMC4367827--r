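test_that("degenerate spec yields a plain random sequence with empty truth", {
  spec <- genomeSpec(length = 5000, satellites = list(), transposon = NULL,
                     genes = list(count = 0, lengthRange = c(0, 0)), seed = 1)
  g <- buildGenome(spec)
  expect_equal(unname(nchar(g$genome)), 5000)
  expect_length(truthFeatures(g$truth), 0)
  expect_match(g$genome, "^[ACGT]+$")
})

test_that("a satellite array is planted verbatim as head-to-tail tandem", {
  set.seed(3)
  mono <- randomDna(166)
  spec <- genomeSpec(length = 1e5,
                     satellites = list(list(monomer = mono,
                                            arrayCopies = 500, arrays = 1)),
                     transposon = NULL,
                     genes = list(count = 0, lengthRange = c(0, 0)), seed = 2)
  g <- buildGenome(spec)
  expect_true(grepl(strrep(mono, 500), g$genome, fixed = TRUE))
  arr <- truthFeatures(g$truth, "satellite_array")
  expect_equal(GenomicRanges::width(arr), 166 * 500)
  expect_identical(unname(substr(g$genome, GenomicRanges::start(arr),
                                 GenomicRanges::end(arr))),
                   strrep(mono, 500))
})

test_that("genome construction is byte-identical under a fixed seed", {
  spec <- genomeSpec(length = 1.5e5, seed = 7)
  g1 <- buildGenome(spec)
  g2 <- buildGenome(spec)
  expect_identical(g1$genome, g2$genome)
  expect_identical(as.data.frame(truthFeatures(g1$truth)),
                   as.data.frame(truthFeatures(g2$truth)))
})

test_that("infeasible packing raises an explicit error", {
  spec <- genomeSpec(length = 1000,
                     satellites = list(list(monomer = 166,
                                            arrayCopies = 100, arrays = 1)),
                     transposon = NULL,
                     genes = list(count = 0, lengthRange = c(0, 0)), seed = 1)
  expect_error(buildGenome(spec), "infeasible packing")
})

test_that("sibling with zero rates and no deletions is identical", {
  spec <- genomeSpec(length = 4e4, satellites = list(), transposon = NULL,
                     genes = list(count = 3, lengthRange = c(1200, 1500)),
                     seed = 4)
  g <- buildGenome(spec)
  ss <- siblingSpec(rates = c(exon = 0, intron = 0, utr5 = 0, utr3 = 0,
                              noncoding = 0),
                    deletions = 0L, jitter = list(prob = 0, magnitude = 0),
                    seed = 5)
  sib <- deriveSibling(g$genome, g$truth, ss)
  expect_identical(unname(sib$genome), unname(g$genome))
  expect_true(all(truthEditCounts(sib$truth) == 0))
})

test_that("an explicit deletion shortens the sibling by its length", {
  spec <- genomeSpec(length = 4e4, satellites = list(), transposon = NULL,
                     genes = list(count = 0, lengthRange = c(0, 0)), seed = 6)
  g <- buildGenome(spec)
  ss <- siblingSpec(rates = c(exon = 0, intron = 0, utr5 = 0, utr3 = 0,
                              noncoding = 0),
                    deletions = data.frame(pos = 10000, length = 50),
                    jitter = list(prob = 0, magnitude = 0), seed = 5)
  sib <- deriveSibling(g$genome, g$truth, ss)
  expect_equal(unname(nchar(sib$genome)), unname(nchar(g$genome)) - 50)
  expect_identical(unname(substr(sib$genome, 1, 10000)),
                   unname(substr(g$genome, 1, 10000)))
  expect_identical(unname(substr(sib$genome, 10001, 10100)),
                   unname(substr(g$genome, 10051, 10150)))
})

test_that("overlapping deletions are rejected", {
  spec <- genomeSpec(length = 2e4, satellites = list(), transposon = NULL,
                     genes = list(count = 0, lengthRange = c(0, 0)), seed = 6)
  g <- buildGenome(spec)
  ss <- siblingSpec(deletions = data.frame(pos = c(5000, 5020),
                                           length = c(50, 30)),
                    seed = 5)
  expect_error(deriveSibling(g$genome, g$truth, ss), "overlap")
})

test_that("realized exon substitutions follow the binomial expectation", {
  fx <- fxDivergence()
  cls <- regionClasses(fx$truth)
  nExon <- sum(cls == "exon")
  p <- 0.003
  realized <- truthEditCounts(fx$sib$truth)[["exon"]]
  expect_lt(abs(realized - nExon * p), 3 * sqrt(nExon * p * (1 - p)) + 1)
})

test_that("read counts, errors and determinism behave as specified", {
  set.seed(8)
  g <- randomDna(1e5)
  reads <- simulateReads(g, depth = 40, readLen = 100, errorRate = 0,
                         seed = 9)
  expect_equal(length(reads), 40000)
  ## error-free reads are exact substrings of the template or its rc
  idx <- sample(length(reads), 40)
  ok <- vapply(reads[idx], function(r)
    grepl(r, g, fixed = TRUE) || grepl(revComp(r), g, fixed = TRUE),
    logical(1))
  expect_true(all(ok))
  ## both strands used
  expect_gt(sum(attr(reads, "meta")$strand == -1), 0.4 * length(reads))
  ## determinism
  reads2 <- simulateReads(g, depth = 40, readLen = 100, errorRate = 0,
                          seed = 9)
  expect_identical(reads, reads2)
  expect_error(simulateReads("", depth = 10), "empty")
})

test_that("mean simulated depth matches the request within 3 binomial s.e.", {
  set.seed(10)
  g <- randomDna(5e4)
  reads <- simulateReads(g, depth = 25, errorRate = 0, seed = 11)
  aln <- mapReads(reads, c(genome = g))
  pu <- pileupFromAlignments(aln, c(genome = g), minQ = 20)
  core <- pileupDepth(pu, 1)[200:(5e4 - 200)]
  se <- sqrt(25 / length(core))  # s.e. of the mean of ~Poisson(25) depths
  expect_lt(abs(mean(core) - 25), max(3 * se, 0.25))
})

test_that("truth sets round-trip losslessly through JSON", {
  spec <- genomeSpec(length = 1.5e5, seed = 13)
  g <- buildGenome(spec)
  ss <- siblingSpec(deletions = 3L, seed = 14)
  sib <- deriveSibling(g$genome, g$truth, ss)
  for (tr in list(g$truth, sib$truth)) {
    path <- tempfile(fileext = ".json")
    writeTruthSet(tr, path)
    back <- readTruthSet(path)
    expect_equal(genomeLength(back), genomeLength(tr))
    expect_equal(as.data.frame(truthFeatures(back)),
                 as.data.frame(truthFeatures(tr)))
    expect_equal(as.data.frame(truthDeletions(back)),
                 as.data.frame(truthDeletions(tr)))
    expect_equal(truthEditCounts(back), truthEditCounts(tr))
  }
})

test_that("rRNA pool concentrates variation in the spacer regions", {
  pool <- simulateRrnaPool(nCopies = 30, divergentFraction = 0.3,
                           divergence = 0.05, seed = 83)
  expect_equal(nchar(pool$consensus), sum(pool$regions$end - pool$regions$start))
  spacer <- pool$regions$region %in% c("ETS", "ITS1", "ITS2", "IGS")
  div <- pool$copies[pool$divergent]
  expect_gt(length(div), 0)
  cons <- strsplit(pool$consensus, "")[[1]]
  for (cp in div[1]) {
    chars <- strsplit(cp, "")[[1]]
    diffPos <- which(chars != cons)
    inSpacer <- rep(FALSE, length(cons))
    for (i in which(spacer))
      inSpacer[(pool$regions$start[i] + 1):pool$regions$end[i]] <- TRUE
    expect_true(all(inSpacer[diffPos]))
  }
})
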