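test_that("zero-run detection equals a brute-force scanner exactly", {
  for (s in 1:5) {
    set.seed(s)
    cov <- rpois(5000, 30)
    ## plant zero runs of assorted lengths, some with damaged flanks
    for (i in 1:6) {
      at <- sample(100:4800, 1)
      len <- sample(c(5, 11, 12, 30, 60), 1)
      cov[at:(at + len - 1)] <- 0
    }
    cov[sample(5000, 50)] <- sample(0:3, 50, replace = TRUE)
    got <- findDeletions(cov, rawCoverage = NULL)$calls
    want <- oracleFindDeletions(cov)
    expect_equal(nrow(got), nrow(want), label = sprintf("seed %d", s))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("flank filters reject edge and low-coverage intervals", {
  cov <- rep(30L, 1000)
  cov[5:30] <- 0L           # too close to the edge for a full flank
  cov[500:540] <- 0L        # good call
  cov[800:840] <- 0L        # low left flank
  cov[790:799] <- 15L
  res <- findDeletions(cov)
  expect_equal(res$calls$start, 499)
  expect_equal(res$calls$end, 540)
  expect_equal(res$edge_rejected, 1L)
  expect_equal(res$flank_rejected, 1L)
  ## the raw-coverage mask rejects mappability artifacts
  raw <- rep(30L, 1000)
  res2 <- findDeletions(cov, rawCoverage = raw)
  expect_equal(nrow(res2$calls), 0)
  expect_equal(res2$ambiguous_rejected, 1L)
})

test_that("a planted deletion is called at its exact coordinates", {
  set.seed(111)
  spec <- genomeSpec(length = 6e4, satellites = list(), transposon = NULL,
                     genes = list(count = 0, lengthRange = c(0, 0)),
                     seed = 112)
  g <- buildGenome(spec)
  ss <- siblingSpec(rates = c(exon = 0, intron = 0, utr5 = 0, utr3 = 0,
                              noncoding = 0),
                    deletions = 1L, jitter = list(prob = 0, magnitude = 0),
                    seed = 113)
  sib <- deriveSibling(g$genome, g$truth, ss)
  reads <- simulateReads(sib$genome, depth = 90, errorRate = 0, paired = TRUE,
                         seed = 114)
  aln <- keepPaired(mapReads(reads, g$genome))
  pu <- pileupFromAlignments(aln, g$genome, minQ = 20)
  res <- findDeletions(pileupDepth(pu, 1))
  td <- as.data.frame(truthDeletions(sib$truth))
  expect_equal(nrow(res$calls), 1)
  expect_lte(abs(res$calls$start - (td$start - 1)), 1)
  expect_lte(abs(res$calls$end - td$end), 1)
})

test_that("an identical sibling produces no deletion calls", {
  fx <- fxDivergence()
  reads <- simulateReads(fx$ref, depth = 60, errorRate = 0.002, paired = TRUE,
                         seed = 115)
  aln <- keepPaired(mapReads(reads, fx$ref))
  pu <- pileupFromAlignments(aln, fx$ref, minQ = 20)
  expect_equal(nrow(findDeletions(pileupDepth(pu, 1))$calls), 0)
})

test_that("deletion recall and precision reach 0.95 on planted truth", {
  fx <- fxDivergence()
  res <- findDeletions(pileupDepth(fx$pileup, 1))
  m <- matchDeletions(res$calls, truthDeletions(fx$sib$truth))
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
})

test_that("association test separates random from repeat-adjacent placement", {
  set.seed(121)
  canonical <- randomDna(1500)
  parts <- character(0)
  for (i in 1:12) parts <- c(parts, randomDna(sample(6000:16000, 1)),
                             canonical)
  parts <- c(parts, randomDna(5000))
  asm <- c(genome = paste(parts, collapse = ""))
  lib <- c(te = canonical)
  L <- nchar(asm)
  ## deletions placed uniformly at random: no association
  calls <- data.frame(scaffold = "genome",
                      start = sort(sample(2000:(L - 2000), 25)))
  calls$end <- calls$start + 40
  r1 <- repeatAssociationTest(calls, asm, lib, nPerm = 500, seed = 7)
  expect_gt(r1$p, 0.05)
  expect_lt(abs(r1$observed - r1$nullMean), 0.15)
  ## deletions inside elements: strong association
  fr <- bactrokit:::.cpp_find_hits(unname(asm), canonical, 12L, 100L, 0.8,
                                   1e5)
  mid <- sort(round((fr$rstart + fr$rend) / 2))
  calls2 <- data.frame(scaffold = "genome", start = mid, end = mid + 40)
  r2 <- repeatAssociationTest(calls2, asm, lib, nPerm = 1000, seed = 8)
  expect_lte(r2$p, 0.001)
  expect_equal(r2$observed, 1)
  ## nothing to test
  expect_error(repeatAssociationTest(calls[0, ], asm, lib), "nothing to test")
})

test_that("the permutation p-value is calibrated under the null", {
  set.seed(122)
  canonical <- randomDna(1500)
  parts <- character(0)
  for (i in 1:6) parts <- c(parts, randomDna(sample(5000:12000, 1)),
                            canonical)
  parts <- c(parts, randomDna(4000))
  asm <- c(genome = paste(parts, collapse = ""))
  lib <- c(te = canonical)
  L <- nchar(asm)
  reject <- vapply(1:50, function(i) {
    calls <- data.frame(scaffold = "genome",
                        start = sort(sample(1500:(L - 1600), 15)))
    calls$end <- calls$start + 30
    repeatAssociationTest(calls, asm, lib, nPerm = 199,
                          seed = 1000 + i)$p <= 0.05
  }, logical(1))
  expect_lte(abs(mean(reject) - 0.05), 0.07)
})

test_that("fragment merging follows the distance and double-length rules", {
  lens <- c(genome = 100000L)
  ## two fragments 800 bp apart merge; 1600 bp apart do not
  f1 <- data.frame(scaffold = "genome", start = c(10000L, 11300L),
                   end = c(10500L, 11800L))
  m1 <- mergeElements(f1, scaffoldLens = lens)
  expect_equal(nrow(m1$elements), 1)
  expect_equal(m1$elements$span, 1800)
  f2 <- data.frame(scaffold = "genome", start = c(10000L, 12100L),
                   end = c(10500L, 12600L))
  m2 <- mergeElements(f2, scaffoldLens = lens)
  expect_equal(nrow(m2$elements), 2)
  ## three pieces with 200/400 bp gaps form one element
  f3 <- data.frame(scaffold = "genome",
                   start = c(20000L, 20700L, 21500L),
                   end = c(20500L, 21100L, 21900L))
  m3 <- mergeElements(f3, scaffoldLens = lens)
  expect_equal(nrow(m3$elements), 1)
  expect_equal(m3$elements$n_fragments, 3)
  ## an over-long merged extent splits at its largest internal gap
  f4 <- data.frame(scaffold = "genome",
                   start = c(30000L, 31400L, 32800L),
                   end = c(31300L, 32700L, 34100L))
  m4 <- mergeElements(f4, scaffoldLens = lens)
  expect_gt(nrow(m4$elements), 1)
  ## flankless elements at scaffold edges are dropped and counted
  f5 <- data.frame(scaffold = "genome", start = 100L, end = 600L)
  m5 <- mergeElements(f5, scaffoldLens = lens)
  expect_equal(nrow(m5$elements), 0)
  expect_equal(m5$dropped_no_flank, 1L)
})

test_that("span comparison detects planted jitter and is null without it", {
  fx <- fxSpans()
  expect_gte(nrow(fx$elements), 10)
  jit <- compareSpans(fx$elements, fx$ref, fx$jittered$genome, seed = 43)
  expect_gt(jit$meanElement, jit$meanControl)
  expect_lt(jit$p, 0.01)
  flat <- compareSpans(fx$elements, fx$ref, fx$flat$genome, seed = 45)
  expect_gt(flat$p, 0.05)
})

test_that("elements whose flanks land on two sibling contigs are excluded", {
  fx <- fxSpans()
  el <- fx$elements[3, , drop = FALSE]
  ## split the sibling inside the element: its flanks end up on two contigs
  cut <- el$start + 200L
  sib2 <- c(c1 = substr(fx$flat$genome, 1, cut),
            c2 = substr(fx$flat$genome, cut + 1, nchar(fx$flat$genome)))
  res <- compareSpans(el, fx$ref, sib2, nControls = 2, seed = 46)
  expect_true(is.na(res$spans$sibling_span[1]))
  expect_equal(res$excluded, 1L)
})
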