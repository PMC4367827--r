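test_that("fixed-difference calling honours the depth and frequency gates", {
  ref <- c(chr = strrep("ACGT", 30))
  mkPileup <- function(nref, nalt, pos = 60L) {
    base <- data.frame(qname = "x", rname = "chr", rid = 1L, pos = pos,
                       strand = 1L, cigar = "1M", mapq = 60L, nm = 0L,
                       seq = "A", stringsAsFactors = FALSE)
    aln <- base[rep(1, nref + nalt), ]
    aln$seq <- c(rep(substr(ref, pos + 1, pos + 1), nref), rep("T", nalt))
    aln$nm <- c(rep(0L, nref), rep(1L, nalt))
    pileupFromAlignments(aln, ref, minQ = 20)
  }
  ## 40x with 39 alternate reads: a call
  calls <- callFixedDifferences(mkPileup(1, 39), ref)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$alt, "T")
  expect_gte(calls$freq, 0.9)
  ## 9x all alternate: below the depth floor, no call
  expect_equal(nrow(callFixedDifferences(mkPileup(0, 9), ref)), 0)
  ## 40x with 30 alternate (75%): below the homozygous frequency, no call
  expect_equal(nrow(callFixedDifferences(mkPileup(10, 30), ref)), 0)
  ## empty pileup: empty result
  noAln <- data.frame(qname = character(0), rname = character(0),
                      rid = integer(0), pos = integer(0), strand = integer(0),
                      cigar = character(0), mapq = integer(0), nm = integer(0),
                      seq = character(0))
  empty <- pileupFromAlignments(noAln, ref, minQ = 20)
  expect_equal(nrow(callFixedDifferences(empty, ref)), 0)
})

test_that("planted substitutions are recovered within binomial error", {
  fx <- fxDivergence()
  planted <- sum(truthEditCounts(fx$sib$truth))
  recovered <- sum(fx$calls$type == "substitution")
  expect_lt(abs(recovered - planted), 3 * sqrt(planted))
})

test_that("per-region rates recover the planted pattern", {
  fx <- fxDivergence()
  part <- partitionByRegion(fx$calls, fx$truth, fx$pileup, fx$ref)
  rates <- setNames(part$rates$rate, part$rates$class)
  callable <- setNames(part$rates$callable, part$rates$class)
  planted <- c(exon = 0.003, intron = 0.006, noncoding = 0.007)
  for (k in names(planted)) {
    n <- callable[[k]]
    p <- planted[[k]]
    expect_lt(abs(rates[[k]] - p), 3 * sqrt(p * (1 - p) / n),
              label = sprintf("%s rate", k))
  }
  ## qualitative ordering as in the sibling-species comparison
  expect_gt(rates[["intron"]], rates[["exon"]])
  expect_gt(rates[["noncoding"]], rates[["exon"]])
  ## callable sites partition across classes
  expect_equal(sum(part$rates$callable),
               sum(pileupDepth(fx$pileup, 1) >= 10))
})

test_that("a zero-rate sibling yields all-zero rates", {
  spec <- genomeSpec(length = 5e4, satellites = list(), transposon = NULL,
                     genes = list(count = 4, lengthRange = c(1200, 1600)),
                     seed = 101)
  g <- buildGenome(spec)
  ss <- siblingSpec(rates = c(exon = 0, intron = 0, utr5 = 0, utr3 = 0,
                              noncoding = 0),
                    deletions = 0L, jitter = list(prob = 0, magnitude = 0),
                    seed = 102)
  sib <- deriveSibling(g$genome, g$truth, ss)
  reads <- simulateReads(sib$genome, depth = 30, errorRate = 0, paired = TRUE,
                         seed = 103)
  aln <- keepPaired(mapReads(reads, g$genome))
  pu <- pileupFromAlignments(aln, g$genome, minQ = 20)
  calls <- callFixedDifferences(pu, g$genome)
  part <- partitionByRegion(calls, g$truth, pu, g$genome)
  expect_true(all(part$rates$substitutions == 0))
})

test_that("region classes follow the exon > UTR > intron precedence", {
  gr <- GenomicRanges::GRanges("genome",
    IRanges::IRanges(start = c(11, 11, 31), end = c(40, 20, 40)),
    strand = "+")
  gr$type <- c("intron", "exon", "utr5")
  gr$id <- "g1"
  gr$phase <- c(NA, 0L, NA)
  gr$monomer <- NA_character_
  truth <- new("TruthSet", genomeLength = 60, features = gr,
               editCounts = numeric(0),
               deletions = GenomicRanges::GRanges(), jitter = data.frame())
  cls <- regionClasses(truth)
  expect_equal(as.character(cls[15]), "exon")    # exon over intron
  expect_equal(as.character(cls[35]), "utr5")    # utr over intron
  expect_equal(as.character(cls[25]), "intron")
  expect_equal(as.character(cls[5]), "noncoding")
})

test_that("coding effects match the worked codon examples", {
  expect_identical(classifyCodingEffect("CAA", "TAA"), "stop_gain")
  expect_identical(classifyCodingEffect("CAA", "TAC"), "stop_compensated")
  expect_identical(classifyCodingEffect("GCT", "GCC"), "synonymous")
  expect_identical(classifyCodingEffect("AAA", "AAA"), "none")
  expect_identical(classifyCodingEffect("AAA", "AGA"), "nonsynonymous")
})

test_that("coding effects agree with the exhaustive oracle on all 64 x 64", {
  codons <- names(Biostrings::GENETIC_CODE)
  for (ref in codons) {
    got <- vapply(codons, function(alt) classifyCodingEffect(ref, alt),
                  character(1))
    want <- vapply(codons, function(alt) oracleCodingEffect(ref, alt),
                   character(1))
    expect_identical(got, want, label = ref)
  }
})

test_that("neutral substitutions give an opportunity-normalized ratio near 1", {
  fx <- fxDivergence()
  part <- partitionByRegion(fx$calls, fx$truth, fx$pileup, fx$ref)
  expect_gt(part$coding$synonymous, 10)
  expect_lt(abs(part$coding$dnds_normalized - 1), 0.6)
  ## raw rates are per callable exon site
  exonCallable <- part$rates$callable[part$rates$class == "exon"]
  expect_equal(part$coding$dN, part$coding$nonsynonymous / exonCallable)
})

test_that("rRNA profiles localise heterogeneity and recover pool ratios", {
  profileOf <- function(divergence, seed) {
    pool <- simulateRrnaPool(nCopies = 30, divergentFraction = 0.3,
                             divergence = divergence, seed = seed)
    reads <- unlist(lapply(seq_along(pool$copies), function(i)
      simulateReads(pool$copies[i], depth = 4, errorRate = 0,
                    seed = seed + i)))
    names(reads) <- sprintf("r%06d", seq_along(reads))
    aln <- mapReads(reads, c(unit = pool$consensus))
    pu <- pileupFromAlignments(aln, c(unit = pool$consensus), minQ = 20)
    list(pool = pool,
         prof = rrnaVariantProfile(pu, pool$consensus, window = 100,
                                   regions = pool$regions))
  }
  a <- profileOf(0.05, 83)
  site <- a$prof$site
  byRegion <- tapply(site$variant_fraction, site$region, mean, na.rm = TRUE)
  spacers <- c("ETS", "ITS1", "ITS2", "IGS")
  genes <- c("18S", "5.8S", "2S", "28S")
  expect_true(all(byRegion[spacers] > 0.003))
  expect_true(all(byRegion[genes] < 1e-3))
  ## error-free single-haplotype pool: zero everywhere
  b <- profileOf(0, 90)
  expect_true(all(b$prof$site$variant_fraction[b$prof$site$depth > 0] == 0))
  ## two pools with 2:1 planted heterogeneity recover the ratio
  c2 <- profileOf(0.025, 97)
  r <- mean(tapply(site$variant_fraction, site$region, mean,
                   na.rm = TRUE)[spacers]) /
       mean(tapply(c2$prof$site$variant_fraction, c2$prof$site$region, mean,
                   na.rm = TRUE)[spacers])
  expect_lt(abs(r - 2), 0.7)
})
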