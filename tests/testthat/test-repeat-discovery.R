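test_that("greedy extension equals the brute-force oracle exactly", {
  set.seed(51)
  ## reads tiling a high-count unique 200-mer over low-count background
  core <- randomDna(200)
  reads <- c(rep(substring(core, 1:(200 - 30 + 1), 30:200), 3),
             vapply(1:50, function(i) randomDna(30), character(1)))
  tab <- countKmers(reads, 12, "as-read")
  lib <- kmerExtend(tab, topN = 500, minExtension = 50)
  oracle <- oracleKmerExtend(tab@kmers, tab@counts, 12, 500, 62)
  expect_identical(unname(repeatSequences(lib)), oracle)
  ## the dominant product reproduces the planted 200-mer
  expect_true(core %in% repeatSequences(lib))
})

test_that("extension is deterministic under all-equal counts", {
  set.seed(52)
  s <- randomDna(400)
  kmers <- unique(substring(s, 1:(400 - 11), 12:400))
  tab <- new("KmerTable", k = 12L, kmers = sort(kmers),
             counts = rep(1, length(kmers)), strandPolicy = "as-read")
  l1 <- kmerExtend(tab, topN = 1000, minExtension = 50)
  l2 <- kmerExtend(tab, topN = 1000, minExtension = 50)
  expect_identical(repeatSequences(l1), repeatSequences(l2))
  oracle <- oracleKmerExtend(tab@kmers, tab@counts, 12, 1000, 62)
  expect_identical(unname(repeatSequences(l1)), oracle)
})

test_that("a tandem monomer extension stops on re-meeting its own k-mers", {
  reads <- fxTandemReads()
  tab <- countKmers(reads, 18, "as-read")
  lib <- kmerExtend(tab, topN = 100, minExtension = 50)
  info <- repeatInfo(lib)
  ## walk length ~ monomer + k - 1, stopped by the already-used rule
  expect_equal(nchar(repeatSequences(lib)[[1]]), 166 + 17)
  expect_equal(info$stop_right[1], "reused")
  expect_equal(info$stop_left[1], "reused")
  ## monomer recovered up to rotation
  id <- rotationIdentity(substr(repeatSequences(lib)[[1]], 1, 166),
                         fxMonomer())
  expect_gte(id, 0.99)
})

test_that("align-and-extend grows a seed to the full planted element", {
  set.seed(53)
  canonical <- randomDna(1500)
  parts <- character(0)
  for (i in 1:20) parts <- c(parts, randomDna(sample(500:2000, 1)), canonical)
  asm <- c(genome = paste(parts, collapse = ""))
  res <- alignAndExtend(substr(canonical, 601, 900), asm)
  expect_gte(res$support, 3)
  expect_equal(nchar(res$sequence), 1500)
  expect_identical(res$sequence, canonical)
})

test_that("align-and-extend respects the support floor and consensus gate", {
  set.seed(54)
  canonical <- randomDna(1500)
  seed <- substr(canonical, 601, 900)
  ## planted once: support < 3, returned unchanged
  asm1 <- c(g = paste0(randomDna(2000), canonical, randomDna(2000)))
  r1 <- alignAndExtend(seed, asm1)
  expect_identical(r1$sequence, seed)
  ## zero matches: warning, unchanged
  expect_warning(r0 <- alignAndExtend(seed, c(g = randomDna(5000))),
                 "no assembly matches")
  expect_identical(r0$sequence, seed)
  ## 30%-divergent flanks: below the 60% column consensus, no real growth
  parts <- character(0)
  fl <- paste0(substr(canonical, 1, 600), substr(canonical, 901, 1500))
  for (i in 1:10) {
    ch <- strsplit(fl, "")[[1]]
    mut <- runif(length(ch)) < 0.3
    ch[mut] <- vapply(ch[mut], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    flz <- paste(ch, collapse = "")
    parts <- c(parts, randomDna(800),
               paste0(substr(flz, 1, 600), seed, substr(flz, 601, 1200)))
  }
  r2 <- alignAndExtend(seed, c(g = paste(parts, collapse = "")))
  expect_lt(r2$extended, 20)
})

test_that("finalization installs majorities, culls redundancy, reports stats", {
  set.seed(55)
  mono <- fxMonomer()
  te <- randomDna(1500)
  genome <- paste0(randomDna(20000), strrep(mono, 150), randomDna(15000),
                   te, randomDna(10000), te, randomDna(10000))
  reads <- simulateReads(c(g = genome), depth = 30, errorRate = 0.002,
                         seed = 56)
  repFrac <- (166 * 150 + 1500 * 2) / nchar(genome)
  ## a wrong consensus base is corrected by the read majority, an exact
  ## duplicate and a contained fragment are culled
  monoBad <- mono
  substr(monoBad, 83, 83) <- setdiff(c("A", "C", "G", "T"),
                                     substr(mono, 83, 83))[1]
  lib <- c(sat = monoBad, te = te, tedup = te, frag = substr(te, 101, 400))
  fin <- finalizeConsensus(lib, reads)
  expect_identical(repeatSequences(fin)[["sat"]], mono)
  expect_false("tedup" %in% names(repeatSequences(fin)))
  expect_false("frag" %in% names(repeatSequences(fin)))
  expect_lt(abs(repeatInfo(fin)$mapped_fraction[1] - repFrac), 0.02)
  expect_lt(repeatInfo(fin)$mean_nm[1], 1)
  ## post-cull pairwise identities sit at or below the cull threshold
  seqs <- repeatSequences(fin)
  for (i in seq_along(seqs)) for (j in seq_along(seqs)) {
    if (i < j) expect_lte(bactrokit:::.pairIdentity(seqs[[i]], seqs[[j]]), 0.8)
  }
})

test_that("species-specific variants are incorporated above 50% frequency", {
  set.seed(57)
  mono <- fxMonomer()
  te <- randomDna(1500)
  lib <- c(sat = mono, te = te)
  ## sibling repeat diverged at ~1%
  ch <- strsplit(te, "")[[1]]
  mut <- sample(1500, 15)
  ch[mut] <- vapply(ch[mut], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  teSib <- paste(ch, collapse = "")
  sibGenome <- paste0(randomDna(15000), strrep(mono, 60), randomDna(10000),
                      teSib, randomDna(8000), teSib, randomDna(8000))
  sibReads <- simulateReads(c(g = sibGenome), depth = 40, errorRate = 0.002,
                            seed = 58)
  sv <- speciesSpecificVariants(lib, sibReads)
  mism <- sum(strsplit(repeatSequences(sv)[["te"]], "")[[1]] !=
              strsplit(teSib, "")[[1]])
  expect_lte(mism / 1500, 0.001)
  expect_identical(repeatSequences(sv)[["sat"]], mono)
  ## zero-coverage entries are flagged, not altered
  sv2 <- speciesSpecificVariants(c(lib, orphan = randomDna(400)), sibReads)
  expect_true(repeatInfo(sv2)$flagged[repeatInfo(sv2)$id == "orphan"])
})

test_that("a site at exactly 50% frequency is left unchanged", {
  set.seed(59)
  rep1 <- randomDna(300)
  alt <- rep1
  substr(alt, 150, 150) <- setdiff(c("A", "C", "G", "T"),
                                   substr(rep1, 150, 150))[1]
  ## equal numbers of reads carrying each allele
  mk <- function(s) substring(s, seq(1, 201, by = 10), seq(100, 300, by = 10))
  reads <- c(mk(rep1), mk(alt))
  names(reads) <- sprintf("r%03d", seq_along(reads))
  sv <- speciesSpecificVariants(c(x = rep1), reads)
  expect_identical(repeatSequences(sv)[["x"]], rep1)
})

test_that("discovery recovers planted satellite and transposon at >= 99%", {
  fx <- fxDiscovery()
  tab <- countKmers(fx$reads, 18, "as-read")
  lib <- kmerExtend(tab, topN = 50000, minExtension = 50)
  seqs <- repeatSequences(lib)
  ## satellite: a monomer-length circular product, identical up to rotation
  satLike <- seqs[abs(nchar(seqs) - (166 + 17)) <= 2]
  expect_gte(length(satLike), 1)
  ids <- vapply(satLike, function(s)
    rotationIdentity(substr(s, 1, 166), fx$monomer), numeric(1))
  expect_gte(max(ids), 0.99)
  ## transposon: extension fragments + align-and-extend reach the core
  teLike <- seqs[nchar(seqs) >= 300]
  teLike <- teLike[vapply(teLike, function(s)
    grepl(substr(s, 1, 100), fx$te, fixed = TRUE) ||
    grepl(revComp(substr(s, 1, 100)), fx$te, fixed = TRUE), logical(1))]
  expect_gte(length(teLike), 1)
  seed <- substr(teLike[[which.max(nchar(teLike))]], 1, 300)
  grown <- alignAndExtend(seed, fx$genome)
  h <- bactrokit:::.cpp_find_hits(fx$te, grown$sequence, 12L, 500L, 0.9, 100L)
  expect_gte(max(h$qend - h$qstart), 0.99 * 1500)
  expect_gte(max(h$identity), 0.99)
})
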