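# Shared fixtures, built once per test run and memoised.  Everything is
# generated in code under fixed seeds; the heavier read sets are reused
# across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# a 166 bp monomer used across satellite tests
fxMonomer <- function() fixture("monomer", function() {
  set.seed(5)
  randomDna(166)
})

# error-free reads from a long head-to-tail array of the monomer
fxTandemReads <- function() fixture("tandemReads", function() {
  simulateReads(strrep(fxMonomer(), 60), depth = 30, errorRate = 0, seed = 2)
})

# repeat-discovery genome: satellite array + transposon copies (some
# fragmented) + unique background; 30x error-free reads
fxDiscovery <- function() fixture("discovery", function() {
  set.seed(31)
  mono <- fxMonomer()
  te <- randomDna(1500)
  parts <- list(randomDna(20000), strrep(mono, 250))
  for (i in 1:6) parts <- c(parts, randomDna(sample(3000:6000, 1)), te)
  for (i in 1:6) {  # fragmented copies: two pieces, small gap
    cut <- sample(400:1100, 1)
    parts <- c(parts, randomDna(sample(3000:6000, 1)),
               substr(te, 1, cut), randomDna(sample(100:300, 1)),
               substr(te, cut + 1, 1500))
  }
  parts <- c(parts, randomDna(15000))
  genome <- c(genome = paste(unlist(parts), collapse = ""))
  reads <- simulateReads(genome, depth = 30, errorRate = 0, seed = 32)
  list(genome = genome, monomer = mono, te = te, reads = reads)
})

# divergence genome: gene models only (uniquely mappable), sibling with the
# emulated per-region rates and 20 planted deletions, deep paired reads
fxDivergence <- function() fixture("divergence", function() {
  spec <- genomeSpec(length = 3e5, satellites = list(),
                     transposon = list(length = 1500, copies = 0,
                                       fragmentation = 0),
                     genes = list(count = 25, lengthRange = c(1500, 2500)),
                     seed = 91)
  g <- buildGenome(spec)
  ss <- siblingSpec(deletions = 20L,
                    jitter = list(prob = 0, magnitude = 0), seed = 92)
  sib <- deriveSibling(g$genome, g$truth, ss)
  reads <- simulateReads(sib$genome, depth = 90, errorRate = 0.002,
                         paired = TRUE, seed = 93)
  aln <- keepPaired(mapReads(reads, g$genome))
  pu <- pileupFromAlignments(aln, g$genome, minQ = 20)
  calls <- callFixedDifferences(pu, g$genome)
  list(ref = g$genome, truth = g$truth, sib = sib, aln = aln, pileup = pu,
       calls = calls)
})

# transposon-span genome: intact + fragmented copies, jittered and
# jitter-free siblings
fxSpans <- function() fixture("spans", function() {
  spec <- genomeSpec(length = 3e5, satellites = list(),
                     transposon = list(length = 1500, copies = 14,
                                       fragmentation = 0.4),
                     genes = list(count = 5, lengthRange = c(1200, 1800)),
                     seed = 41)
  g <- buildGenome(spec)
  canonical <- attr(g$truth, "transposonCanonical")
  fr <- bactrokit:::.cpp_find_hits(unname(g$genome), canonical, 12L, 100L,
                                   0.8, 100000L)
  frags <- data.frame(scaffold = "genome", start = fr$rstart, end = fr$rend)
  me <- mergeElements(frags, scaffoldLens = nchar(g$genome))
  rates0 <- c(exon = 0, intron = 0, utr5 = 0, utr3 = 0, noncoding = 0.002)
  jit <- deriveSibling(g$genome, g$truth,
                       siblingSpec(rates = rates0, deletions = 0L,
                                   jitter = list(prob = 0.6, magnitude = 50L),
                                   seed = 42))
  flat <- deriveSibling(g$genome, g$truth,
                        siblingSpec(rates = rates0, deletions = 0L,
                                    jitter = list(prob = 0, magnitude = 0),
                                    seed = 44))
  list(ref = g$genome, truth = g$truth, canonical = canonical,
       elements = me$elements, jittered = jit, flat = flat)
})

# genome-size recovery conditions: 2 Mbp genome, 35x reads at 0.5% error
fxGenomeSize <- function() fixture("genomeSize", function() {
  spec <- genomeSpec(length = 2e6, satellites = list(),
                     transposon = list(length = 1500, copies = 0,
                                       fragmentation = 0),
                     genes = list(count = 60, lengthRange = c(1500, 2500)),
                     seed = 11)
  g <- buildGenome(spec)
  reads <- simulateReads(g$genome, depth = 35, errorRate = 0.005, seed = 12)
  tf <- truthFeatures(g$truth)
  ids <- unique(tf$id[tf$type == "exon"])
  segs <- vapply(ids, function(gid) {
    rr <- range(GenomicRanges::ranges(tf[tf$id == gid]))
    substr(g$genome, IRanges::start(rr) - 100, IRanges::end(rr) + 100)
  }, character(1))
  list(genome = g$genome, truth = g$truth, reads = reads,
       segments = transcriptSegments(setNames(segs, ids)))
})

# reciprocal-overlap matching of deletion calls against planted truth
matchDeletions <- function(calls, truthDel, minOverlap = 0.8) {
  td <- as.data.frame(truthDel)
  td$start0 <- td$start - 1
  if (nrow(calls) == 0 || nrow(td) == 0) {
    return(list(recall = 0, precision = NA_real_))
  }
  f <- function(i, j) {
    o <- pmin(calls$end[i], td$end[j]) - pmax(calls$start[i], td$start0[j])
    o / pmax(calls$end[i] - calls$start[i], td$end[j] - td$start0[j])
  }
  hit <- outer(seq_len(nrow(calls)), seq_len(nrow(td)), f) >= minOverlap
  list(recall = mean(apply(hit, 2, any)), precision = mean(apply(hit, 1, any)))
}

# brute-force k-mer counter (independent oracle)
oracleCountKmers <- function(seqs, k, canonical = FALSE) {
  acc <- new.env(parent = emptyenv())
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      km <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", km)) next
      if (canonical) km <- min(km, revComp(km))
      assign(km, (if (exists(km, acc)) get(km, acc) else 0) + 1, acc)
    }
  }
  keys <- sort(ls(acc))
  setNames(vapply(keys, get, numeric(1), envir = acc), keys)
}

# brute-force greedy k-mer extension (independent oracle, string-hash based)
oracleKmerExtend <- function(kmers, counts, k, topN, minTotalLen) {
  tab <- setNames(as.numeric(counts), kmers)
  used <- new.env(parent = emptyenv())
  ord <- order(-counts, kmers)
  out <- character(0)
  processed <- 0
  for (i in ord) {
    if (processed >= topN) break
    processed <- processed + 1
    seed <- kmers[i]
    if (exists(seed, used)) next
    assign(seed, TRUE, used)
    seq <- seed
    repeat {  # rightwards
      suf <- substr(seq, nchar(seq) - k + 2, nchar(seq))
      cand <- paste0(suf, c("A", "C", "G", "T"))
      cand <- cand[cand %in% names(tab)]
      if (!length(cand)) break
      best <- cand[order(-tab[cand], cand)][1]
      if (exists(best, used)) break
      assign(best, TRUE, used)
      seq <- paste0(seq, substr(best, k, k))
    }
    repeat {  # leftwards
      pre <- substr(seq, 1, k - 1)
      cand <- paste0(c("A", "C", "G", "T"), pre)
      cand <- cand[cand %in% names(tab)]
      if (!length(cand)) break
      best <- cand[order(-tab[cand], cand)][1]
      if (exists(best, used)) break
      assign(best, TRUE, used)
      seq <- paste0(substr(best, 1, 1), seq)
    }
    if (nchar(seq) >= minTotalLen) out <- c(out, seq)
  }
  out
}

# brute-force zero-run deletion scanner (independent oracle)
oracleFindDeletions <- function(cov, minLen = 10, flankLen = 10,
                                flankMinCov = 20, noiseFloor = 2) {
  zero <- cov <= noiseFloor
  out <- list()
  i <- 1
  n <- length(cov)
  while (i <= n) {
    if (!zero[i]) { i <- i + 1; next }
    j <- i
    while (j < n && zero[j + 1]) j <- j + 1
    len <- j - i + 1
    if (len > minLen && i - flankLen >= 1 && j + flankLen <= n &&
        min(cov[(i - flankLen):(i - 1)]) > flankMinCov &&
        min(cov[(j + 1):(j + flankLen)]) > flankMinCov) {
      out[[length(out) + 1]] <- c(start = i - 1, end = j)
    }
    i <- j + 1
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  as.data.frame(do.call(rbind, out))
}

# independent codon-effect oracle via full enumeration of intermediates
oracleCodingEffect <- function(ref, alt) {
  gc <- Biostrings::GENETIC_CODE
  if (ref == alt) return("none")
  if (gc[[alt]] == "*") return("stop_gain")
  if (gc[[alt]] == gc[[ref]]) return("synonymous")
  rc <- strsplit(ref, "")[[1]]
  ac <- strsplit(alt, "")[[1]]
  d <- which(rc != ac)
  if (length(d) >= 2) {
    for (p in d) {
      one <- rc
      one[p] <- ac[p]
      if (gc[[paste(one, collapse = "")]] == "*") return("stop_compensated")
    }
  }
  "nonsynonymous"
}
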