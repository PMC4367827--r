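## Fixed-difference calling between a reference species and sibling read
## sets, substitution-rate partitioning by genomic region, joint-codon
## synonymous / non-synonymous classification with compensated-stop logic,
## and rRNA per-site variant profiling.

#' Call fixed differences from a pileup
#'
#' A site is a fixed (near-homozygous) difference when its depth is at least
#' `minDepth` and the most frequent non-reference allele reaches
#' `homozygousFreq` of the depth.  Deletion runs of 1-2 bp and insertion
#' evidence passing the same rule are reported as indel calls; longer
#' zero-coverage structures are the deletion caller's business, not this
#' one's.
#'
#' @param pileup a [Pileup] built from alignments passing the q > 20 filter.
#' @param reference named character vector of reference sequences.
#' @param minDepth minimum site depth (default 10).
#' @param homozygousFreq alternate-allele frequency for a homozygous call
#'   (default 0.9).
#' @return data.frame: `scaffold`, `pos` (0-based), `ref`, `alt`, `freq`,
#'   `depth`, `type` (`substitution`, `deletion`, `insertion`), `len`.
#' @export
callFixedDifferences <- function(pileup, reference, minDepth = 10L,
                                 homozygousFreq = 0.9) {
  out <- list()
  for (ri in seq_along(pileup@refnames)) {
    rn <- pileup@refnames[ri]
    refseq <- toupper(reference[[rn]])
    depth <- pileupDepth(pileup, ri)
    if (!length(depth)) next
    cnt <- baseCounts(pileup, ri)
    refChars <- strsplit(refseq, "")[[1]]
    refIdx <- match(refChars, DNA_BASES)
    ## mask the reference allele, find the top alternate
    cntAlt <- cnt
    ok <- !is.na(refIdx)
    cntAlt[cbind(refIdx[ok], which(ok))] <- -1L
    altIdx <- max.col(t(cntAlt), ties.method = "first")
    altN <- cnt[cbind(altIdx, seq_along(depth))]
    call <- depth >= minDepth & altN / pmax(depth, 1L) >= homozygousFreq &
      altN > 0L
    if (any(call)) {
      w <- which(call)
      out[[length(out) + 1L]] <- data.frame(
        scaffold = rn, pos = w - 1L, ref = refChars[w],
        alt = DNA_BASES[altIdx[w]], freq = altN[w] / depth[w],
        depth = depth[w], type = "substitution", len = 0L,
        stringsAsFactors = FALSE)
    }
    ## short deletions: per-site del evidence, merged into runs
    ind <- indelEvidence(pileup, ri)
    totHere <- depth + ind$del
    delCall <- totHere >= minDepth & ind$del / pmax(totHere, 1L) >= homozygousFreq
    if (any(delCall)) {
      r <- rle(delCall)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values & r$lengths <= 2L)
      for (j in runs) {
        w <- starts[j]
        out[[length(out) + 1L]] <- data.frame(
          scaffold = rn, pos = w - 1L, ref = refChars[w], alt = "-",
          freq = ind$del[w] / totHere[w], depth = totHere[w],
          type = "deletion", len = r$lengths[j], stringsAsFactors = FALSE)
      }
    }
    insCall <- depth >= minDepth & ind$ins / pmax(depth, 1L) >= homozygousFreq &
      ind$ins > 0L
    if (any(insCall)) {
      w <- which(insCall)
      lens <- pmax(1L, round(ind$ins_len[w] / ind$ins[w]))
      sel <- lens <= 2L
      if (any(sel)) {
        out[[length(out) + 1L]] <- data.frame(
          scaffold = rn, pos = w[sel] - 1L, ref = refChars[w[sel]],
          alt = "+", freq = ind$ins[w[sel]] / depth[w[sel]],
          depth = depth[w[sel]], type = "insertion", len = lens[sel],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(scaffold = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      freq = numeric(0), depth = integer(0),
                      type = character(0), len = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$scaffold, res$pos), , drop = FALSE]
}

#' Classify the coding effect of substitutions within one codon
#'
#' All fixed differences falling in a codon are applied jointly before
#' translation.  `stop_gain` requires the jointly mutated codon to be a stop;
#' `stop_compensated` flags codons where one substitution taken in isolation
#' would create a stop but a second substitution in the same codon negates
#' it.
#'
#' @param refCodon,altCodon three-letter codons (ACGT).
#' @return one of `"none"`, `"synonymous"`, `"nonsynonymous"`,
#'   `"stop_gain"`, `"stop_compensated"`.
#' @export
classifyCodingEffect <- function(refCodon, altCodon) {
  gc <- Biostrings::GENETIC_CODE
  refCodon <- toupper(refCodon)
  altCodon <- toupper(altCodon)
  if (nchar(refCodon) != 3L || nchar(altCodon) != 3L)
    stop("codons must be 3 bp")
  if (refCodon == altCodon) return("none")
  aaRef <- gc[[refCodon]]
  aaAlt <- gc[[altCodon]]
  if (aaAlt == "*") return("stop_gain")
  if (identical(aaAlt, aaRef)) return("synonymous")
  ## would any single substitution alone have produced a stop?
  rc <- strsplit(refCodon, "")[[1]]
  ac <- strsplit(altCodon, "")[[1]]
  diffs <- which(rc != ac)
  if (length(diffs) >= 2L) {
    for (d in diffs) {
      one <- rc
      one[d] <- ac[d]
      if (gc[[paste(one, collapse = "")]] == "*") return("stop_compensated")
    }
  }
  "nonsynonymous"
}

## spliced CDS bookkeeping: genomic position (0-based) -> CDS index, codon
## and within-codon offset for every annotated gene
.cdsMap <- function(truthOrGr) {
  gr <- if (is(truthOrGr, "TruthSet")) truthFeatures(truthOrGr) else truthOrGr
  cds <- gr[gr$type == "exon"]
  if (!length(cds)) return(NULL)
  split(cds, cds$id)
}

#' Partition fixed differences by genomic region
#'
#' Region classes partition every reference base (precedence
#' exon > 5' UTR > 3' UTR > intron > non-coding); per-class rates use
#' *callable* sites (depth >= `minDepth`) as denominators so they are
#' reproducible.  Within coding sequence, substitutions are classified on
#' the jointly mutated codon (strand- and phase-aware); 1-2 bp indels count
#' as non-synonymous changes.  Both the raw per-callable-site dN and dS
#' rates and the per-site-opportunity-normalized ratio are reported.
#'
#' @param calls a [callFixedDifferences()] data.frame (single scaffold).
#' @param truth a [TruthSet] (or GRanges with `type`/`id`/`phase` columns)
#'   providing the annotation.
#' @param pileup the [Pileup] the calls came from.
#' @param reference named character vector with the reference sequence.
#' @param minDepth callable-site depth floor (default 10).
#' @return list: `rates` data.frame (class, callable, substitutions, rate),
#'   `coding` list (counts and rates of synonymous / nonsynonymous calls,
#'   novel and compensated stops, `dnds_raw`, `dnds_normalized`).
#' @export
partitionByRegion <- function(calls, truth, pileup, reference,
                              minDepth = 10L) {
  refseq <- toupper(reference[[1]])
  L <- nchar(refseq)
  cls <- regionClasses(truth, L)
  depth <- pileupDepth(pileup, 1L)
  callable <- depth >= minDepth
  subs <- calls[calls$type == "substitution", , drop = FALSE]
  clsOfCall <- cls[subs$pos + 1L]
  rates <- data.frame(
    class = levels(cls),
    callable = vapply(levels(cls), function(k) sum(callable[cls == k]),
                      numeric(1)),
    substitutions = vapply(levels(cls), function(k) sum(clsOfCall == k),
                           numeric(1)))
  rates$rate <- ifelse(rates$callable > 0,
                       rates$substitutions / rates$callable, NA_real_)

  ## joint-codon coding effects
  cdsByGene <- .cdsMap(truth)
  nSyn <- nNon <- nStop <- nComp <- 0L
  effects <- list()
  if (!is.null(cdsByGene) && nrow(subs)) {
    for (gid in names(cdsByGene)) {
      g <- cdsByGene[[gid]]
      g <- g[order(GenomicRanges::start(g))]
      strand <- as.character(GenomicRanges::strand(g))[1]
      ## spliced CDS genomic positions 5'->3'
      gpos <- unlist(lapply(seq_along(g), function(i)
        GenomicRanges::start(g)[i]:GenomicRanges::end(g)[i]))
      if (strand == "-") gpos <- rev(gpos)
      cdsSeq <- strsplit(refseq, "")[[1]][gpos]
      if (strand == "-")
        cdsSeq <- c(A = "T", C = "G", G = "C", T = "A")[cdsSeq]
      nCodon <- length(gpos) %/% 3L
      inCds <- match(subs$pos + 1L, gpos)
      hit <- which(!is.na(inCds))
      if (!length(hit)) next
      codonIdx <- (inCds[hit] - 1L) %/% 3L
      for (ci in unique(codonIdx)) {
        if (ci >= nCodon) next
        take <- hit[codonIdx == ci]
        ref3 <- cdsSeq[ci * 3L + 1:3]
        alt3 <- ref3
        for (t in take) {
          o <- (inCds[t] - 1L) %% 3L
          b <- subs$alt[t]
          if (strand == "-") b <- c(A = "T", C = "G", G = "C", T = "A")[b]
          alt3[o + 1L] <- b
        }
        eff <- classifyCodingEffect(paste(ref3, collapse = ""),
                                    paste(alt3, collapse = ""))
        effects[[length(effects) + 1L]] <- data.frame(
          gene = gid, codon = ci, n_subs = length(take), effect = eff,
          stringsAsFactors = FALSE)
        ## count per substitution for syn/nonsyn rates, per codon for stops
        if (eff == "synonymous") nSyn <- nSyn + length(take)
        else if (eff == "nonsynonymous") nNon <- nNon + length(take)
        else if (eff == "stop_gain") { nStop <- nStop + 1L
                                       nNon <- nNon + length(take) }
        else if (eff == "stop_compensated") { nComp <- nComp + 1L
                                              nNon <- nNon + length(take) }
      }
    }
  }
  ## 1-2 bp indels inside CDS are non-synonymous changes
  indels <- calls[calls$type %in% c("deletion", "insertion"), , drop = FALSE]
  if (nrow(indels)) {
    inExon <- cls[indels$pos + 1L] == "exon"
    nNon <- nNon + sum(inExon)
  }
  exonCallable <- rates$callable[rates$class == "exon"]
  dN <- if (exonCallable > 0) nNon / exonCallable else NA_real_
  dS <- if (exonCallable > 0) nSyn / exonCallable else NA_real_
  ## opportunity normalization over the callable coding sequence
  opp <- .codingOpportunity(cdsByGene, refseq)
  dndsNorm <- if (!is.null(opp) && nSyn > 0)
    (nNon / opp$nonsyn_sites) / (nSyn / opp$syn_sites) else NA_real_
  list(rates = rates,
       coding = list(synonymous = nSyn, nonsynonymous = nNon,
                     novel_stops = nStop, compensated_stops = nComp,
                     dN = dN, dS = dS,
                     dnds_raw = if (!is.na(dS) && dS > 0) dN / dS else NA_real_,
                     dnds_normalized = dndsNorm,
                     effects = if (length(effects)) do.call(rbind, effects)
                               else data.frame()))
}

## Nei-Gojobori style site counting: fraction of single mutations that are
## synonymous, summed over codons of all annotated CDS
.codingOpportunity <- function(cdsByGene, refseq) {
  if (is.null(cdsByGene)) return(NULL)
  gc <- Biostrings::GENETIC_CODE
  synSites <- 0
  totSites <- 0
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (gid in names(cdsByGene)) {
    g <- cdsByGene[[gid]]
    g <- g[order(GenomicRanges::start(g))]
    strand <- as.character(GenomicRanges::strand(g))[1]
    gpos <- unlist(lapply(seq_along(g), function(i)
      GenomicRanges::start(g)[i]:GenomicRanges::end(g)[i]))
    if (strand == "-") gpos <- rev(gpos)
    cdsSeq <- strsplit(refseq, "")[[1]][gpos]
    if (strand == "-") cdsSeq <- comp[cdsSeq]
    nCodon <- length(cdsSeq) %/% 3L
    for (ci in seq_len(nCodon)) {
      cod <- cdsSeq[(ci - 1L) * 3L + 1:3]
      if (anyNA(cod)) next
      aa <- gc[[paste(cod, collapse = "")]]
      for (p in 1:3) {
        for (b in setdiff(DNA_BASES, cod[p])) {
          mut <- cod
          mut[p] <- b
          if (gc[[paste(mut, collapse = "")]] == aa)
            synSites <- synSites + 1 / 3
        }
        totSites <- totSites + 1
      }
    }
  }
  list(syn_sites = synSites, nonsyn_sites = totSites - synSites,
       total_sites = totSites)
}

#' Per-site variant profile over a multicopy consensus unit
#'
#' For a deep pileup over a consensus sequence (an rRNA transcribed unit
#' being the canonical case), reports per position the fraction of mapped
#' bases differing from the consensus, plus non-overlapping windowed means
#' for plotting, with region labels applied from an input annotation.
#'
#' @param pileup a [Pileup] over the consensus.
#' @param consensus the consensus sequence (single character string).
#' @param window window width in bp for the smoothed profile (default 50).
#' @param regions optional data.frame `start`, `end` (0-based half-open),
#'   `region` labelling unit parts (18S/ITS1/5.8S/2S/ITS2/28S/ETS/IGS).
#' @return list with `site` (pos, depth, variant_fraction, region; zero-depth
#'   sites carry NA and are excluded from windows) and `windows` (start, end,
#'   mean_fraction, n_sites, region of the window midpoint).
#' @export
rrnaVariantProfile <- function(pileup, consensus, window = 50L,
                               regions = NULL) {
  consensus <- toupper(unname(consensus[1]))
  depth <- pileupDepth(pileup, 1L)
  cnt <- baseCounts(pileup, 1L)
  chars <- strsplit(consensus, "")[[1]]
  idx <- match(chars, DNA_BASES)
  refN <- cnt[cbind(idx, seq_along(chars))]
  vf <- ifelse(depth > 0, 1 - refN / depth, NA_real_)
  lab <- rep(NA_character_, length(chars))
  if (!is.null(regions)) {
    for (i in seq_len(nrow(regions)))
      lab[(regions$start[i] + 1L):regions$end[i]] <- regions$region[i]
  }
  site <- data.frame(pos = seq_along(chars) - 1L, depth = depth,
                     variant_fraction = vf, region = lab,
                     stringsAsFactors = FALSE)
  starts <- seq(0L, length(chars) - 1L, by = window)
  win <- data.frame(
    start = starts,
    end = pmin(starts + window, length(chars)))
  win$mean_fraction <- vapply(seq_len(nrow(win)), function(i) {
    v <- vf[(win$start[i] + 1L):win$end[i]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  win$n_sites <- vapply(seq_len(nrow(win)), function(i)
    sum(!is.na(vf[(win$start[i] + 1L):win$end[i]])), numeric(1))
  mid <- pmin(length(chars), win$start + window %/% 2 + 1L)
  win$region <- lab[mid]
  list(site = site, windows = win)
}
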