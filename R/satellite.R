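## Satellite DNA: arrangement classification from raw reads via tiling
## 12-mer spacing/orientation, the analytic co-occurrence expectation, and
## variant-tolerant copy-number / abundance estimation.

#' Satellite model: a monomer and its tiling k-mers
#'
#' The monomer is rotation-normalized (lexicographically minimal rotation)
#' so that tandem-derived circular extensions compare stably; the anchor is
#' the tiling k-mer at position 0 of the normalized monomer, and further
#' tiling k-mers follow at non-overlapping steps of `k`.
#'
#' @param monomer monomer sequence (100-300 bp).
#' @param readLen read length the arrangement statistics assume.
#' @param k tiling k-mer length (12; 12-mers were chosen over 18-mers to
#'   speed counting).
#' @param normalize rotation-normalize the monomer (default TRUE).
#' @param id model id.
#' @return list of class `"SatelliteModel"`: `id`, `monomer`, `L`, `k`,
#'   `readLen`, `tiling` (k-mer strings), `positions` (0-based).
#' @export
satelliteModel <- function(monomer, readLen = 100L, k = 12L,
                           normalize = TRUE, id = "sat") {
  monomer <- toupper(unname(monomer[1]))
  L <- nchar(monomer)
  if (L < 100 || L > 300) stop("monomer length must be in [100, 300] bp")
  if (normalize) monomer <- minimalRotation(monomer)
  positions <- seq(0L, by = as.integer(k), length.out = L %/% k)
  tiling <- substring(monomer, positions + 1L, positions + k)
  structure(list(id = id, monomer = monomer, L = L, k = as.integer(k),
                 readLen = as.integer(readLen), tiling = tiling,
                 positions = positions),
            class = "SatelliteModel")
}

#' Analytic co-occurrence probability of two k-mers on one read
#'
#' For a read of length `R` drawn uniformly from a long head-to-tail tandem
#' array, the probability that a read containing a fixed k-mer also fully
#' contains a second k-mer at signed offset `d` is
#' `(R - k - |d| + 1) / (R - k + 1)` for `|d| <= R - k`, else 0.  With
#' R = 100, k = 12 and adjacent tiling k-mers (d = 12) this is 77/89, about
#' 0.87.
#'
#' @param R read length (> k).
#' @param k k-mer length (> 0).
#' @param d signed offset between the k-mer start positions.
#' @return probability in `[0, 1]`.
#' @export
expectedCooccurrence <- function(R, k, d) {
  if (any(R <= k) || any(k <= 0)) stop("need R > k > 0")
  p <- (R - k - abs(d) + 1) / (R - k + 1)
  p[abs(d) > R - k] <- 0
  pmax(p, 0)
}

#' Expected tiling k-mer offsets on reads from a tandem array
#'
#' In a head-to-tail array every tiling k-mer recurs with period L, so a
#' k-mer at monomer position p can co-occur with the anchor at signed offset
#' p (same copy) and p - L (adjacent copy).  Both representatives within the
#' read span `|d| <= R - k` are expected; for the classic 166 bp monomer on
#' 100 bp reads this enumerates 13 offsets.
#'
#' @param model a [satelliteModel()].
#' @return sorted integer vector of expected signed offsets (0 excluded).
#' @export
expectedOffsets <- function(model) {
  span <- model$readLen - model$k
  d <- c(model$positions, model$positions - model$L)
  d <- unique(d[abs(d) <= span & d != 0L])
  sort(d)
}

#' Arrangement profile and classification from raw reads
#'
#' Every read containing the anchor k-mer (up to `maxMismatch`
#' substitutions, either strand) is put in anchor-forward frame and the
#' signed offsets and orientations of all other tiling k-mer occurrences are
#' accumulated.  Arrays in head-to-tail tandem place >= ~90% of
#' co-occurrences at the expected offsets in consistent orientation,
#' including the junction-spanning (adjacent-copy) offsets; isolated
#' dispersed copies lack the junction offsets; inverted (head-to-head)
#' arrangements show orientation-flipped co-occurrences.
#'
#' @param reads character vector of uniform-length reads.
#' @param model a [satelliteModel()].
#' @param maxMismatch per-k-mer mismatch tolerance (default 1).
#' @param tandemFraction expected-offset fraction required to call
#'   head-to-tail (default 0.9).
#' @return list with `classification` (`"head-to-tail tandem"`,
#'   `"head-to-head"`, `"dispersed"` or `"not detected"`), `profile`
#'   (data.frame: kmer, offset, flipped, observed, expected probability),
#'   `anchorReads`, `fractionExpected`, `flippedFraction`,
#'   `junctionSupport`.
#' @export
arrangementProfile <- function(reads, model, maxMismatch = 1L,
                               tandemFraction = 0.9) {
  res <- .cpp_satellite_scan(as.character(reads), model$tiling,
                             as.integer(maxMismatch))
  tab <- res$table
  if (res$anchor_reads == 0) {
    return(list(classification = "not detected",
                profile = data.frame(), anchorReads = 0,
                fractionExpected = NA_real_, flippedFraction = NA_real_,
                junctionSupport = NA_real_))
  }
  exp_off <- expectedOffsets(model)
  tab$expected <- expectedCooccurrence(model$readLen, model$k, tab$offset) *
    (tab$offset %in% exp_off)
  total <- sum(tab$count)
  atExpected <- sum(tab$count[tab$offset %in% exp_off & tab$flipped == 0L])
  fracExpected <- if (total > 0) atExpected / total else 0
  flippedFraction <- if (total > 0) sum(tab$count[tab$flipped == 1L]) / total
    else 0
  ## junction support: adjacent-copy offsets must actually be observed
  junction <- exp_off[exp_off < 0]
  junctionSupport <- if (!length(junction)) NA_real_ else {
    obs <- vapply(junction, function(d)
      sum(tab$count[tab$offset == d & tab$flipped == 0L]), numeric(1))
    expd <- res$anchor_reads *
      expectedCooccurrence(model$readLen, model$k, junction)
    mean(obs / pmax(expd, 1))
  }
  classification <-
    if (total == 0) "dispersed"
    else if (fracExpected >= tandemFraction &&
             (!is.na(junctionSupport) && junctionSupport >= 0.3))
      "head-to-tail tandem"
    else if (flippedFraction >= 0.3) "head-to-head"
    else "dispersed"
  list(classification = classification, profile = tab,
       anchorReads = res$anchor_reads, fractionExpected = fracExpected,
       flippedFraction = flippedFraction, junctionSupport = junctionSupport)
}

#' Construct an abundance estimate
#'
#' Total genomic span follows the convention of multiplying monomer length
#' by the variable-element count.
#'
#' @param canonical estimated canonical element count (exact-match copies).
#' @param variable estimated variable element count (copies within one
#'   substitution, insertion or deletion).
#' @param monomerLength monomer length L in bp.
#' @return list of class `"AbundanceEstimate"`: `canonical`, `variable`,
#'   `monomerLength`, `totalMbp` = L * variable / 1e6.
#' @export
abundanceEstimate <- function(canonical, variable, monomerLength) {
  if (variable < canonical)
    stop("variable element count cannot be below the canonical count")
  structure(list(canonical = canonical, variable = variable,
                 monomerLength = monomerLength,
                 totalMbp = monomerLength * variable / 1e6),
            class = "AbundanceEstimate")
}

#' Satellite abundance from an 18-mer table
#'
#' The canonical copy number is the mean, over the monomer's non-overlapping
#' 18-mers, of observed count / per-k-mer depth, where per-k-mer depth =
#' per-base depth * (R - 18 + 1) / R (a read of length R exposes only
#' R - k + 1 k-mer windows).  The variable count uses counts summed over
#' each tiling 18-mer's edit-distance-<=1 neighbourhood (all single
#' substitutions plus single-insertion/deletion neighbours, deduplicated).
#'
#' @param table a [KmerTable] with k = 18 (canonical policy recommended:
#'   reads are unstranded).
#' @param model a [satelliteModel()].
#' @param perBaseDepth sequencing depth of the read set (> 0).
#' @param readLen read length R.
#' @return an [abundanceEstimate()].
#' @export
estimateAbundance <- function(table, model, perBaseDepth, readLen = 100L) {
  stopifnot(is(table, "KmerTable"))
  if (perBaseDepth <= 0) stop("depth must be > 0")
  k <- table@k
  positions <- seq(0L, by = k, length.out = model$L %/% k)
  tiling <- substring(model$monomer, positions + 1L, positions + k)
  res <- .cpp_neighbour_counts(tiling, table@kmers, table@counts, k,
                               table@strandPolicy == "canonical")
  kmerDepth <- perBaseDepth * (readLen - k + 1) / readLen
  canonical <- mean(res$count) / kmerDepth
  variable <- mean(res$neighbourhood_count) / kmerDepth
  abundanceEstimate(canonical, max(variable, canonical), model$L)
}
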