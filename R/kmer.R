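## Exact k-mer counting and the k-mer-histogram genome-size estimator.

#' Count k-mers in a read set
#'
#' Every read contributes `read_len - k + 1` k-mers; windows containing a
#' non-ACGT character are skipped (not corrected).  Under the `"canonical"`
#' policy a k-mer is merged with its reverse complement under the
#' lexicographically smaller key; `"as-read"` keeps the two distinct, which
#' the strand-directional extension walk and the satellite spacing statistic
#' require.
#'
#' @param reads character vector of reads (or any sequences).
#' @param k k-mer length (1..31).
#' @param strandPolicy `"canonical"` or `"as-read"`.
#' @return a [KmerTable].
#' @export
countKmers <- function(reads, k = 18L,
                       strandPolicy = c("canonical", "as-read")) {
  strandPolicy <- match.arg(strandPolicy)
  if (k <= 0) stop("k must be positive")
  res <- .cpp_count_kmers(as.character(reads), as.integer(k),
                          strandPolicy == "canonical")
  new("KmerTable", k = as.integer(k), kmers = as.character(res$kmer),
      counts = as.numeric(res$count), strandPolicy = strandPolicy)
}

#' Multiplicity histogram of a read set's k-mers
#'
#' Computed without materialising the k-mer strings, so it scales to full
#' synthetic read sets.
#'
#' @inheritParams countKmers
#' @return a [KmerHistogram].
#' @export
kmerHistogram <- function(reads, k = 18L,
                          strandPolicy = c("canonical", "as-read")) {
  strandPolicy <- match.arg(strandPolicy)
  res <- .cpp_kmer_histogram(as.character(reads), as.integer(k),
                             strandPolicy == "canonical")
  new("KmerHistogram", k = as.integer(k),
      multiplicity = as.numeric(res$multiplicity),
      nKmers = as.numeric(res$n_kmers), totalKmers = res$total_kmers,
      strandPolicy = strandPolicy)
}

#' @rdname kmerHistogram
#' @param table a [KmerTable].
#' @export
histogramFromTable <- function(table) {
  tab <- table(table@counts)
  new("KmerHistogram", k = table@k,
      multiplicity = as.numeric(names(tab)), nKmers = as.numeric(tab),
      totalKmers = sum(table@counts), strandPolicy = table@strandPolicy)
}

#' Locate the main coverage peak of a k-mer histogram
#'
#' The spectrum is densified, smoothed with a window-3 running median, and
#' the peak is the argmax over multiplicities beyond the first local minimum
#' (the trough separating the error-kmer spike at low multiplicity from the
#' single-copy peak).  If the spectrum never rises again past the trough the
#' coverage is too low to call a peak.
#'
#' @param hist a [KmerHistogram].
#' @return list with `peak` (multiplicity of the main peak) and `trough`.
#' @export
findMainPeak <- function(hist) {
  m <- hist@multiplicity
  n <- hist@nKmers
  if (!length(m)) stop("coverage too low: empty histogram")
  maxm <- max(max(m), 10)
  dense <- numeric(maxm)
  dense[m] <- n
  s <- stats::runmed(dense, 3)
  ## first local minimum of the smoothed spectrum: the trough separating the
  ## error spike from the main peak.  A spectrum that rises from the start
  ## has no error spike.  The peak itself is the raw-count argmax beyond the
  ## trough (median smoothing flattens sharp modes and would bias it).
  trough <- 1L
  while (trough < length(s) && s[trough + 1L] < s[trough]) trough <- trough + 1L
  if (trough >= length(s) - 1L) stop("coverage too low: no peak beyond trough")
  region <- (trough + 1L):length(dense)
  peak <- region[which.max(dense[region])]
  if (dense[peak] <= 0 || peak >= length(dense))
    stop("coverage too low: no peak beyond trough")
  list(peak = peak, trough = trough)
}

#' Genome size from a k-mer histogram
#'
#' Size = total k-mer instances / main-peak multiplicity, the classic k-mer
#' coverage estimator.
#'
#' @param hist a [KmerHistogram].
#' @param totalKmers total k-mer instances; defaults to the histogram's own
#'   total.
#' @return list with `size` (bp), `peak`, and `totalKmers`.
#' @export
genomeSizeFromHistogram <- function(hist, totalKmers = NULL) {
  if (is.null(totalKmers)) totalKmers <- hist@totalKmers
  pk <- findMainPeak(hist)
  list(size = totalKmers / pk$peak, peak = pk$peak, trough = pk$trough,
       totalKmers = totalKmers)
}
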