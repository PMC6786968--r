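#' Simulate shotgun reads from a genome
#'
#' Draws fixed-length substrings uniformly from the genome, from a random
#' strand, to the requested depth. Substitution errors only (optional);
#' no indels or quality model.
#'
#' @param sim A [SimGenome-class] (or a `DNAStringSet`).
#' @param coverage Target sequencing depth (default 20).
#' @param readLength Read length in bases (default 100).
#' @param errorRate Per-base substitution error rate (default 0).
#' @param seed Integer seed.
#' @return A [Biostrings::DNAStringSet] of reads.
#' @export
simulateReads <- function(sim, coverage = 20, readLength = 100,
                          errorRate = 0, seed) {
  if (missing(seed)) stop("a seed is required")
  g <- if (is(sim, "SimGenome")) genomeSeqs(sim) else sim
  lens <- Biostrings::width(g)
  stopifnot(all(lens >= readLength), coverage > 0)
  .setStream(seed, "reads")
  n <- ceiling(coverage * sum(lens) / readLength)
  ci <- sample(seq_along(lens), n, replace = TRUE, prob = lens / sum(lens))
  chromChars <- vapply(seq_along(lens), function(i) as.character(g[[i]]), "")
  pos <- vapply(ci, function(i)
    sample.int(lens[i] - readLength + 1L, 1L), 0L)
  reads <- substring(chromChars[ci], pos, pos + readLength - 1L)
  if (errorRate > 0)
    reads <- vapply(reads, .mutateRate, "", rate = errorRate,
                    USE.NAMES = FALSE)
  rs <- Biostrings::DNAStringSet(reads)
  flip <- runif(n) < 0.5
  rs[flip] <- Biostrings::reverseComplement(rs[flip])
  names(rs) <- sprintf("read%07d", seq_len(n))
  rs
}

#' Estimate genome size from the k-mer spectrum of reads
#'
#' Counts canonical k-mers (the lexicographically smaller of a k-mer and
#' its reverse complement, here via 2-bit numeric encoding) across all
#' reads, builds the multiplicity histogram, takes the coverage peak as the
#' histogram mode at multiplicity 2 or more (multiplicity 1 is dominated by
#' sequencing errors), and estimates genome size as total k-mers divided by
#' the peak. K-mers with multiplicity within `[peak/2, 1.5 peak]` scale to
#' the unique (single-copy) genome portion; the remainder of the estimate is
#' attributed to repetitive sequence.
#'
#' @param reads A `DNAStringSet` or character vector of reads (coverage of
#'   10x or more recommended).
#' @param k K-mer length (default 25); must not exceed the read length.
#' @return A list: `size`, `unique_size`, `repetitive_size` (bases),
#'   `unique_fraction`, `repetitive_fraction`, `peak` (coverage peak
#'   multiplicity) and `histogram` (data.frame `multiplicity`,
#'   `n_kmers`).
#' @export
kmerGenomeSize <- function(reads, k = 25) {
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  if (k > min(Biostrings::width(reads)))
    stop("k (", k, ") exceeds the shortest read length")
  stopifnot(k >= 5, k <= 25)  # 4^k must stay exactly representable
  big <- paste(as.character(reads), collapse = "N")
  codes <- .baseCodes(big)
  fwd <- .kmerHash(codes, k)
  rev <- as.numeric(stats::filter(3 - codes, 4^((k - 1):0), sides = 1))
  canon <- pmin(fwd, rev)
  canon <- canon[!is.na(canon)]
  dt <- data.table::data.table(h = canon)
  mult <- dt[, list(n = .N), by = "h"]$n
  hist <- data.table::data.table(m = mult)[, list(n_kmers = .N), by = "m"]
  data.table::setorder(hist, m)
  if (!any(hist$m >= 2L))
    stop("no k-mer reaches multiplicity 2; coverage too low")
  h2 <- hist[hist$m >= 2L, ]
  peak <- h2$m[which.max(h2$n_kmers)]
  total <- sum(as.numeric(hist$m) * hist$n_kmers)
  size <- total / peak
  band <- hist$m >= peak / 2 & hist$m <= 1.5 * peak
  uniqueSize <- sum(as.numeric(hist$m[band]) * hist$n_kmers[band]) / peak
  list(size = size, unique_size = uniqueSize,
       repetitive_size = size - uniqueSize,
       unique_fraction = uniqueSize / size,
       repetitive_fraction = 1 - uniqueSize / size,
       peak = peak,
       histogram = data.frame(multiplicity = hist$m, n_kmers = hist$n_kmers))
}
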