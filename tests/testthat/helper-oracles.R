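## Independent oracles used to check the package's own algorithms.
## These are deliberately naive (exhaustive) implementations.

## exhaustive sliding-window Hamming search over all offsets and both
## strands; returns every placement at the minimal mismatch count
bruteForceBestHits <- function(probe, contigs) {
  L <- nchar(probe)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(probe)))
  best <- Inf
  hits <- list()
  for (nm in names(contigs)) {
    s <- as.character(contigs[[nm]])
    cl <- nchar(s)
    if (cl < L) next
    for (query in c("+", "-")) {
      q <- if (query == "+") probe else rc
      qr <- charToRaw(q)
      nr <- charToRaw("N")
      sr <- charToRaw(s)
      for (off in seq_len(cl - L + 1L)) {
        w <- sr[off:(off + L - 1L)]
        mm <- sum(qr != w | qr == nr)
        if (mm < best) {
          best <- mm
          hits <- list()
        }
        if (mm == best)
          hits[[length(hits) + 1L]] <- data.frame(
            contig = nm, position = off, strand = query, mismatches = mm)
      }
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

## brute-force tandem period: scores every candidate period by the mean
## identity of consecutive period-length chunks and returns the smallest
## period within 1% of the best score (any multiple of the fundamental
## period scores essentially the same, so the fundamental is the smallest
## of the near-ties)
bruteForceBestPeriod <- function(x, minPeriod, maxPeriod) {
  L <- nchar(x)
  ps <- minPeriod:min(maxPeriod, L %/% 2)
  scores <- vapply(ps, function(p) {
    n <- L %/% p
    if (n < 2L) return(-1)
    starts <- 1L + p * (seq_len(n) - 1L)
    chunks <- substring(x, starts, starts + p - 1L)
    mean(vapply(seq_len(n - 1L), function(i)
      mean(charToRaw(chunks[i]) == charToRaw(chunks[i + 1L])), 0))
  }, 0)
  best <- max(scores)
  p <- ps[scores >= best - 0.01][1L]
  list(period = p, score = best)
}

## N50 from the definition: smallest length l with sum(lengths >= l) >= total/2
bruteForceN50 <- function(lengths) {
  total <- sum(lengths)
  for (l in sort(unique(lengths), decreasing = TRUE)) {
    if (sum(lengths[lengths >= l]) >= total / 2) return(l)
  }
  stop("unreachable")
}
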