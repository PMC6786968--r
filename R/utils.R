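#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats cor rbinom runif setNames aggregate ave
#' @importFrom utils head tail write.table read.table
NULL

## One named random stream per operation: a single global seed plus the
## operation name deterministically derive the stream seed, so adding a new
## operation never perturbs fixtures generated by existing ones.
.streamSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  m <- 2147480009  # prime below 2^31
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% m
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% m)
}

.setStream <- function(seed, stream) {
  set.seed(.streamSeed(seed, stream))
}

.randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Substitute exactly `n` positions with a different base; returns character.
.mutateBases <- function(x, n) {
  if (n == 0L) return(x)
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  pos <- sample(length(ch), n)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

## Per-base substitution at rate `rate`; returns character.
.mutateRate <- function(x, rate) {
  if (rate <= 0) return(x)
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(ch)) < rate)
  for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Hamming distance between equal-length strings (N mismatches everything
## including N, matching the aligner's strict scoring).
.hamming <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  n <- charToRaw("N")
  sum(ra != rb | ra == n)
}

.emptyDF <- function(...) {
  proto <- list(...)
  S4Vectors::DataFrame(lapply(proto, function(t) vector(t, 0L)))
}
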