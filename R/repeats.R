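## 2-bit base codes with NA for anything but A/C/G/T
.baseCodes <- function(x) {
  v <- match(strsplit(x, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T")) - 1L
  as.numeric(v)
}

## rolling k-mer hashes; H[i] is the hash of the window ENDING at i
.kmerHash <- function(codes, k) {
  as.numeric(stats::filter(codes, 4^(0:(k - 1)), sides = 1))
}

#' Find tandem-repeat arrays by k-mer offset periodicity
#'
#' Detects tandem arrays (satellite repeats) in a sequence: every exact
#' k-mer is matched to its previous occurrence, and the distances between
#' successive occurrences vote for candidate periods; runs of positions
#' supporting one period delimit candidate arrays, which are refined by
#' building a per-column majority consensus monomer and scoring each copy's
#' identity to it. Overlapping candidates are resolved greedily by vote
#' count, so harmonics of the fundamental period are suppressed. Exact k-mer
#' voting tolerates the few percent of substitution divergence typical of
#' centromeric satellite arrays.
#'
#' @param seqs A [Biostrings::DNAStringSet] (or single `DNAString`).
#' @param minPeriod,maxPeriod Period search range in bases (2--2000).
#' @param minCopies Minimum copy number to report (default 5).
#' @param k Exact-match seed length for the periodicity vote (default 8).
#' @return A [S4Vectors::DataFrame]: `seqname`, `start`, `end` (1-based
#'   closed), `period`, `consensus` (monomer), `copies` (real), `identity`
#'   (mean per-copy identity to the consensus).
#' @examples
#' s <- Biostrings::DNAStringSet(c(x = strrep("ACGT", 50)))
#' findTandemArrays(s, minCopies = 5)
#' @export
findTandemArrays <- function(seqs, minPeriod = 2, maxPeriod = 2000,
                             minCopies = 5, k = 8) {
  stopifnot(minPeriod >= 2, minPeriod <= maxPeriod, maxPeriod <= 2000,
            minCopies >= 2, k >= 4)
  if (is(seqs, "DNAString")) seqs <- Biostrings::DNAStringSet(list(seqs))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  empty <- .emptyDF(seqname = "character", start = "integer",
                    end = "integer", period = "integer",
                    consensus = "character", copies = "numeric",
                    identity = "numeric")
  out <- list()
  minVotes <- max(3, ceiling((minCopies - 1) / 2))
  for (sn in names(seqs)) {
    x <- as.character(seqs[[sn]])
    L <- nchar(x)
    if (L < k + minPeriod) next
    H <- .kmerHash(.baseCodes(x), k)
    dt <- data.table::data.table(h = H, pos = seq_len(L) - k + 1L)
    dt <- dt[seq(k, L), ]
    dt <- dt[!is.na(dt$h), ]
    data.table::setorder(dt, h, pos)
    dt[, prev := data.table::shift(pos), by = "h"]
    dt <- dt[!is.na(dt$prev), ]
    dt[, d := pos - prev]
    dt <- dt[dt$d >= minPeriod & dt$d <= maxPeriod, ]
    if (!nrow(dt)) next
    cnt <- dt[, list(n = .N), by = "d"]
    cands <- list()
    for (p in cnt$d[cnt$n >= minVotes]) {
      sup <- sort(dt$pos[dt$d == p])
      runBreak <- c(0L, which(diff(sup) > 2L * p + 2L * k), length(sup))
      for (j in seq_len(length(runBreak) - 1L)) {
        idx <- (runBreak[j] + 1L):runBreak[j + 1L]
        votes <- length(idx)
        if (votes < minVotes) next
        s0 <- max(1L, min(sup[idx]) - p)
        e0 <- min(L, max(sup[idx]) + k - 1L)
        if ((e0 - s0 + 1L) / p < minCopies) next
        cands[[length(cands) + 1L]] <- data.frame(
          start = s0, end = e0, period = as.integer(p), votes = votes)
      }
    }
    if (!length(cands)) next
    cands <- do.call(rbind, cands)
    ## greedy non-overlapping selection by vote support
    cands <- cands[order(-cands$votes, cands$period), , drop = FALSE]
    keep <- logical(nrow(cands))
    taken <- IRanges::IRanges()
    for (i in seq_len(nrow(cands))) {
      ir <- IRanges::IRanges(cands$start[i], cands$end[i])
      if (!length(IRanges::findOverlaps(ir, taken))) {
        keep[i] <- TRUE
        taken <- c(taken, ir)
      }
    }
    cands <- cands[keep, , drop = FALSE]
    for (i in seq_len(nrow(cands))) {
      ref <- .refineArray(x, cands$start[i], cands$end[i], cands$period[i])
      if (is.null(ref) || ref$copies < minCopies) next
      out[[length(out) + 1L]] <- cbind(data.frame(seqname = sn), ref)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$seqname, res$start), , drop = FALSE]
  rownames(res) <- NULL
  S4Vectors::DataFrame(res)
}

## consensus refinement: chop the candidate into period-length copies,
## majority-vote a consensus, and report mean per-copy identity
.refineArray <- function(x, start, end, period) {
  span <- end - start + 1L
  n <- span %/% period
  if (n < 2L) return(NULL)
  starts <- start + period * (seq_len(n) - 1L)
  copies <- substring(x, starts, starts + period - 1L)
  mat <- do.call(rbind, strsplit(copies, "", fixed = TRUE))
  cons <- apply(mat, 2L, function(col) names(which.max(table(col))))
  consensus <- paste(cons, collapse = "")
  ident <- vapply(seq_len(n), function(i) mean(mat[i, ] == cons), 0)
  data.frame(start = as.integer(start), end = as.integer(end),
             period = as.integer(period), consensus = consensus,
             copies = span / period, identity = mean(ident))
}

## best identity between two monomers under cyclic rotation and reverse
## complement; denominator is the longer monomer, penalizing length mismatch
.monomerIdentity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  la <- nchar(a); lb <- nchar(b)
  bref <- substr(b, 1L, la)
  best <- 0
  for (cand in c(a, .revcomp(a))) {
    doubled <- paste0(cand, cand)
    for (r in seq_len(la)) {
      rot <- substr(doubled, r, r + la - 1L)
      m <- sum(charToRaw(rot) == charToRaw(bref))
      if (m > best) best <- m
    }
  }
  best / lb
}

#' Cluster tandem arrays into repeat families
#'
#' Single-linkage clustering of arrays on pairwise monomer identity,
#' computed under all cyclic rotations and reverse complement (tandem
#' monomers have no defined phase or strand). Each family reports a
#' representative monomer (from its highest-copy member), total genome
#' copies, and the genome fraction its members span.
#'
#' @param arrays Array table from [findTandemArrays()].
#' @param identity Linking identity threshold (default 0.8).
#' @param genomeLength Total genome length in bases (for the genome
#'   fraction).
#' @return A list: `families` (`DataFrame`: `family`, `representative`,
#'   `period`, `n_arrays`, `total_copies`, `genome_fraction`) and
#'   `membership` (integer family id per input array row).
#' @export
clusterRepeatFamilies <- function(arrays, identity = 0.8, genomeLength) {
  a <- as.data.frame(arrays)
  n <- nrow(a)
  if (!n)
    return(list(families = .emptyDF(family = "integer",
                  representative = "character", period = "integer",
                  n_arrays = "integer", total_copies = "numeric",
                  genome_fraction = "numeric"),
                membership = integer(0)))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (.monomerIdentity(a$consensus[i], a$consensus[j]) >= identity) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  fam <- match(roots, unique(roots))
  members <- split(seq_len(n), fam)
  families <- do.call(rbind, lapply(seq_along(members), function(f) {
    idx <- members[[f]]
    rep_i <- idx[which.max(a$copies[idx])]
    data.frame(family = f, representative = a$consensus[rep_i],
               period = a$period[rep_i], n_arrays = length(idx),
               total_copies = sum(a$copies[idx]),
               genome_fraction = sum(a$end[idx] - a$start[idx] + 1) /
                 genomeLength)
  }))
  list(families = S4Vectors::DataFrame(families), membership = fam)
}

#' Windowed repeat coverage and candidate centromeric intervals
#'
#' Computes, for each sequence, the fraction of bases in fixed windows
#' covered by a repeat family's member arrays, and calls one candidate
#' (centromeric) interval per sequence as the maximal run of consecutive
#' windows at or above `threshold` coverage.
#'
#' @param arrays Array table ([findTandemArrays()] rows) restricted to the
#'   family of interest.
#' @param seqLengths Named integer vector of sequence lengths.
#' @param window Window size in bases (default 10000; must be at least the
#'   family's period).
#' @param threshold Coverage fraction calling a window repeat-dense
#'   (default 0.5).
#' @return A list: `track` (`DataFrame`: `seqname`, `start`, `end`,
#'   `coverage`) and `candidates` (`DataFrame`: `seqname`, `start`, `end` —
#'   at most one interval per sequence, none where no window passes).
#' @export
repeatDensityTrack <- function(arrays, seqLengths, window = 10000,
                               threshold = 0.5) {
  a <- as.data.frame(arrays)
  stopifnot(!is.null(names(seqLengths)))
  if (nrow(a) && window < max(a$period))
    stop("window must be at least the family period")
  track <- list(); cands <- list()
  for (sn in names(seqLengths)) {
    L <- as.integer(seqLengths[[sn]])
    starts <- seq.int(1L, L, by = window)
    ends <- pmin(starts + window - 1L, L)
    rows <- a[a$seqname == sn, , drop = FALSE]
    ir <- if (nrow(rows))
      IRanges::reduce(IRanges::IRanges(rows$start, rows$end))
    else IRanges::IRanges()
    cov <- IRanges::coverage(ir, width = L)
    covered <- IRanges::viewSums(IRanges::Views(cov, starts, ends))
    frac <- covered / (ends - starts + 1L)
    track[[sn]] <- data.frame(seqname = sn, start = starts, end = ends,
                              coverage = frac)
    hot <- frac >= threshold
    if (any(hot)) {
      r <- rle(hot)
      runEnd <- cumsum(r$lengths)
      runStart <- runEnd - r$lengths + 1L
      best <- which(r$values)[which.max(r$lengths[r$values])]
      cands[[sn]] <- data.frame(seqname = sn,
                                start = starts[runStart[best]],
                                end = ends[runEnd[best]])
    }
  }
  list(track = S4Vectors::DataFrame(do.call(rbind, c(track,
         list(make.row.names = FALSE))))
       , candidates = if (length(cands))
           S4Vectors::DataFrame(do.call(rbind, c(cands,
             list(make.row.names = FALSE))))
         else .emptyDF(seqname = "character", start = "integer",
                       end = "integer"))
}
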