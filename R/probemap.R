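#' Align marker probes to contigs with a seeded ungapped aligner
#'
#' Places each probe on both strands of every contig using exact k-mer seeds
#' followed by full-length ungapped (Hamming) extension. The probe is chopped
#' into non-overlapping k-mers (plus one flush with the probe's 3' end); any
#' exact seed match nominates a candidate placement, whose mismatch count is
#' then computed over the full probe length. By the pigeonhole principle a
#' placement with at most `floor(probeLength / k) - 1` mismatches is always
#' nominated by at least one clean seed, which comfortably covers the
#' alignment-quality band used for marker filtering (at most 4% mismatch).
#'
#' Hits within `band` score points of the marker's best hit are reported so
#' that best-hit ties (ambiguous markers) can be detected downstream. Score
#' is `matches - mismatches`; `N` in probe or contig counts as a mismatch.
#'
#' @param probes Named character vector of probe sequences (names are marker
#'   ids). Probes containing characters other than A/C/G/T/N are rejected and
#'   reported in the `invalid` attribute of the result.
#' @param contigs A named [Biostrings::DNAStringSet].
#' @param k Seed length (>= 11).
#' @param band Reporting band in score points below the best hit (default 10).
#' @return A [S4Vectors::DataFrame] of hits with columns `marker_id`,
#'   `contig`, `position` (1-based start on the contig's forward strand),
#'   `strand`, `matches`, `mismatches`, `aligned_length`, `score`, sorted by
#'   marker then score (descending), ties broken by (contig, position).
#'   Markers with unalignable probes are listed in `attr(x, "invalid")`.
#' @examples
#' ctg <- Biostrings::DNAStringSet(c(c1 = paste(rep("ACGT", 50), collapse = "")))
#' alignProbes(c(m1 = substr(as.character(ctg[[1]]), 11, 80)), ctg)
#' @export
alignProbes <- function(probes, contigs, k = 11, band = 10) {
  stopifnot(k >= 11, all(nchar(probes) >= k), !is.null(names(probes)),
            !is.null(names(contigs)))
  k <- as.integer(k)
  ok <- grepl("^[ACGTN]*$", probes)
  invalid <- names(probes)[!ok]
  probes <- probes[ok]

  empty <- S4Vectors::DataFrame(
    marker_id = character(0), contig = character(0), position = integer(0),
    strand = character(0), matches = integer(0), mismatches = integer(0),
    aligned_length = integer(0), score = integer(0))
  if (!length(probes)) {
    attr(empty, "invalid") <- invalid
    return(empty)
  }

  ## oriented queries: forward probe finds "+" hits, reverse complement "-"
  pl <- nchar(probes)
  orient <- data.table::data.table(
    marker_id = rep(names(probes), 2L),
    strand = rep(c("+", "-"), each = length(probes)),
    seq = c(probes,
            as.character(Biostrings::reverseComplement(
              Biostrings::DNAStringSet(probes)))),
    plen = rep(pl, 2L))

  ## seed table: non-overlapping k-mers + one flush with the probe end
  seedList <- lapply(seq_len(nrow(orient)), function(i) {
    L <- orient$plen[i]
    st <- unique(c(seq.int(1L, L - k + 1L, by = k), L - k + 1L))
    data.table::data.table(qi = i, offset = st,
                           seed = substring(orient$seq[i], st, st + k - 1L))
  })
  seeds <- data.table::rbindlist(seedList)
  seeds <- seeds[!grepl("N", seeds$seed, fixed = TRUE), ]
  if (!nrow(seeds)) {
    attr(empty, "invalid") <- invalid
    return(empty)
  }
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds$seed))

  ## candidate generation per contig
  cand <- vector("list", length(contigs))
  for (ci in seq_along(contigs)) {
    m <- Biostrings::matchPDict(pd, contigs[[ci]])
    si <- Biostrings::startIndex(m)
    cnt <- lengths(si)
    if (!sum(cnt)) next
    hitSeed <- rep.int(seq_along(cnt), cnt)
    starts <- unlist(si, use.names = FALSE)
    cand[[ci]] <- data.table::data.table(
      qi = seeds$qi[hitSeed],
      position = starts - seeds$offset[hitSeed] + 1L,
      ci = ci)
  }
  cand <- data.table::rbindlist(cand)
  if (!nrow(cand)) {
    attr(empty, "invalid") <- invalid
    return(empty)
  }
  cand <- unique(cand)
  cand[, `:=`(plen = orient$plen[cand$qi])]
  clen <- Biostrings::width(contigs)
  cand <- cand[cand$position >= 1L &
               cand$position + cand$plen - 1L <= clen[cand$ci], ]
  if (!nrow(cand)) {
    attr(empty, "invalid") <- invalid
    return(empty)
  }

  ## Hamming extension over the full probe length (raw comparison; N never
  ## matches, on either side)
  data.table::setorder(cand, ci, qi, position)
  usedC <- unique(cand$ci)
  craw <- vector("list", length(contigs))
  for (ci in usedC) craw[[ci]] <- charToRaw(as.character(contigs[[ci]]))
  oraw <- lapply(orient$seq, charToRaw)
  rawN <- charToRaw("N")
  mm <- integer(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    p <- oraw[[cand$qi[i]]]
    s <- cand$position[i]
    w <- craw[[cand$ci[i]]][s:(s + length(p) - 1L)]
    mm[i] <- sum(p != w | p == rawN)
  }
  cand[, mismatches := mm]

  hits <- data.table::data.table(
    marker_id = orient$marker_id[cand$qi],
    contig = names(contigs)[cand$ci],
    position = cand$position,
    strand = orient$strand[cand$qi],
    matches = cand$plen - cand$mismatches,
    mismatches = cand$mismatches,
    aligned_length = cand$plen,
    score = cand$plen - 2L * cand$mismatches)
  ## same placement found on both strands (palindromic probe): keep one row
  hits <- hits[!duplicated(hits[, c("marker_id", "contig", "position")]), ]
  hits[, best := max(score), by = "marker_id"]
  hits <- hits[hits$score >= hits$best - band, ]
  hits[, best := NULL]
  data.table::setorder(hits, marker_id, -score, contig, position)

  out <- S4Vectors::DataFrame(as.data.frame(hits))
  attr(out, "invalid") <- invalid
  out
}

#' Filter probe hits on identity thresholds and best-hit uniqueness
#'
#' Applies the marker retention rule: a marker is eliminated when it has no
#' hit (`unmapped`) or when two or more hits tie at its top score
#' (`ambiguous`); otherwise its unique best hit is retained only when
#' `matches / probeLength >= minMatch` and
#' `mismatches / probeLength <= maxMismatch` (`quality` otherwise). Both
#' fractions use the full probe length as denominator. Uniqueness is decided
#' before the quality thresholds, so an ambiguous marker is reported as
#' ambiguous even if its tied hits would also fail on quality. Only exact
#' score ties eliminate; a second-best hit one point below the best does not.
#'
#' @param hits A hit table as returned by [alignProbes()] (one or many
#'   markers).
#' @param minMatch Minimum match fraction (default 0.95).
#' @param maxMismatch Maximum mismatch fraction (default 0.04).
#' @return A list with `kept` (one row per retained marker, same columns as
#'   `hits`) and `rejected` (`DataFrame`: `marker_id`, `reason`).
#' @export
filterProbeHits <- function(hits, minMatch = 0.95, maxMismatch = 0.04) {
  stopifnot(minMatch > 0, minMatch <= 1, maxMismatch > 0, maxMismatch <= 1)
  h <- data.table::as.data.table(as.data.frame(hits))
  if (!nrow(h)) {
    return(list(kept = hits[0, ],
                rejected = .emptyDF(marker_id = "character",
                                    reason = "character")))
  }
  h[, best := max(score), by = "marker_id"]
  top <- h[h$score == h$best, ]
  nTop <- table(top$marker_id)
  ambiguous <- names(nTop)[nTop >= 2L]
  uniq <- top[!top$marker_id %in% ambiguous, ]
  passes <- uniq$matches / uniq$aligned_length >= minMatch &
    uniq$mismatches / uniq$aligned_length <= maxMismatch
  kept <- uniq[passes, ]
  kept[, best := NULL]
  rejected <- rbind(
    data.frame(marker_id = ambiguous,
               reason = rep("ambiguous", length(ambiguous))),
    data.frame(marker_id = uniq$marker_id[!passes],
               reason = rep("quality", sum(!passes))))
  list(kept = S4Vectors::DataFrame(as.data.frame(kept)),
       rejected = S4Vectors::DataFrame(rejected[order(rejected$marker_id), ,
                                                drop = FALSE]))
}

#' Place the markers of a genetic map onto contigs
#'
#' Runs [alignProbes()] and [filterProbeHits()] for every marker of a
#' [GeneticMap-class] and joins the retained placements with the map's
#' linkage-group and centimorgan coordinates. Markers are counted through the
#' funnel: `total` markers, `positioned` (at least one reported hit),
#' `unique_best` (positioned and not ambiguous) and `passed` (retained after
#' the identity filter).
#'
#' @param map A [GeneticMap-class].
#' @param contigs A named [Biostrings::DNAStringSet].
#' @param k Seed length for [alignProbes()].
#' @param minMatch,maxMismatch Identity thresholds for [filterProbeHits()].
#' @param band Reporting band for [alignProbes()].
#' @return A [MarkerPlacements-class].
#' @export
placeMarkers <- function(map, contigs, k = 11, minMatch = 0.95,
                         maxMismatch = 0.04, band = 10) {
  stopifnot(is(map, "GeneticMap"))
  validObject(map)
  m <- markers(map)
  if (!nrow(m)) {
    return(new("MarkerPlacements",
      placements = .emptyDF(marker_id = "character", contig = "character",
        position = "integer", strand = "character", matches = "integer",
        mismatches = "integer", linkage_group = "integer", cM = "numeric",
        parent = "character"),
      rejections = .emptyDF(marker_id = "character", reason = "character"),
      counts = c(total = 0L, positioned = 0L, unique_best = 0L, passed = 0L),
      parent = parentLabel(map)))
  }
  probes <- setNames(as.character(m$probe_seq), m$marker_id)
  hits <- alignProbes(probes, contigs, k = k, band = band)
  invalid <- attr(hits, "invalid")
  flt <- filterProbeHits(hits, minMatch = minMatch, maxMismatch = maxMismatch)

  kept <- as.data.frame(flt$kept)
  idx <- match(kept$marker_id, m$marker_id)
  placements <- S4Vectors::DataFrame(
    marker_id = kept$marker_id, contig = kept$contig,
    position = kept$position, strand = kept$strand,
    matches = kept$matches, mismatches = kept$mismatches,
    linkage_group = as.integer(m$linkage_group[idx]),
    cM = as.numeric(m$cM[idx]),
    parent = rep(parentLabel(map), nrow(kept)))

  positionedIds <- unique(hits$marker_id)
  unmapped <- setdiff(m$marker_id, c(positionedIds, invalid))
  rejections <- rbind(
    as.data.frame(flt$rejected),
    data.frame(marker_id = unmapped,
               reason = rep("unmapped", length(unmapped))),
    data.frame(marker_id = invalid,
               reason = rep("invalid", length(invalid))))
  rejections <- rejections[order(rejections$marker_id), , drop = FALSE]

  counts <- c(total = nrow(m),
              positioned = length(positionedIds),
              unique_best = length(positionedIds) -
                sum(rejections$reason == "ambiguous"),
              passed = nrow(placements))
  new("MarkerPlacements", placements = placements,
      rejections = S4Vectors::DataFrame(rejections),
      counts = setNames(as.integer(counts), names(counts)),
      parent = parentLabel(map))
}
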