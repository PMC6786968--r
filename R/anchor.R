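.placementsTable <- function(placements) {
  if (is(placements, "MarkerPlacements"))
    return(as.data.frame(placements(placements)))
  if (is.list(placements) && !is.data.frame(placements) &&
      !is(placements, "DataFrame"))
    return(do.call(rbind, lapply(placements, .placementsTable)))
  as.data.frame(placements)
}

#' Assign contigs to linkage groups by marker majority
#'
#' For every contig carrying at least one placed marker, tallies its markers
#' per linkage group and assigns the modal (most common) linkage group.
#' Markers on the modal group are "concordant", all others "discordant".
#' Contigs with fewer than `minMarkers` concordant markers are unanchorable
#' (anchoring requires more than one supporting marker). A k-way tie in the
#' tally yields no modal assignment (`modal_lg` is `NA`, `tied` is `TRUE`);
#' tied contigs are escalated to chimera detection rather than silently
#' resolved.
#'
#' @param placements A [MarkerPlacements-class], a placements table, or a
#'   list of either (e.g. the female and male tables combined).
#' @param minMarkers Minimum concordant markers for anchorability (default 2).
#' @return A [S4Vectors::DataFrame]: `contig`, `modal_lg`, `concordant`,
#'   `discordant`, `n_markers`, `tied`, `anchorable`.
#' @export
assignLinkageGroups <- function(placements, minMarkers = 2) {
  p <- .placementsTable(placements)
  if (!nrow(p))
    return(.emptyDF(contig = "character", modal_lg = "integer",
                    concordant = "integer", discordant = "integer",
                    n_markers = "integer", tied = "logical",
                    anchorable = "logical"))
  byc <- split(p$linkage_group, p$contig)
  res <- lapply(names(byc), function(ctg) {
    tab <- table(byc[[ctg]])
    top <- max(tab)
    tiedLGs <- names(tab)[tab == top]
    tied <- length(tiedLGs) > 1L
    modal <- if (tied) NA_integer_ else as.integer(tiedLGs)
    conc <- if (tied) 0L else as.integer(top)
    data.frame(contig = ctg, modal_lg = modal, concordant = conc,
               discordant = length(byc[[ctg]]) - conc,
               n_markers = length(byc[[ctg]]), tied = tied)
  })
  out <- do.call(rbind, res)
  out$anchorable <- !out$tied & out$concordant >= minMarkers
  S4Vectors::DataFrame(out[order(out$contig), , drop = FALSE])
}

#' Detect chimeric contigs from two-block marker patterns
#'
#' A contig is proposed for splitting when its markers, sorted by physical
#' position, form exactly two contiguous blocks of at least `minBlock`
#' markers each, belonging to two different linkage groups — the signature
#' of an assembly artefact joining two chromosomes. The breakpoint interval
#' runs from the last base of the final block-1 marker to the base before
#' the first block-2 marker. Contigs whose linkage-group tally is tied but
#' whose markers interleave (for example 1,5,1,5) are irresolvable: no split
#' is proposed and they are excluded from anchoring (reported in
#' `attr(x, "irresolvable")`).
#'
#' @param placements Placements (any form accepted by
#'   [assignLinkageGroups()]); typically both parental maps combined.
#' @param probeLength Marker probe length in bases, used to compute the end
#'   of the last block-1 marker (default 70).
#' @param minBlock Minimum markers per block (default 2).
#' @return A [S4Vectors::DataFrame] of split proposals: `contig`, `left_lg`,
#'   `right_lg`, `break_left` (last base of block 1's final marker),
#'   `break_right` (first base of block 2's first marker), with tied
#'   non-two-block contigs in `attr(x, "irresolvable")`.
#' @export
detectChimeras <- function(placements, probeLength = 70, minBlock = 2) {
  p <- .placementsTable(placements)
  empty <- .emptyDF(contig = "character", left_lg = "integer",
                    right_lg = "integer", break_left = "integer",
                    break_right = "integer")
  if (!nrow(p)) {
    attr(empty, "irresolvable") <- character(0)
    return(empty)
  }
  p <- p[order(p$contig, p$position), , drop = FALSE]
  byc <- split(p, p$contig)
  props <- list()
  irres <- character(0)
  for (ctg in names(byc)) {
    q <- byc[[ctg]]
    r <- rle(as.integer(q$linkage_group))
    twoBlock <- length(r$values) == 2L && all(r$lengths >= minBlock) &&
      r$values[1L] != r$values[2L]
    if (twoBlock) {
      lastLeft <- r$lengths[1L]
      props[[ctg]] <- data.frame(
        contig = ctg, left_lg = r$values[1L], right_lg = r$values[2L],
        break_left = as.integer(q$position[lastLeft] + probeLength - 1L),
        break_right = as.integer(q$position[lastLeft + 1L]))
    } else if (length(r$values) > 1L) {
      tab <- table(q$linkage_group)
      if (sum(tab == max(tab)) > 1L) irres <- c(irres, ctg)
    }
  }
  out <- if (length(props)) S4Vectors::DataFrame(do.call(rbind, props))
         else empty
  rownames(out) <- NULL
  attr(out, "irresolvable") <- irres
  out
}

#' Split contigs at proposed chimera breakpoints
#'
#' Each proposed contig is replaced by two contigs named `<name>_a` and
#' `<name>_b`, cut at the midpoint of the breakpoint interval. Residues are
#' conserved and the contig count grows by exactly the number of proposals.
#' Only one split per contig is supported.
#'
#' @param contigs A named [Biostrings::DNAStringSet].
#' @param proposals Split proposals from [detectChimeras()].
#' @return A [Biostrings::DNAStringSet] with split contigs in place of their
#'   parents.
#' @export
splitContigs <- function(contigs, proposals) {
  pr <- as.data.frame(proposals)
  if (!nrow(pr)) return(contigs)
  if (anyDuplicated(pr$contig))
    stop("only one split per contig is supported: ",
         paste(unique(pr$contig[duplicated(pr$contig)]), collapse = ", "))
  missing <- setdiff(pr$contig, names(contigs))
  if (length(missing))
    stop("proposals reference unknown contigs: ",
         paste(missing, collapse = ", "))
  out <- list()
  for (nm in names(contigs)) {
    i <- match(nm, pr$contig)
    if (is.na(i)) {
      out[[nm]] <- contigs[[nm]]
    } else {
      cut <- (pr$break_left[i] + pr$break_right[i]) %/% 2L
      len <- Biostrings::width(contigs)[match(nm, names(contigs))]
      stopifnot(cut >= 1L, cut < len)
      out[[paste0(nm, "_a")]] <- Biostrings::subseq(contigs[[nm]], 1L, cut)
      out[[paste0(nm, "_b")]] <- Biostrings::subseq(contigs[[nm]], cut + 1L,
                                                    len)
    }
  }
  res <- Biostrings::DNAStringSet(vapply(out, as.character, ""))
  names(res) <- names(out)
  res
}

#' Order anchored contigs along each linkage group by mean centimorgan
#'
#' Uses only concordant markers of the requested parental map: each contig's
#' ordering key is the arithmetic mean cM of its concordant markers on that
#' map; contigs are sorted by that key within their linkage group (stable
#' sort; ties broken by descending contig length, then name).
#'
#' @param placements Placements of one parental map.
#' @param assignments Contig assignments from [assignLinkageGroups()]
#'   (computed from the same or the combined placements).
#' @param contigLengths Named integer vector of contig lengths (for tie
#'   breaking).
#' @return A [S4Vectors::DataFrame]: `linkage_group`, `rank`, `contig`,
#'   `mean_cM`, `n_markers`, ordered by linkage group then rank.
#' @export
orderContigs <- function(placements, assignments, contigLengths) {
  p <- .placementsTable(placements)
  a <- as.data.frame(assignments)
  a <- a[a$anchorable, , drop = FALSE]
  p <- p[p$contig %in% a$contig, , drop = FALSE]
  p$modal <- a$modal_lg[match(p$contig, a$contig)]
  p <- p[p$linkage_group == p$modal, , drop = FALSE]  # concordant only
  if (!nrow(p))
    return(.emptyDF(linkage_group = "integer", rank = "integer",
                    contig = "character", mean_cM = "numeric",
                    n_markers = "integer"))
  agg <- aggregate(cM ~ contig + modal, data = p, FUN = mean)
  names(agg) <- c("contig", "linkage_group", "mean_cM")
  nmk <- table(p$contig)
  agg$n_markers <- as.integer(nmk[agg$contig])
  len <- contigLengths[agg$contig]
  ord <- order(agg$linkage_group, agg$mean_cM, -as.numeric(len), agg$contig)
  agg <- agg[ord, , drop = FALSE]
  agg$rank <- stats::ave(seq_len(nrow(agg)), agg$linkage_group,
                         FUN = seq_along)
  rownames(agg) <- NULL
  S4Vectors::DataFrame(agg[, c("linkage_group", "rank", "contig", "mean_cM",
                               "n_markers")])
}

#' Orient contigs from the physical-vs-genetic position correlation
#'
#' For each anchorable contig and each parental map, computes the Spearman
#' rank correlation between its concordant markers' physical positions and
#' their centimorgan positions. A positive correlation orients the contig
#' forward (`+`), a negative one reverse (`-`). The orientation is `?` when
#' the correlation is zero, undefined (fewer than two distinct cM or
#' physical values on both maps), or when the two maps disagree in sign.
#'
#' @param placements Placements of one or both maps (list or combined table;
#'   the `parent` column separates the maps).
#' @param assignments Contig assignments from [assignLinkageGroups()].
#' @return A named character vector of orientations (`+`, `-`, `?`) for each
#'   anchorable contig.
#' @export
orientContigs <- function(placements, assignments) {
  p <- .placementsTable(placements)
  a <- as.data.frame(assignments)
  a <- a[a$anchorable, , drop = FALSE]
  sgn <- function(q) {
    if (nrow(q) < 2L || length(unique(q$cM)) < 2L ||
        length(unique(q$position)) < 2L) return(NA_real_)
    rho <- suppressWarnings(cor(q$position, q$cM, method = "spearman"))
    if (is.na(rho)) NA_real_ else sign(rho)
  }
  out <- setNames(character(nrow(a)), a$contig)
  for (i in seq_len(nrow(a))) {
    q <- p[p$contig == a$contig[i] &
           p$linkage_group == a$modal_lg[i], , drop = FALSE]
    s <- vapply(split(q, q$parent), sgn, 0)
    s <- s[!is.na(s) & s != 0]
    out[i] <- if (!length(s)) "?"
      else if (all(s > 0)) "+"
      else if (all(s < 0)) "-"
      else "?"
  }
  out
}

#' Integrate the female and male contig orders into one anchoring plan
#'
#' Contigs present on both maps take their female-map position (the female
#' map is the denser one); contigs on the male map only are inserted between
#' their male-map neighbours that are also female-anchored, preserving their
#' male relative order. Contigs whose two maps assign different linkage
#' groups are excluded and reported. Everything else — unanchorable,
#' irresolvable-pattern and markerless contigs — goes to Chr0.
#'
#' @param femaleOrder,maleOrder Per-map orders from [orderContigs()].
#' @param orientations Named orientation vector from [orientContigs()].
#' @param allContigs Character vector of all contig names in the assembly.
#' @param irresolvable Contigs flagged irresolvable by [detectChimeras()].
#' @param splits Optional `DataFrame` of applied split proposals, recorded in
#'   the plan.
#' @return An [AnchorPlan-class].
#' @export
integrateMaps <- function(femaleOrder, maleOrder, orientations, allContigs,
                          irresolvable = character(0), splits = NULL) {
  fo <- as.data.frame(femaleOrder)
  mo <- as.data.frame(maleOrder)
  fo <- fo[!fo$contig %in% irresolvable, , drop = FALSE]
  mo <- mo[!mo$contig %in% irresolvable, , drop = FALSE]

  shared <- intersect(fo$contig, mo$contig)
  flg <- setNames(fo$linkage_group, fo$contig)
  mlg <- setNames(mo$linkage_group, mo$contig)
  conflict <- shared[flg[shared] != mlg[shared]]
  fo <- fo[!fo$contig %in% conflict, , drop = FALSE]
  mo <- mo[!mo$contig %in% conflict, , drop = FALSE]

  lgs <- sort(unique(c(fo$linkage_group, mo$linkage_group)))
  rows <- list()
  for (lg in lgs) {
    f <- fo[fo$linkage_group == lg, , drop = FALSE]
    m <- mo[mo$linkage_group == lg, , drop = FALSE]
    seqn <- f$contig
    maleOnly <- setdiff(m$contig, fo$contig)  # not female-anchored anywhere
    if (length(maleOnly) && nrow(f)) {
      anchorAfter <- setNames(character(length(maleOnly)), maleOnly)
      lastShared <- NA_character_
      for (ctg in m$contig) {
        if (ctg %in% seqn) lastShared <- ctg
        else if (ctg %in% maleOnly) anchorAfter[ctg] <- lastShared
      }
      newSeq <- character(0)
      pre <- maleOnly[is.na(anchorAfter[maleOnly])]
      newSeq <- c(newSeq, pre)
      for (ctg in seqn) {
        newSeq <- c(newSeq, ctg,
                    maleOnly[!is.na(anchorAfter[maleOnly]) &
                             anchorAfter[maleOnly] == ctg])
      }
      seqn <- newSeq
    } else if (!nrow(f)) {
      seqn <- m$contig
    }
    if (!length(seqn)) next
    fcm <- setNames(fo$mean_cM, fo$contig)
    mcm <- setNames(mo$mean_cM, mo$contig)
    rows[[as.character(lg)]] <- data.frame(
      chromosome = paste0("Chr", lg),
      rank = seq_along(seqn),
      contig = seqn,
      orientation = ifelse(seqn %in% names(orientations),
                           orientations[seqn], "?"),
      female_cM = unname(fcm[seqn]),
      male_cM = unname(mcm[seqn]),
      support = ifelse(seqn %in% shared, "both",
                       ifelse(seqn %in% fo$contig, "female", "male")))
  }
  anchored <- if (length(rows)) do.call(rbind, rows)
    else data.frame(chromosome = character(), rank = integer(),
                    contig = character(), orientation = character(),
                    female_cM = numeric(), male_cM = numeric(),
                    support = character())
  rownames(anchored) <- NULL
  excluded <- data.frame(
    contig = c(conflict, irresolvable),
    female_lg = c(as.integer(flg[conflict]),
                  rep(NA_integer_, length(irresolvable))),
    male_lg = c(as.integer(mlg[conflict]),
                rep(NA_integer_, length(irresolvable))),
    reason = c(rep("lg_conflict", length(conflict)),
               rep("irresolvable", length(irresolvable))))
  chr0 <- setdiff(allContigs, c(anchored$contig, excluded$contig))
  new("AnchorPlan", anchored = S4Vectors::DataFrame(anchored),
      chr0 = chr0, excluded = S4Vectors::DataFrame(excluded),
      splits = if (is.null(splits)) NULL else S4Vectors::DataFrame(splits))
}
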