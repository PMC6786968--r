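#' Build pseudo-molecule sequences and their AGP ledger from an anchor plan
#'
#' Concatenates each chromosome's contigs in plan order, reverse-
#' complementing `-` contigs, and inserts a run of `gap` N between
#' consecutive contigs (none terminal). Contigs with orientation `?` are
#' written forward but their AGP record keeps `?`. Unanchored contigs are
#' additionally assembled into a `Chr0` object the same way, in descending
#' length order, and are also returned individually.
#'
#' @param plan An [AnchorPlan-class].
#' @param contigs A named [Biostrings::DNAStringSet] containing every contig
#'   referenced by the plan.
#' @param gap Gap length in bases between consecutive contigs (default
#'   10000).
#' @param chr0 Build the concatenated Chr0 object (default `TRUE`).
#' @return A list: `sequences` (a `DNAStringSet` of pseudo-molecules
#'   including Chr0), `agp` (a `data.frame` of AGP v2.1 records), `unplaced`
#'   (a `DNAStringSet` of the individual Chr0 contigs).
#' @export
buildPseudomolecules <- function(plan, contigs, gap = 10000, chr0 = TRUE) {
  stopifnot(is(plan, "AnchorPlan"), gap >= 0)
  gap <- as.integer(gap)
  a <- as.data.frame(anchoredContigs(plan))
  a <- a[order(a$chromosome, a$rank), , drop = FALSE]
  layout <- split(a, a$chromosome)
  ## Chr0: unanchored contigs in descending length order
  c0 <- chr0Contigs(plan)
  if (chr0 && length(c0)) {
    miss <- setdiff(c0, names(contigs))
    if (length(miss)) stop("missing contig(s): ", paste(miss, collapse = ", "))
    lens <- Biostrings::width(contigs)[match(c0, names(contigs))]
    c0 <- c0[order(-lens, c0)]
    layout$Chr0 <- data.frame(chromosome = "Chr0", rank = seq_along(c0),
                              contig = c0, orientation = "+",
                              female_cM = NA_real_, male_cM = NA_real_,
                              support = "none")
  }
  used <- unlist(lapply(layout, `[[`, "contig"))
  if (anyDuplicated(used))
    stop("contig referenced twice: ",
         paste(unique(used[duplicated(used)]), collapse = ", "))
  miss <- setdiff(used, names(contigs))
  if (length(miss)) stop("missing contig(s): ", paste(miss, collapse = ", "))

  ## order chromosomes numerically, Chr0 last
  nm <- names(layout)
  num <- suppressWarnings(as.integer(sub("^Chr", "", nm)))
  layout <- layout[order(num == 0L, num, nm)]

  seqs <- character(0)
  agp <- list()
  for (obj in names(layout)) {
    L <- layout[[obj]]
    pieces <- character(nrow(L))
    pos <- 0L
    part <- 0L
    for (i in seq_len(nrow(L))) {
      if (i > 1L && gap > 0L) {
        part <- part + 1L
        agp[[length(agp) + 1L]] <- data.frame(
          object = obj, object_beg = pos + 1L, object_end = pos + gap,
          part_number = part, component_type = "N",
          component_id = as.character(gap), component_beg = "scaffold",
          component_end = "yes", orientation = "map")
        pos <- pos + as.integer(gap)
      }
      ctg <- L$contig[i]
      s <- contigs[[ctg]]
      w <- length(s)
      ori <- L$orientation[i]
      pieces[i] <- as.character(
        if (ori == "-") Biostrings::reverseComplement(s) else s)
      part <- part + 1L
      agp[[length(agp) + 1L]] <- data.frame(
        object = obj, object_beg = pos + 1L, object_end = pos + w,
        part_number = part, component_type = "W",
        component_id = ctg, component_beg = "1",
        component_end = as.character(w), orientation = ori)
      pos <- pos + w
    }
    seqs[obj] <- paste(pieces,
                       collapse = strrep("N", if (nrow(L) > 1L) gap else 0L))
  }
  agp <- do.call(rbind, agp)
  rownames(agp) <- NULL
  unplacedNames <- if (length(chr0Contigs(plan)))
    chr0Contigs(plan) else character(0)
  list(sequences = Biostrings::DNAStringSet(seqs),
       agp = agp,
       unplaced = contigs[names(contigs) %in% unplacedNames])
}

#' Reconstruct pseudo-molecule sequences from AGP records and contigs
#'
#' The inverse of [buildPseudomolecules()]: replays the AGP ledger against a
#' contig set, yielding byte-identical pseudo-molecules. `?` orientations
#' are written forward, like the builder.
#'
#' @param agp AGP records as returned by [buildPseudomolecules()] or
#'   [readAGP()].
#' @param contigs A named [Biostrings::DNAStringSet].
#' @return A [Biostrings::DNAStringSet] of reconstructed objects.
#' @export
assembleFromAGP <- function(agp, contigs) {
  agp <- .validateAGP(agp)
  seqs <- vapply(split(agp, factor(agp$object, unique(agp$object))),
    function(L) {
      L <- L[order(L$part_number), , drop = FALSE]
      paste(vapply(seq_len(nrow(L)), function(i) {
        if (L$component_type[i] == "N")
          return(strrep("N", as.integer(L$component_id[i])))
        ctg <- L$component_id[i]
        if (!ctg %in% names(contigs)) stop("missing contig: ", ctg)
        s <- Biostrings::subseq(contigs[[ctg]],
                                as.integer(L$component_beg[i]),
                                as.integer(L$component_end[i]))
        if (L$orientation[i] == "-")
          as.character(Biostrings::reverseComplement(s))
        else as.character(s)
      }, ""), collapse = "")
    }, "")
  Biostrings::DNAStringSet(seqs)
}
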