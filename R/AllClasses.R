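#' @import methods
NULL

setClassUnion("DataFrameOrNULL", c("DataFrame", "NULL"))

#' SimGenome: a truth-tracked simulated genome
#'
#' Holds a multi-chromosome haploid genome together with the ground truth of
#' its planted tandem-repeat (centromeric) arrays and the seed that produced
#' it. All downstream simulator outputs (contigs, maps, variants) reference
#' this object so every stage of the anchoring pipeline can be scored against
#' known truth.
#'
#' @slot genome A [Biostrings::DNAStringSet] of chromosome sequences.
#' @slot centromeres A [GenomicRanges::GRanges] with one range per planted
#'   array and metadata columns `monomer` (character), `copies` (integer).
#'   Empty when no arrays were planted.
#' @slot seed Integer scalar; the global simulation seed.
#'
#' @export
setClass("SimGenome",
  representation(genome = "DNAStringSet", centromeres = "GRanges",
                 seed = "integer"))

setValidity("SimGenome", function(object) {
  msg <- NULL
  g <- object@genome
  if (is.null(names(g)) || anyDuplicated(names(g)))
    msg <- c(msg, "chromosomes must have unique names")
  freq <- Biostrings::alphabetFrequency(g)
  if (length(g) && any(rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE]) !=
                       Biostrings::width(g)))
    msg <- c(msg, "chromosome residues must be A/C/G/T only")
  cen <- object@centromeres
  if (length(cen)) {
    if (!all(c("monomer", "copies") %in% names(S4Vectors::mcols(cen))))
      msg <- c(msg, "centromere truth needs 'monomer' and 'copies' columns")
    idx <- match(as.character(GenomicRanges::seqnames(cen)), names(g))
    if (anyNA(idx))
      msg <- c(msg, "centromere seqnames must be chromosome names")
    else if (any(GenomicRanges::start(cen) < 1L |
                 GenomicRanges::end(cen) > Biostrings::width(g)[idx]))
      msg <- c(msg, "centromere interval outside chromosome bounds")
  }
  if (is.null(msg)) TRUE else msg
})

#' ContigSet: simulated contigs with their source-segment truth
#'
#' The result of fragmenting a [SimGenome] into draft contigs. `truth` has one
#' row per source segment with columns `contig`, `segment` (1 or 2),
#' `chromosome`, `start`, `end` (1-based closed, on the source chromosome),
#' `strand`, and `contig_start`/`contig_end` (the segment's span on the
#' contig). Clean contigs have one segment; chimeras have two segments from
#' different chromosomes.
#'
#' @slot contigs A [Biostrings::DNAStringSet] of contig sequences.
#' @slot truth A [S4Vectors::DataFrame] of source segments (see above).
#' @slot seed Integer scalar.
#'
#' @export
setClass("ContigSet",
  representation(contigs = "DNAStringSet", truth = "DataFrame",
                 seed = "integer"))

setValidity("ContigSet", function(object) {
  msg <- NULL
  tr <- object@truth
  need <- c("contig", "segment", "chromosome", "start", "end", "strand",
            "contig_start", "contig_end")
  if (!all(need %in% names(tr)))
    return(paste("truth must have columns:", paste(need, collapse = ", ")))
  if (nrow(tr)) {
    if (!all(tr$contig %in% names(object@contigs)))
      msg <- c(msg, "truth references unknown contigs")
    seglen <- tr$end - tr$start + 1L
    if (any(seglen != tr$contig_end - tr$contig_start + 1L))
      msg <- c(msg, "segment length mismatch between genome and contig spans")
    bycontig <- split(as.numeric(seglen), tr$contig)
    w <- Biostrings::width(object@contigs)[match(names(bycontig),
                                                 names(object@contigs))]
    if (any(vapply(bycontig, sum, 0) != w))
      msg <- c(msg, "segment lengths do not sum to contig lengths")
  }
  if (is.null(msg)) TRUE else msg
})

#' GeneticMap: marker records for one parent
#'
#' A linkage map as a table of markers: `marker_id`, `linkage_group`
#' (integer), `cM` (non-negative, non-decreasing within a linkage group when
#' sorted), `parent` ("female" or "male") and `probe_seq` (the 70-bp probe
#' used to place the marker on sequence).
#'
#' @slot markers A [S4Vectors::DataFrame] with the columns above.
#' @slot parent Character scalar, "female" or "male".
#'
#' @export
setClass("GeneticMap",
  representation(markers = "DataFrame", parent = "character"))

setValidity("GeneticMap", function(object) {
  m <- object@markers
  need <- c("marker_id", "linkage_group", "cM", "parent", "probe_seq")
  if (!all(need %in% names(m)))
    return(paste("markers must have columns:", paste(need, collapse = ", ")))
  msg <- NULL
  if (length(object@parent) != 1L ||
      !object@parent %in% c("female", "male"))
    msg <- c(msg, "parent must be 'female' or 'male'")
  if (nrow(m)) {
    if (anyDuplicated(m$marker_id))
      msg <- c(msg, paste("duplicate marker ids:",
        paste(unique(m$marker_id[duplicated(m$marker_id)]), collapse = ", ")))
    if (any(m$cM < 0)) msg <- c(msg, "cM positions must be non-negative")
  }
  if (is.null(msg)) TRUE else msg
})

#' MarkerPlacements: filtered probe-to-contig alignments for one map
#'
#' The join between a [GeneticMap] and an assembly: for every retained marker
#' a unique placement (contig, 1-based start, strand) carrying the marker's
#' linkage group and centimorgan position; plus a rejection ledger giving,
#' for every non-retained marker, the reason (`unmapped`, `ambiguous`, or
#' `quality`), and the marker counts needed for anchoring reports.
#'
#' @slot placements DataFrame: `marker_id`, `contig`, `position`, `strand`,
#'   `matches`, `mismatches`, `linkage_group`, `cM`, `parent`.
#' @slot rejections DataFrame: `marker_id`, `reason`.
#' @slot counts Named integer vector: `total`, `positioned`, `unique_best`,
#'   `passed`.
#' @slot parent Character scalar.
#'
#' @export
setClass("MarkerPlacements",
  representation(placements = "DataFrame", rejections = "DataFrame",
                 counts = "integer", parent = "character"))

setValidity("MarkerPlacements", function(object) {
  p <- object@placements
  need <- c("marker_id", "contig", "position", "strand", "linkage_group",
            "cM", "parent")
  if (!all(need %in% names(p)))
    return(paste("placements must have columns:", paste(need, collapse = ", ")))
  if (nrow(p) && anyDuplicated(p$marker_id))
    return("a marker may have at most one placement")
  TRUE
})

#' AnchorPlan: the integrated per-chromosome contig layout
#'
#' @slot anchored DataFrame: `chromosome`, `rank`, `contig`, `orientation`
#'   (`+`, `-` or `?`), `female_cM`, `male_cM` (NA when the map gives no
#'   position), `support` (`female`, `male` or `both`).
#' @slot chr0 Character vector of unanchored contig names.
#' @slot excluded DataFrame: `contig`, `female_lg`, `male_lg`, `reason` —
#'   contigs whose two maps conflict, plus contigs with irresolvable marker
#'   patterns.
#' @slot splits DataFrame of applied split proposals (may be empty).
#'
#' @export
setClass("AnchorPlan",
  representation(anchored = "DataFrame", chr0 = "character",
                 excluded = "DataFrame", splits = "DataFrameOrNULL"))

setValidity("AnchorPlan", function(object) {
  a <- object@anchored
  need <- c("chromosome", "rank", "contig", "orientation", "female_cM",
            "male_cM", "support")
  if (!all(need %in% names(a)))
    return(paste("anchored must have columns:", paste(need, collapse = ", ")))
  msg <- NULL
  all3 <- c(a$contig, object@chr0,
            if (nrow(object@excluded)) object@excluded$contig)
  if (anyDuplicated(all3))
    msg <- c(msg, "a contig may appear only once across the whole plan")
  if (nrow(a) && !all(a$orientation %in% c("+", "-", "?")))
    msg <- c(msg, "orientation must be one of +, -, ?")
  if (is.null(msg)) TRUE else msg
})
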