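#' @include AllClasses.R
NULL

#' Accessors for AnchorMap classes
#'
#' Small accessor family: `genomeSeqs` and `centromereTruth` for
#' [SimGenome-class]; `contigSeqs` and `contigTruth` for [ContigSet-class];
#' `markers` and `parentLabel` for [GeneticMap-class]; `placements`,
#' `rejections` and `placementCounts` for [MarkerPlacements-class];
#' `anchoredContigs`, `chr0Contigs` and `excludedContigs` for
#' [AnchorPlan-class].
#'
#' @param x An AnchorMap object.
#' @return The corresponding slot value (a `DNAStringSet`, `GRanges`,
#'   `DataFrame`, character vector or named integer vector).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeSeqs", function(x) standardGeneric("genomeSeqs"))
#' @rdname accessors
#' @export
setGeneric("centromereTruth", function(x) standardGeneric("centromereTruth"))
#' @rdname accessors
#' @export
setGeneric("contigSeqs", function(x) standardGeneric("contigSeqs"))
#' @rdname accessors
#' @export
setGeneric("contigTruth", function(x) standardGeneric("contigTruth"))
#' @rdname accessors
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))
#' @rdname accessors
#' @export
setGeneric("parentLabel", function(x) standardGeneric("parentLabel"))
#' @rdname accessors
#' @export
setGeneric("placements", function(x) standardGeneric("placements"))
#' @rdname accessors
#' @export
setGeneric("rejections", function(x) standardGeneric("rejections"))
#' @rdname accessors
#' @export
setGeneric("placementCounts", function(x) standardGeneric("placementCounts"))
#' @rdname accessors
#' @export
setGeneric("anchoredContigs", function(x) standardGeneric("anchoredContigs"))
#' @rdname accessors
#' @export
setGeneric("chr0Contigs", function(x) standardGeneric("chr0Contigs"))
#' @rdname accessors
#' @export
setGeneric("excludedContigs", function(x) standardGeneric("excludedContigs"))

#' @rdname accessors
setMethod("genomeSeqs", "SimGenome", function(x) x@genome)
#' @rdname accessors
setMethod("centromereTruth", "SimGenome", function(x) x@centromeres)
#' @rdname accessors
setMethod("contigSeqs", "ContigSet", function(x) x@contigs)
#' @rdname accessors
setMethod("contigTruth", "ContigSet", function(x) x@truth)
#' @rdname accessors
setMethod("markers", "GeneticMap", function(x) x@markers)
#' @rdname accessors
setMethod("parentLabel", "GeneticMap", function(x) x@parent)
#' @rdname accessors
setMethod("placements", "MarkerPlacements", function(x) x@placements)
#' @rdname accessors
setMethod("rejections", "MarkerPlacements", function(x) x@rejections)
#' @rdname accessors
setMethod("placementCounts", "MarkerPlacements", function(x) x@counts)
#' @rdname accessors
setMethod("anchoredContigs", "AnchorPlan", function(x) x@anchored)
#' @rdname accessors
setMethod("chr0Contigs", "AnchorPlan", function(x) x@chr0)
#' @rdname accessors
setMethod("excludedContigs", "AnchorPlan", function(x) x@excluded)

setMethod("show", "SimGenome", function(object) {
  cat("SimGenome:", length(object@genome), "chromosome(s),",
      sum(Biostrings::width(object@genome)), "bp total;",
      length(object@centromeres), "planted array(s); seed",
      object@seed, "\n")
})

setMethod("show", "ContigSet", function(object) {
  nchim <- sum(table(object@truth$contig) == 2L)
  cat("ContigSet:", length(object@contigs), "contig(s),",
      sum(Biostrings::width(object@contigs)), "bp total;",
      nchim, "chimera(s); seed", object@seed, "\n")
})

setMethod("show", "GeneticMap", function(object) {
  m <- object@markers
  cat("GeneticMap (", object@parent, "): ", nrow(m), " marker(s) on ",
      length(unique(m$linkage_group)), " linkage group(s)\n", sep = "")
})

setMethod("show", "MarkerPlacements", function(object) {
  cat("MarkerPlacements (", object@parent, "): ",
      nrow(object@placements), " placed, ",
      nrow(object@rejections), " rejected\n", sep = "")
})

setMethod("show", "AnchorPlan", function(object) {
  a <- object@anchored
  cat("AnchorPlan:", nrow(a), "contig(s) anchored on",
      length(unique(a$chromosome)), "chromosome(s);",
      length(object@chr0), "on Chr0;",
      nrow(object@excluded), "excluded\n")
})
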