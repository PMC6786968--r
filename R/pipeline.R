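#' Anchor a draft assembly to parental genetic maps, end to end
#'
#' Runs the full anchoring pipeline: both parental maps are placed on the
#' contigs ([placeMarkers()]); chimeric contigs are detected from the
#' combined placements and split ([detectChimeras()], [splitContigs()]);
#' both maps are re-placed on the split contigs; contigs are assigned to
#' linkage groups, ordered by mean centimorgan and oriented
#' ([assignLinkageGroups()], [orderContigs()], [orientContigs()]); the two
#' per-map orders are integrated with female priority ([integrateMaps()]);
#' and pseudo-molecules plus their AGP ledger are built
#' ([buildPseudomolecules()]) and summarized ([anchoringReport()]).
#'
#' @param contigs A named [Biostrings::DNAStringSet] of draft contigs.
#' @param femaleMap,maleMap The parental [GeneticMap-class] objects.
#' @param k Seed length for probe alignment (default 11).
#' @param minMatch,maxMismatch Identity thresholds (defaults 0.95 / 0.04).
#' @param minMarkers Minimum concordant markers to anchor a contig
#'   (default 2).
#' @param band Hit reporting band in score points (default 10).
#' @param gap Inter-contig gap in the pseudo-molecules (default 10000).
#' @return A list: `plan` ([AnchorPlan-class]), `contigs` (post-split
#'   `DNAStringSet`), `placements` (list `female`/`male`), `assignments`
#'   (combined), `proposals` (split proposals), `sequences`
#'   (pseudo-molecules), `agp`, `unplaced`, `report`.
#' @export
anchorAssembly <- function(contigs, femaleMap, maleMap, k = 11,
                           minMatch = 0.95, maxMismatch = 0.04,
                           minMarkers = 2, band = 10, gap = 10000) {
  probeLength <- nchar(markers(femaleMap)$probe_seq[1L]) %||% 70L

  pf <- placeMarkers(femaleMap, contigs, k = k, minMatch = minMatch,
                     maxMismatch = maxMismatch, band = band)
  pm <- placeMarkers(maleMap, contigs, k = k, minMatch = minMatch,
                     maxMismatch = maxMismatch, band = band)
  proposals <- detectChimeras(list(pf, pm), probeLength = probeLength)
  contigs2 <- splitContigs(contigs, proposals)
  if (nrow(proposals)) {
    pf <- placeMarkers(femaleMap, contigs2, k = k, minMatch = minMatch,
                       maxMismatch = maxMismatch, band = band)
    pm <- placeMarkers(maleMap, contigs2, k = k, minMatch = minMatch,
                       maxMismatch = maxMismatch, band = band)
  }
  post <- detectChimeras(list(pf, pm), probeLength = probeLength)
  irres <- attr(post, "irresolvable")

  asnF <- assignLinkageGroups(pf, minMarkers = minMarkers)
  asnM <- assignLinkageGroups(pm, minMarkers = minMarkers)
  asn <- assignLinkageGroups(list(pf, pm), minMarkers = minMarkers)
  lens <- setNames(Biostrings::width(contigs2), names(contigs2))
  of <- orderContigs(pf, asnF, lens)
  om <- orderContigs(pm, asnM, lens)
  ori <- orientContigs(list(pf, pm), asn)
  plan <- integrateMaps(of, om, ori, names(contigs2),
                        irresolvable = irres,
                        splits = if (nrow(proposals)) proposals else NULL)
  build <- buildPseudomolecules(plan, contigs2, gap = gap)
  report <- anchoringReport(plan, pf, pm, asn, build$sequences)
  list(plan = plan, contigs = contigs2,
       placements = list(female = pf, male = pm),
       assignments = asn, proposals = proposals,
       sequences = build$sequences, agp = build$agp,
       unplaced = build$unplaced, report = report)
}

#' Serialize an anchor plan as tab-separated text
#'
#' Writes the anchored layout (`chromosome  rank  contig  orientation
#' female_cM  male_cM  support`), followed by the Chr0 list and the
#' exclusion ledger as commented sections.
#'
#' @param plan An [AnchorPlan-class].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeAnchorPlan <- function(plan, path) {
  stopifnot(is(plan, "AnchorPlan"))
  con <- file(path, "w")
  on.exit(close(con))
  a <- as.data.frame(anchoredContigs(plan))
  writeLines(paste(names(a), collapse = "\t"), con)
  write.table(a, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  writeLines("## chr0", con)
  writeLines(paste0("# ", chr0Contigs(plan)), con)
  ex <- as.data.frame(excludedContigs(plan))
  writeLines("## excluded", con)
  if (nrow(ex))
    writeLines(paste("#", ex$contig, ex$reason, sep = "\t"), con)
  invisible(path)
}
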