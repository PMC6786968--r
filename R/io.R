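#' Write and read genetic maps as tab-separated text
#'
#' The exchange format is a TSV with header
#' `marker_id  linkage_group  cM  parent  probe_seq`, preceded by `##`
#' comment lines recording provenance (including the simulation seed for
#' simulated maps).
#'
#' @param map A [GeneticMap-class].
#' @param path File path.
#' @param seed Optional integer recorded as a `##seed=` header comment.
#' @return `writeGeneticMap()` returns `path` invisibly; `readGeneticMap()`
#'   returns a [GeneticMap-class].
#' @export
writeGeneticMap <- function(map, path, seed = NULL) {
  stopifnot(is(map, "GeneticMap"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##format=AnchorMap genetic map v1", con)
  if (!is.null(seed)) writeLines(paste0("##seed=", seed), con)
  m <- as.data.frame(markers(map))
  m <- m[, c("marker_id", "linkage_group", "cM", "parent", "probe_seq")]
  writeLines(paste(names(m), collapse = "\t"), con)
  write.table(m, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneticMap
#' @export
readGeneticMap <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  parent <- unique(m$parent)
  if (length(parent) != 1L)
    stop("a map file must contain exactly one parent, found: ",
         paste(parent, collapse = ", "))
  new("GeneticMap",
      markers = S4Vectors::DataFrame(
        marker_id = as.character(m$marker_id),
        linkage_group = as.integer(m$linkage_group),
        cM = as.numeric(m$cM), parent = m$parent,
        probe_seq = as.character(m$probe_seq)),
      parent = parent)
}

#' Write and read minimal VCF v4.2 variant tables
#'
#' `writeSimpleVcf()` writes one sample's variant table (columns `chrom`,
#' `pos`, `id`, `ref`, `alt`, `gt`) as a minimal single-sample VCF v4.2 with
#' CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO/FORMAT/GT columns.
#' `readSimpleVcf()` parses any VCF via [vcfR::read.vcfR()] and returns the
#' first sample's table in the same shape.
#'
#' @param variants A variant `data.frame` (see above).
#' @param path File path.
#' @param sample Sample name written to the header (default "sample").
#' @param contigLengths Optional named vector adding `##contig` header lines.
#' @param seed Optional integer recorded in a `##source=` header line.
#' @return `writeSimpleVcf()` returns `path` invisibly; `readSimpleVcf()`
#'   returns a variant `data.frame`.
#' @export
writeSimpleVcf <- function(variants, path, sample = "sample",
                           contigLengths = NULL, seed = NULL) {
  stopifnot(all(c("chrom", "pos", "id", "ref", "alt", "gt") %in%
                names(variants)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  src <- "##source=AnchorMap"
  if (!is.null(seed)) src <- paste0(src, " seed=", seed)
  writeLines(src, con)
  if (!is.null(contigLengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contigLengths),
                       as.integer(contigLengths)), con)
  writeLines(paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                    "Description=\"Genotype\">"), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample), collapse = "\t"), con)
  if (nrow(variants)) {
    v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
    writeLines(paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".",
                     "GT", v$gt, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname writeSimpleVcf
#' @export
readSimpleVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
             id = ifelse(is.na(fix$ID), ".", fix$ID),
             ref = fix$REF, alt = fix$ALT,
             gt = unname(gt[, 1L]))
}
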