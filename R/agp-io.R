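.agpCols <- c("object", "object_beg", "object_end", "part_number",
              "component_type", "component_id", "component_beg",
              "component_end", "orientation")

## Validity: parts tile each object without overlap or holes; N records carry
## their length in column 6 (with gap_type/linkage/evidence in columns 7-9).
.validateAGP <- function(agp) {
  agp <- as.data.frame(agp)
  if (!all(.agpCols %in% names(agp)))
    stop("AGP table must have columns: ", paste(.agpCols, collapse = ", "))
  for (obj in unique(agp$object)) {
    L <- agp[agp$object == obj, , drop = FALSE]
    L <- L[order(L$part_number), , drop = FALSE]
    if (any(L$object_end < L$object_beg))
      stop("AGP object ", obj, ": inverted span")
    exp_beg <- c(1L, head(L$object_end, -1L) + 1L)
    if (any(L$object_beg != exp_beg))
      stop("AGP object ", obj, ": parts do not tile the object")
    isW <- L$component_type == "W"
    spanW <- L$object_end[isW] - L$object_beg[isW] + 1L
    compW <- as.integer(L$component_end[isW]) -
      as.integer(L$component_beg[isW]) + 1L
    if (any(spanW != compW))
      stop("AGP object ", obj, ": component span does not match object span")
    isN <- L$component_type == "N"
    if (any(as.integer(L$component_id[isN]) !=
            L$object_end[isN] - L$object_beg[isN] + 1L))
      stop("AGP object ", obj, ": gap length does not match span")
  }
  agp
}

#' Write and read AGP v2.1
#'
#' `writeAGP()` serializes an AGP record table (as produced by
#' [buildPseudomolecules()]) as tab-separated AGP v2.1 with a
#' `##agp-version 2.1` pragma; `readAGP()` parses it back, validating that
#' every object is tiled without overlaps or holes and reporting the line
#' number of any malformed row. Round-tripping is the identity on the record
#' table. Gap rows store the gap length in column 6 and
#' `scaffold`/`yes`/`map` (gap type, linkage, evidence) in columns 7--9, per
#' the AGP specification.
#'
#' @param agp An AGP record table.
#' @param path File path.
#' @return `writeAGP()` returns `path` invisibly; `readAGP()` returns the
#'   record `data.frame`.
#' @export
writeAGP <- function(agp, path) {
  agp <- .validateAGP(agp)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  write.table(agp[, .agpCols], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeAGP
#' @export
readAGP <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad))
    stop("malformed AGP line ", which(keep)[bad[1L]], ": expected 9 fields")
  m <- do.call(rbind, fields)
  agp <- data.frame(object = m[, 1L],
                    object_beg = as.integer(m[, 2L]),
                    object_end = as.integer(m[, 3L]),
                    part_number = as.integer(m[, 4L]),
                    component_type = m[, 5L],
                    component_id = m[, 6L],
                    component_beg = m[, 7L],
                    component_end = m[, 8L],
                    orientation = m[, 9L])
  if (anyNA(agp$object_beg) || anyNA(agp$object_end) ||
      anyNA(agp$part_number))
    stop("malformed AGP: non-numeric coordinates")
  .validateAGP(agp)
}

#' Write and read FASTA (60-column wrap)
#'
#' Thin wrappers over [Biostrings::writeXStringSet()] and
#' [Biostrings::readDNAStringSet()] fixing the 60-column line width used for
#' assembly exchange.
#'
#' @param seqs A [Biostrings::DNAStringSet].
#' @param path File path.
#' @return `writeFastaFile()` returns `path` invisibly; `readFastaFile()`
#'   returns a `DNAStringSet` (names truncated at the first whitespace).
#' @export
writeFastaFile <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' @rdname writeFastaFile
#' @export
readFastaFile <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  names(s) <- sub("\\s.*$", "", names(s))
  s
}
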