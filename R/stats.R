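#' Anchoring metrics report
#'
#' Aggregates the pipeline's ledgers into the standard anchoring summary:
#' per chromosome, the concordant markers used from each parental map, the
#' contigs each map anchors, the integrated contig count and the
#' pseudo-molecule size; plus global totals (markers positioned, passed,
#' concordant per map; contigs split; Chr0 contigs and size). Totals are
#' column sums by construction.
#'
#' @param plan An [AnchorPlan-class].
#' @param femalePlacements,malePlacements The two [MarkerPlacements-class]
#'   objects the plan was derived from.
#' @param assignments Combined contig assignments from
#'   [assignLinkageGroups()].
#' @param pseudomolecules The `DNAStringSet` from [buildPseudomolecules()].
#' @return A list: `per_chromosome` (`DataFrame` with a `Total` row) and
#'   `global` (named numeric vector).
#' @export
anchoringReport <- function(plan, femalePlacements, malePlacements,
                            assignments, pseudomolecules) {
  stopifnot(is(plan, "AnchorPlan"))
  a <- as.data.frame(anchoredContigs(plan))
  asn <- as.data.frame(assignments)
  perMap <- function(mp) {
    p <- .placementsTable(mp)
    p$modal <- asn$modal_lg[match(p$contig, asn$contig)]
    p[!is.na(p$modal) & p$linkage_group == p$modal, , drop = FALSE]
  }
  fConc <- perMap(femalePlacements)
  mConc <- perMap(malePlacements)

  chroms <- unique(a$chromosome)
  chroms <- chroms[order(as.integer(sub("^Chr", "", chroms)))]
  width <- Biostrings::width(pseudomolecules)
  names(width) <- names(pseudomolecules)
  rows <- lapply(chroms, function(ch) {
    ctgs <- a$contig[a$chromosome == ch]
    data.frame(chromosome = ch,
      markers_female = sum(fConc$contig %in% ctgs),
      markers_male = sum(mConc$contig %in% ctgs),
      contigs_female = sum(a$chromosome == ch & a$support %in%
                             c("female", "both")),
      contigs_male = sum(a$chromosome == ch & a$support %in%
                           c("male", "both")),
      contigs_integrated = length(ctgs),
      size_bp = unname(width[ch]))
  })
  per <- do.call(rbind, rows)
  tot <- data.frame(chromosome = "Total",
    markers_female = sum(per$markers_female),
    markers_male = sum(per$markers_male),
    contigs_female = sum(per$contigs_female),
    contigs_male = sum(per$contigs_male),
    contigs_integrated = sum(per$contigs_integrated),
    size_bp = sum(per$size_bp))
  per <- rbind(per, tot)

  cf <- placementCounts(femalePlacements)
  cm <- placementCounts(malePlacements)
  chr0Size <- if ("Chr0" %in% names(width)) unname(width["Chr0"]) else 0
  global <- c(
    markers_total = unname(cf["total"] + cm["total"]),
    markers_positioned = unname(cf["positioned"] + cm["positioned"]),
    markers_passed = unname(cf["passed"] + cm["passed"]),
    concordant_female = nrow(fConc),
    concordant_male = nrow(mConc),
    contigs_split = if (is.null(plan@splits)) 0L else nrow(plan@splits),
    contigs_anchored = sum(per$contigs_integrated[per$chromosome != "Total"]),
    contigs_chr0 = length(chr0Contigs(plan)),
    contigs_excluded = nrow(excludedContigs(plan)),
    size_without_chr0 = tot$size_bp,
    size_chr0 = chr0Size,
    size_total = tot$size_bp + chr0Size)
  list(per_chromosome = S4Vectors::DataFrame(per), global = global)
}

#' Co-linearity of pseudo-chromosomes against an independent map
#'
#' Validates a built assembly against a genetic map that was not used for
#' anchoring: the independent map's probes are placed on the
#' pseudo-molecules, and for each linkage group the Spearman rank
#' correlation between pseudo-molecule coordinate and centimorgan position
#' is reported. Contigs whose independent-map markers majority-vote for a
#' different linkage group than the chromosome they sit on are listed as
#' relocation candidates — including Chr0 contigs carrying two or more
#' markers of one linkage group, which could potentially be anchored.
#'
#' @param placements [MarkerPlacements-class] of the independent map against
#'   the pseudo-molecules (from [placeMarkers()]).
#' @param agp AGP records of the build, used to attribute pseudo-molecule
#'   positions back to contigs.
#' @return A list: `per_lg` (`DataFrame`: `linkage_group`, `chromosome`,
#'   `n_markers`, `rho`) and `relocation_candidates` (`DataFrame`: `contig`,
#'   `current`, `proposed_lg`, `n_markers`).
#' @export
colinearityStats <- function(placements, agp) {
  p <- .placementsTable(placements)
  agp <- as.data.frame(agp)
  w <- agp[agp$component_type == "W", , drop = FALSE]

  per <- lapply(split(p, p$linkage_group), function(q) {
    ch <- paste0("Chr", q$linkage_group[1L])
    q <- q[q$contig == ch, , drop = FALSE]  # markers on the matching object
    rho <- if (nrow(q) >= 2L)
      suppressWarnings(cor(q$position, q$cM, method = "spearman"))
    else NA_real_
    data.frame(linkage_group = q$linkage_group[1L] %||%
                 NA_integer_, chromosome = ch,
               n_markers = nrow(q), rho = rho)
  })
  perLG <- do.call(rbind, c(per, list(make.row.names = FALSE)))

  ## attribute each placement to the underlying contig through the AGP
  p$src_contig <- NA_character_
  for (i in seq_len(nrow(p))) {
    hit <- w[w$object == p$contig[i] & w$object_beg <= p$position[i] &
             w$object_end >= p$position[i], , drop = FALSE]
    if (nrow(hit) == 1L) p$src_contig[i] <- hit$component_id
  }
  q <- p[!is.na(p$src_contig), , drop = FALSE]
  reloc <- list()
  for (ctg in unique(q$src_contig)) {
    rows <- q[q$src_contig == ctg, , drop = FALSE]
    tab <- table(rows$linkage_group)
    modal <- names(tab)[which.max(tab)]
    current <- rows$contig[1L]
    currentLG <- suppressWarnings(as.integer(sub("^Chr", "", current)))
    if (max(tab) >= 2L &&
        (is.na(currentLG) || currentLG == 0L ||
         as.integer(modal) != currentLG)) {
      reloc[[ctg]] <- data.frame(contig = ctg, current = current,
                                 proposed_lg = as.integer(modal),
                                 n_markers = as.integer(max(tab)))
    }
  }
  list(per_lg = S4Vectors::DataFrame(perLG),
       relocation_candidates = if (length(reloc))
         S4Vectors::DataFrame(do.call(rbind, c(reloc,
           list(make.row.names = FALSE))))
       else .emptyDF(contig = "character", current = "character",
                     proposed_lg = "integer", n_markers = "integer"))
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a

#' Windowed variant density
#'
#' Counts variants in fixed-origin windows `[0, w)`, `[w, 2w)`, ... on each
#' sequence and reports density per kb; the final partial window is
#' normalized by its true span so edge windows are not inflated.
#'
#' @param variants A variant `data.frame` (columns `chrom`, `pos`; 1-based,
#'   sorted).
#' @param seqLengths Named integer vector of sequence lengths.
#' @param window Window size in bases (default 200000).
#' @return A [S4Vectors::DataFrame]: `seqname`, `start`, `end` (1-based
#'   closed), `count`, `density_per_kb`.
#' @export
windowDensity <- function(variants, seqLengths, window = 200000) {
  stopifnot(!is.null(names(seqLengths)), window >= 1)
  window <- as.integer(window)
  rows <- lapply(names(seqLengths), function(sn) {
    L <- as.integer(seqLengths[[sn]])
    starts <- seq.int(1L, L, by = window)
    ends <- pmin(starts + window - 1L, L)
    pos <- variants$pos[variants$chrom == sn]
    idx <- pmin((pos - 1L) %/% window + 1L, length(starts))
    count <- tabulate(idx, nbins = length(starts))
    span <- ends - starts + 1L
    data.frame(seqname = sn, start = starts, end = ends, count = count,
               density_per_kb = count * 1000 / span)
  })
  S4Vectors::DataFrame(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Per-sample homozygosity summary
#'
#' Counts homozygous-alternate and heterozygous variant calls per sample and
#' their fractions (which sum to 1 per sample); samples without variants are
#' reported with missing fractions.
#'
#' @param variantList Named list of per-sample variant `data.frame`s (column
#'   `gt` with `"0/1"` or `"1/1"`, `|`-separated genotypes accepted).
#' @return A [S4Vectors::DataFrame]: `sample`, `n_variants`, `hom`, `het`,
#'   `hom_fraction`, `het_fraction`.
#' @export
hetSummary <- function(variantList) {
  rows <- lapply(names(variantList), function(s) {
    gt <- gsub("|", "/", variantList[[s]]$gt, fixed = TRUE)
    al <- strsplit(gt, "/", fixed = TRUE)
    het <- sum(vapply(al, function(x) length(unique(x)) > 1L, TRUE))
    hom <- length(gt) - het
    n <- length(gt)
    data.frame(sample = s, n_variants = n, hom = hom, het = het,
               hom_fraction = if (n) hom / n else NA_real_,
               het_fraction = if (n) het / n else NA_real_)
  })
  S4Vectors::DataFrame(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Merge homozygous SNPs across samples into a phylogeny-ready alignment
#'
#' Sites are the union of positions at which at least one sample carries a
#' homozygous-alternate SNP. At each site a sample contributes its
#' homozygous alternate allele, the reference allele when it has no variant
#' there, or `N` when its own call at the site is heterozygous (heterozygous
#' calls are excluded per sample). Constant columns are dropped, so the
#' matrix contains only variable sites — the input expected by
#' ascertainment-bias-corrected phylogenetic inference.
#'
#' @param variantList Named list of per-sample variant `data.frame`s sharing
#'   reference coordinates (columns `chrom`, `pos`, `ref`, `alt`, `gt`).
#' @return A character matrix (samples x sites) with column names
#'   `chrom:pos`; `attr(x, "sites")` holds the site table.
#' @export
homSnpAlignment <- function(variantList) {
  stopifnot(length(variantList) >= 2L, !is.null(names(variantList)))
  all <- do.call(rbind, lapply(names(variantList), function(s)
    cbind(variantList[[s]], sample = s)))
  all$key <- paste(all$chrom, all$pos, sep = ":")
  refmap <- tapply(all$ref, all$key, unique)
  if (any(lengths(refmap) > 1L))
    stop("conflicting REF alleles at: ",
         paste(head(names(refmap)[lengths(refmap) > 1L]), collapse = ", "))
  isHom <- !grepl("0", all$gt)
  sites <- sort(unique(all$key[isHom]))
  if (!length(sites))
    return(matrix(character(0), nrow = length(variantList), ncol = 0,
                  dimnames = list(names(variantList), NULL)))
  mat <- matrix(rep(unlist(refmap[sites]), each = length(variantList)),
                nrow = length(variantList),
                dimnames = list(names(variantList), sites))
  idx <- all$key %in% sites
  sub <- all[idx, , drop = FALSE]
  homSub <- !grepl("0", sub$gt)
  mat[cbind(sub$sample, sub$key)] <- ifelse(homSub, sub$alt, "N")
  variable <- vapply(seq_len(ncol(mat)), function(j) {
    v <- setdiff(unique(mat[, j]), "N")
    length(v) > 1L
  }, TRUE)
  mat <- mat[, variable, drop = FALSE]
  attr(mat, "sites") <- colnames(mat)
  mat
}

#' N50 of a length distribution
#'
#' The smallest length such that pieces at least that long cover at least
#' half of the total.
#'
#' @param lengths Numeric vector of piece lengths.
#' @return The N50 in the input's units.
#' @examples
#' contigN50(c(1, 1, 1, 1, 6))  # 6
#' @export
contigN50 <- function(lengths) {
  stopifnot(length(lengths) > 0, all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}
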