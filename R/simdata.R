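#' Simulate a multi-chromosome haploid genome with planted centromeric arrays
#'
#' Generates `nChrom` chromosomes of i.i.d. uniform A/C/G/T residues and
#' plants one tandem-repeat array per chromosome: a single genome-wide
#' satellite monomer repeated `copies` times, with per-base substitution
#' noise at `mutationRate`, inserted at a random position in the central
#' third of each chromosome. The default monomer length of 159 bp matches
#' the length class of plant centromeric satellites this emulates.
#'
#' @param nChrom Number of chromosomes (default 7).
#' @param chromLength Chromosome length in bases (scalar or per-chromosome).
#' @param monomerLength Satellite monomer length in bases (>= 2).
#' @param copies Array copy number per chromosome; 0 plants no array.
#' @param mutationRate Per-base substitution probability within the array,
#'   in `[0, 1)`.
#' @param seed Integer seed; the simulation is fully deterministic in it.
#' @return A [SimGenome-class] object.
#' @examples
#' g <- simulateGenome(nChrom = 1, chromLength = 20000, copies = 10, seed = 1)
#' centromereTruth(g)
#' @export
simulateGenome <- function(nChrom = 7, chromLength = 1e6, monomerLength = 159,
                           copies = 300, mutationRate = 0.02, seed) {
  stopifnot(nChrom >= 1, monomerLength >= 2, copies >= 0,
            mutationRate >= 0, mutationRate < 1)
  if (missing(seed)) stop("a seed is required")
  lens <- as.integer(rep_len(chromLength, nChrom))
  arrlen <- as.integer(copies) * as.integer(monomerLength)
  if (copies > 0 && any(arrlen >= lens))
    stop("planted array (", arrlen, " bp) does not fit in a chromosome")

  .setStream(seed, "genome")
  chroms <- vapply(lens, .randomDNA, "")
  names(chroms) <- paste0("chr", seq_len(nChrom))

  cen <- GenomicRanges::GRanges()
  if (copies > 0) {
    monomer <- .randomDNA(monomerLength)
    starts <- integer(nChrom)
    for (i in seq_len(nChrom)) {
      lo <- lens[i] %/% 3L
      hi <- lens[i] - lo - arrlen
      start <- lo + sample.int(max(hi - lo, 1L), 1L)
      array <- strrep(monomer, copies)
      array <- .mutateRate(array, mutationRate)
      substr(chroms[i], start, start + arrlen - 1L) <- array
      starts[i] <- start
    }
    cen <- GenomicRanges::GRanges(names(chroms),
      IRanges::IRanges(starts, width = arrlen),
      monomer = monomer, copies = as.integer(copies))
  }
  new("SimGenome", genome = Biostrings::DNAStringSet(chroms),
      centromeres = cen, seed = as.integer(seed))
}

#' Fragment a simulated genome into contigs, optionally planting chimeras
#'
#' Cuts every chromosome into segments at random breakpoints and emits
#' `nContigs` contigs that together tile the genome: clean contigs are single
#' segments; each of the `chimeraCount` chimeric contigs concatenates two
#' segments from two different chromosomes (the assembly artefact class that
#' anchoring must detect and split). Chimera junctions fall at least
#' `minSegment` bases from both contig ends so both sides can carry markers.
#'
#' @param sim A [SimGenome-class].
#' @param nContigs Number of contigs to emit (>= number of chromosomes).
#' @param chimeraCount Number of chimeric contigs (default 0).
#' @param minSegment Minimum segment length in bases (default 5000).
#' @param seed Integer seed.
#' @return A [ContigSet-class]; `contigTruth()` records each contig's source
#'   segments (chromosome, span, strand).
#' @export
fragmentContigs <- function(sim, nContigs, chimeraCount = 0,
                            minSegment = 5000, seed) {
  stopifnot(is(sim, "SimGenome"), chimeraCount >= 0,
            nContigs >= length(genomeSeqs(sim)))
  if (missing(seed)) stop("a seed is required")
  g <- genomeSeqs(sim)
  lens <- Biostrings::width(g)
  nSeg <- nContigs + chimeraCount
  if (nSeg * minSegment > sum(lens))
    stop("not enough sequence for ", nSeg, " segments of >= ",
         minSegment, " bases")

  .setStream(seed, "contigs")
  ## allocate segment counts per chromosome, proportional to length
  per <- pmax(1L, as.integer(round(nSeg * lens / sum(lens))))
  while (sum(per) != nSeg) {
    i <- if (sum(per) > nSeg) which.max(per) else which.min(per * minSegment / lens)
    per[i] <- per[i] + sign(nSeg - sum(per))
  }
  if (any(per * minSegment > lens))
    stop("chromosome too short for its allotted breakpoints")

  segs <- do.call(rbind, lapply(seq_along(lens), function(i) {
    k <- per[i]
    if (k == 1L) return(data.frame(chromosome = names(g)[i], start = 1L,
                                   end = lens[i]))
    ## k-1 internal breakpoints keeping every segment >= minSegment
    slack <- lens[i] - k * minSegment
    cuts <- sort(sample.int(slack + 1L, k - 1L, replace = FALSE)) - 1L
    starts <- c(0L, cuts + minSegment * seq_len(k - 1L)) + 1L
    ends <- c(starts[-1L] - 1L, lens[i])
    data.frame(chromosome = names(g)[i], start = starts, end = ends)
  }))
  segs$strand <- "+"

  ## choose chimera pairs from different chromosomes
  pairIdx <- integer(0)
  if (chimeraCount > 0) {
    avail <- seq_len(nrow(segs))
    pairs <- matrix(0L, nrow = chimeraCount, ncol = 2L)
    for (j in seq_len(chimeraCount)) {
      a <- sample(avail, 1L)
      bpool <- avail[segs$chromosome[avail] != segs$chromosome[a]]
      if (!length(bpool)) stop("cannot place chimera: one chromosome left")
      b <- if (length(bpool) == 1L) bpool else sample(bpool, 1L)
      pairs[j, ] <- c(a, b)
      avail <- setdiff(avail, c(a, b))
    }
    pairIdx <- as.vector(t(pairs))
  } else {
    pairs <- matrix(0L, 0L, 2L)
  }
  singles <- setdiff(seq_len(nrow(segs)), pairIdx)

  nOut <- length(singles) + nrow(pairs)
  ord <- sample.int(nOut)  # shuffle output order
  cname <- sprintf("contig%04d", seq_len(nOut))

  seqs <- character(nOut)
  truth <- vector("list", nOut)
  extract <- function(i, flip) {
    s <- as.character(Biostrings::subseq(g[[segs$chromosome[i]]],
                                         segs$start[i], segs$end[i]))
    if (flip) .revcomp(s) else s
  }
  slot <- 1L
  emit <- function(rows, flips) {
    s <- vapply(seq_along(rows), function(j) extract(rows[j], flips[j]), "")
    off <- c(0L, cumsum(nchar(s)))[seq_along(s)]
    nm <- cname[ord[slot]]
    truth[[ord[slot]]] <<- data.frame(
      contig = nm, segment = seq_along(rows),
      chromosome = segs$chromosome[rows],
      start = segs$start[rows], end = segs$end[rows],
      strand = ifelse(flips, "-", "+"),
      contig_start = off + 1L, contig_end = off + nchar(s))
    seqs[ord[slot]] <<- paste(s, collapse = "")
    slot <<- slot + 1L
  }
  for (i in singles) emit(i, FALSE)
  if (nrow(pairs)) for (j in seq_len(nrow(pairs)))
    emit(pairs[j, ], c(FALSE, runif(1) < 0.5))

  contigs <- Biostrings::DNAStringSet(seqs)
  names(contigs) <- cname
  new("ContigSet", contigs = contigs,
      truth = S4Vectors::DataFrame(do.call(rbind, truth)),
      seed = as.integer(seed))
}

#' Simulate female and male genetic maps with 70-bp probes
#'
#' Samples marker positions genome-wide, derives each marker's probe as the
#' 70-base genome substring starting at its position, and assigns centimorgan
#' coordinates linearly (`cM = cMperMb * position / 1e6`), so cM is monotone
#' in the genome coordinate within each linkage group (= chromosome). A
#' configurable fraction of probes carries exactly `probeMutations`
#' substitutions, to exercise the alignment quality filters. A fraction of
#' markers is shared between the two parental maps under identical ids,
#' mirroring a two-parent array genotyping design in which the female map is
#' the denser one.
#'
#' @param sim A [SimGenome-class].
#' @param nFemale,nMale Marker counts for the two parental maps.
#' @param sharedFraction Fraction of the smaller map's markers present in
#'   both maps (default 0.3).
#' @param probeMutations Substitutions per mutated probe (0--3).
#' @param mutatedFraction Fraction of markers whose probe is mutated
#'   (default 0).
#' @param cMperMb Linear map rate in centimorgan per megabase (default 4).
#' @param probeLength Probe length in bases (default 70).
#' @param seed Integer seed.
#' @return A list with elements `female` and `male` ([GeneticMap-class]) and
#'   `truth` (a `DataFrame`: `marker_id`, `chromosome`, `position`,
#'   `mutations`).
#' @export
simulateMaps <- function(sim, nFemale = 1000, nMale = 400,
                         sharedFraction = 0.3, probeMutations = 0,
                         mutatedFraction = 0, cMperMb = 4, probeLength = 70,
                         seed) {
  stopifnot(is(sim, "SimGenome"), cMperMb > 0, probeMutations <= 3,
            probeMutations >= 0, sharedFraction >= 0, sharedFraction <= 1,
            mutatedFraction >= 0, mutatedFraction <= 1)
  if (missing(seed)) stop("a seed is required")
  g <- genomeSeqs(sim)
  lens <- Biostrings::width(g)
  nShared <- round(sharedFraction * min(nFemale, nMale))
  nTotal <- nFemale + nMale - nShared
  if (nTotal > sum(pmax(lens - probeLength, 0L)))
    stop("marker count exceeds genome capacity")

  .setStream(seed, "maps")
  ## sample distinct genome positions (probe fully inside its chromosome)
  chromIdx <- sample(seq_along(lens), nTotal, replace = TRUE,
                     prob = lens / sum(lens))
  pos <- vapply(chromIdx, function(i)
    sample.int(lens[i] - probeLength + 1L, 1L), 0L)
  dup <- duplicated(paste(chromIdx, pos))
  while (any(dup)) {
    pos[dup] <- vapply(chromIdx[dup], function(i)
      sample.int(lens[i] - probeLength + 1L, 1L), 0L)
    dup <- duplicated(paste(chromIdx, pos))
  }
  ids <- sprintf("MK%05d", seq_len(nTotal))
  probes <- as.character(Biostrings::subseq(
    g[chromIdx], start = pos, width = probeLength))
  nmut <- ifelse(runif(nTotal) < mutatedFraction, probeMutations, 0L)
  for (i in which(nmut > 0)) probes[i] <- .mutateBases(probes[i], nmut[i])

  truth <- S4Vectors::DataFrame(marker_id = ids,
    chromosome = names(g)[chromIdx], position = pos,
    mutations = as.integer(nmut))

  lg <- chromIdx
  cM <- cMperMb * pos / 1e6
  pick <- sample.int(nTotal)
  sharedIdx <- pick[seq_len(nShared)]
  rest <- if (nShared > 0) pick[-seq_len(nShared)] else pick
  femOnly <- rest[seq_len(nFemale - nShared)]
  maleOnly <- rest[(nFemale - nShared) + seq_len(nMale - nShared)]

  mkMap <- function(idx, parent) {
    idx <- idx[order(lg[idx], pos[idx])]
    m <- S4Vectors::DataFrame(marker_id = ids[idx],
      linkage_group = as.integer(lg[idx]), cM = cM[idx],
      parent = parent, probe_seq = probes[idx])
    new("GeneticMap", markers = m, parent = parent)
  }
  list(female = mkMap(c(sharedIdx, femOnly), "female"),
       male = mkMap(c(sharedIdx, maleOnly), "male"),
       truth = truth)
}

#' Simulate per-sample variant tables
#'
#' Draws per-sample SNPs as a Bernoulli process along the genome at rate
#' `snpRate`, assigns heterozygous genotypes with probability `hetFraction`
#' (homozygous-alternate otherwise), and returns one sorted, 1-based variant
#' table per sample, emulating the resequencing panels whose windowed
#' densities and homozygosity summaries the stats functions compute.
#'
#' @param sim A [SimGenome-class].
#' @param nSamples Number of samples (default 8).
#' @param snpRate Per-base SNP probability in `[0, 1)`.
#' @param hetFraction Probability that a variant is heterozygous.
#' @param seed Integer seed.
#' @return A named list of `data.frame`s with columns `chrom`, `pos`, `id`,
#'   `ref`, `alt`, `gt` (`"0/1"` or `"1/1"`).
#' @export
simulateVariants <- function(sim, nSamples = 8, snpRate = 0.012,
                             hetFraction = 0.4, seed) {
  stopifnot(is(sim, "SimGenome"), snpRate >= 0, snpRate < 1,
            hetFraction >= 0, hetFraction <= 1, nSamples >= 1)
  if (missing(seed)) stop("a seed is required")
  g <- genomeSeqs(sim)
  lens <- Biostrings::width(g)
  .setStream(seed, "variants")
  bases <- c("A", "C", "G", "T")
  chromChars <- lapply(seq_along(lens), function(i) as.character(g[[i]]))
  out <- lapply(seq_len(nSamples), function(s) {
    tabs <- lapply(seq_along(lens), function(i) {
      n <- rbinom(1L, lens[i], snpRate)
      if (n == 0L) return(NULL)
      p <- sort(sample.int(lens[i], n))
      ref <- substring(chromChars[[i]], p, p)
      ri <- match(ref, bases)
      alt <- bases[((ri - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L]
      data.frame(chrom = names(g)[i], pos = p,
                 id = ".", ref = ref, alt = alt,
                 gt = ifelse(runif(n) < hetFraction, "0/1", "1/1"))
    })
    tabs <- Filter(Negate(is.null), tabs)
    if (!length(tabs)) return(NULL)
    r <- do.call(rbind, tabs)
    rownames(r) <- NULL
    r
  })
  names(out) <- sprintf("sample%02d", seq_len(nSamples))
  out[vapply(out, is.null, TRUE)] <- list(
    data.frame(chrom = character(), pos = integer(), id = character(),
               ref = character(), alt = character(), gt = character()))
  out
}
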