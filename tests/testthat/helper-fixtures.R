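## Shared fixtures, built once per test run and cached.
.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

## a dense, noise-free map built deterministically at regular spacing, so
## every contig segment longer than 2 * spacing carries >= 2 markers
denseMap <- function(sim, spacing, parent, cMperMb = 4, probeLength = 70) {
  g <- genomeSeqs(sim)
  rows <- list()
  for (i in seq_along(g)) {
    pos <- seq.int(spacing, Biostrings::width(g)[i] - probeLength, by = spacing)
    rows[[i]] <- data.frame(
      chromosome = names(g)[i], linkage_group = i, position = pos)
  }
  tab <- do.call(rbind, rows)
  tab$marker_id <- sprintf("%s_%05d", toupper(substr(parent, 1, 1)),
                           seq_len(nrow(tab)))
  probes <- as.character(Biostrings::subseq(
    g[match(tab$chromosome, names(g))], start = tab$position,
    width = probeLength))
  m <- S4Vectors::DataFrame(
    marker_id = tab$marker_id,
    linkage_group = as.integer(tab$linkage_group),
    cM = cMperMb * tab$position / 1e6,
    parent = parent, probe_seq = probes)
  map <- new("GeneticMap", markers = m, parent = parent)
  attr(map, "truth") <- tab
  map
}

## noise-free anchoring fixture: 3 chromosomes, clean fragmentation, dense
## maps; used by recovery and co-linearity tests
cleanAnchorFixture <- function() {
  sim <- simulateGenome(nChrom = 3, chromLength = 15e4, copies = 0, seed = 11)
  cs <- fragmentContigs(sim, nContigs = 15, chimeraCount = 0, seed = 11)
  fem <- denseMap(sim, spacing = 2000, parent = "female")
  mal <- denseMap(sim, spacing = 5000, parent = "male")
  res <- anchorAssembly(contigSeqs(cs), fem, mal)
  list(sim = sim, cs = cs, female = fem, male = mal, res = res)
}

## fixture with planted chimeras, dense maps
chimeraFixture <- function() {
  sim <- simulateGenome(nChrom = 3, chromLength = 15e4, copies = 0, seed = 23)
  cs <- fragmentContigs(sim, nContigs = 14, chimeraCount = 3, seed = 23)
  fem <- denseMap(sim, spacing = 1500, parent = "female")
  mal <- denseMap(sim, spacing = 4000, parent = "male")
  list(sim = sim, cs = cs, female = fem, male = mal)
}

## expected contig for a genome coordinate, from the truth ledger
truthContigAt <- function(cs, chromosome, position) {
  tr <- as.data.frame(contigTruth(cs))
  hit <- tr[tr$chromosome == chromosome & tr$start <= position &
            tr$end >= position, , drop = FALSE]
  hit
}
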