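test_that("anchoring report totals are column sums and funnel counts nest", {
  fx <- fixture("clean", cleanAnchorFixture)
  rep <- fx$res$report
  per <- as.data.frame(rep$per_chromosome)
  tot <- per[per$chromosome == "Total", ]
  body <- per[per$chromosome != "Total", ]
  for (col in c("markers_female", "markers_male", "contigs_female",
                "contigs_male", "contigs_integrated", "size_bp"))
    expect_identical(sum(body[[col]]), tot[[col]])
  g <- rep$global
  expect_lte(g["concordant_female"] + g["concordant_male"],
             g["markers_passed"])
  expect_lte(g["markers_passed"], g["markers_positioned"])
  expect_lte(g["markers_positioned"], g["markers_total"])
  expect_identical(unname(g["size_total"]),
                   unname(g["size_without_chr0"] + g["size_chr0"]))
  ## pseudo-molecule sizes follow the gap law against the plan
  a <- as.data.frame(anchoredContigs(fx$res$plan))
  lens <- setNames(Biostrings::width(fx$res$contigs),
                   names(fx$res$contigs))
  for (ch in unique(a$chromosome)) {
    ctgs <- a$contig[a$chromosome == ch]
    expected <- sum(lens[ctgs]) + 10000L * (length(ctgs) - 1L)
    expect_identical(body$size_bp[body$chromosome == ch],
                     as.integer(expected))
  }
})

test_that("an empty plan yields an all-zero report", {
  emptyPlan <- new("AnchorPlan",
    anchored = S4Vectors::DataFrame(chromosome = character(0),
      rank = integer(0), contig = character(0), orientation = character(0),
      female_cM = numeric(0), male_cM = numeric(0), support = character(0)),
    chr0 = character(0),
    excluded = S4Vectors::DataFrame(contig = character(0),
      female_lg = integer(0), male_lg = integer(0), reason = character(0)),
    splits = NULL)
  emptyMap <- new("GeneticMap",
    markers = S4Vectors::DataFrame(marker_id = character(0),
      linkage_group = integer(0), cM = numeric(0), parent = character(0),
      probe_seq = character(0)), parent = "female")
  ctg <- Biostrings::DNAStringSet(c(x = "ACGT"))
  pl <- placeMarkers(emptyMap, ctg)
  rep <- anchoringReport(emptyPlan, pl, pl, assignLinkageGroups(pl),
                         Biostrings::DNAStringSet())
  expect_true(all(rep$global == 0))
})

test_that("co-linearity against the anchoring map itself is perfect", {
  fx <- fixture("clean", cleanAnchorFixture)
  pl <- placeMarkers(fx$female, fx$res$sequences)
  col <- colinearityStats(pl, fx$res$agp)
  per <- as.data.frame(col$per_lg)
  expect_equal(per$rho, rep(1, nrow(per)))
  expect_identical(nrow(as.data.frame(col$relocation_candidates)), 0L)
})

test_that("an independent map validates the build and flags plantable Chr0 contigs", {
  sim <- simulateGenome(nChrom = 3, chromLength = 15e4, copies = 0,
                        seed = 11)
  cs <- fragmentContigs(sim, nContigs = 15, chimeraCount = 0, seed = 11)
  fem <- denseMap(sim, spacing = 2000, parent = "female")
  mal <- denseMap(sim, spacing = 5000, parent = "male")
  ## hold one contig out of both anchoring maps so it lands on Chr0
  tr <- as.data.frame(contigTruth(cs))
  target <- tr$contig[which.max(tr$end - tr$start)][1]
  seg <- tr[tr$contig == target, ][1, ]
  drop <- function(map) {
    m <- markers(map)
    t2 <- attr(map, "truth")
    inTarget <- t2$chromosome == seg$chromosome &
      t2$position >= seg$start & t2$position + 69 <= seg$end
    new("GeneticMap", markers = m[!inTarget, ], parent = parentLabel(map))
  }
  res <- anchorAssembly(contigSeqs(cs), drop(fem), drop(mal))
  expect_true(target %in% chr0Contigs(res$plan))
  ## the independent (full) map sees the held-out contig
  indep <- denseMap(sim, spacing = 3000, parent = "female", cMperMb = 4)
  pl <- placeMarkers(indep, res$sequences)
  col <- colinearityStats(pl, res$agp)
  per <- as.data.frame(col$per_lg)
  expect_true(all(per$rho > 0.95))
  reloc <- as.data.frame(col$relocation_candidates)
  expect_true(target %in% reloc$contig)
  row <- reloc[reloc$contig == target, ]
  expect_identical(row$proposed_lg,
                   match(seg$chromosome, names(genomeSeqs(sim))))
  expect_identical(row$current, "Chr0")
})

test_that("window densities tile, count and normalize correctly", {
  v <- data.frame(chrom = "chr1",
                  pos = c(10L, 150000L, 199999L, 200000L, 900001L),
                  id = ".", ref = "A", alt = "C", gt = "1/1")
  wd <- as.data.frame(windowDensity(v, c(chr1 = 1000000L)))
  expect_identical(nrow(wd), 5L)
  expect_identical(wd$count, c(4L, 0L, 0L, 0L, 1L))
  expect_equal(wd$density_per_kb, wd$count * 1000 / 200000)
  expect_identical(sum(wd$count), nrow(v))
  ## final partial window is normalized by its true span
  v2 <- data.frame(chrom = "c", pos = c(1L, 250100L), id = ".", ref = "A",
                   alt = "C", gt = "1/1")
  wd2 <- as.data.frame(windowDensity(v2, c(c = 250200L)))
  expect_identical(nrow(wd2), 2L)
  expect_identical(wd2$end[2] - wd2$start[2] + 1L, 50200L)
  expect_equal(wd2$density_per_kb[2], 1 * 1000 / 50200)
  ## density recomputed from count matches at tight tolerance
  expect_equal(wd2$density_per_kb, wd2$count * 1000 /
                 (wd2$end - wd2$start + 1), tolerance = 1e-9)
})

test_that("heterozygosity summaries recover the simulated fraction", {
  sim <- simulateGenome(nChrom = 1, chromLength = 200000, copies = 0,
                        seed = 97)
  v <- simulateVariants(sim, nSamples = 3, snpRate = 2e-3,
                        hetFraction = 0.3, seed = 97)
  hs <- as.data.frame(hetSummary(v))
  expect_equal(hs$hom_fraction + hs$het_fraction, rep(1, 3))
  for (i in 1:3) {
    n <- hs$n_variants[i]
    se <- sqrt(0.3 * 0.7 / n)
    expect_lt(abs(hs$hom_fraction[i] - 0.7), 5 * se)
  }
  ## all-het and empty edge cases
  allHet <- list(s = data.frame(chrom = "c", pos = 1:3, id = ".", ref = "A",
                                alt = "C", gt = "0/1"))
  expect_equal(as.data.frame(hetSummary(allHet))$het_fraction, 1)
  none <- list(s = data.frame(chrom = character(0), pos = integer(0),
    id = character(0), ref = character(0), alt = character(0),
    gt = character(0)))
  expect_true(is.na(as.data.frame(hetSummary(none))$hom_fraction))
})

test_that("homozygous-SNP alignments merge sites as specified", {
  s1 <- data.frame(chrom = "c", pos = c(10L, 20L, 30L), id = ".",
                   ref = c("A", "C", "G"), alt = c("T", "G", "A"),
                   gt = "1/1")
  s2 <- data.frame(chrom = "c", pos = c(40L, 50L), id = ".",
                   ref = c("T", "A"), alt = c("C", "G"), gt = "1/1")
  al <- homSnpAlignment(list(a = s1, b = s2))
  expect_identical(dim(al), c(2L, 5L))
  ## sample without a call shows the reference allele
  expect_identical(unname(al["b", "c:10"]), "A")
  expect_identical(unname(al["a", "c:10"]), "T")

  ## a site heterozygous in every sample is not a site at all
  h1 <- data.frame(chrom = "c", pos = 60L, id = ".", ref = "A", alt = "C",
                   gt = "0/1")
  h2 <- data.frame(chrom = "c", pos = 60L, id = ".", ref = "A", alt = "G",
                   gt = "0/1")
  al2 <- homSnpAlignment(list(a = rbind(s1, h1), b = rbind(s2, h2)))
  expect_false("c:60" %in% colnames(al2))
  ## column count is bounded by the distinct hom positions
  expect_lte(ncol(al2), 5L)
  ## a het call at someone else's hom site is masked, not reference
  ## (a third sample keeps the column variable so it survives)
  m1 <- data.frame(chrom = "c", pos = 70L, id = ".", ref = "G", alt = "T",
                   gt = "1/1")
  m2 <- data.frame(chrom = "c", pos = 70L, id = ".", ref = "G", alt = "C",
                   gt = "0/1")
  s3 <- data.frame(chrom = "c", pos = 90L, id = ".", ref = "A", alt = "C",
                   gt = "1/1")
  al3 <- homSnpAlignment(list(a = rbind(s1, m1), b = rbind(s2, m2), c = s3))
  expect_identical(unname(al3["b", "c:70"]), "N")
  expect_identical(unname(al3["c", "c:70"]), "G")
  ## conflicting REF alleles are an error
  bad <- data.frame(chrom = "c", pos = 10L, id = ".", ref = "G", alt = "C",
                    gt = "1/1")
  expect_error(homSnpAlignment(list(a = s1, b = rbind(s2, bad))),
               "conflicting REF")
})

test_that("k-mer spectrum recovers genome size and repeat structure", {
  sim <- simulateGenome(nChrom = 1, chromLength = 2e5, copies = 0,
                        seed = 101)
  reads <- simulateReads(sim, coverage = 20, readLength = 100, seed = 101)
  est <- kmerGenomeSize(reads, k = 25)
  expect_lt(abs(est$size / 2e5 - 1), 0.02)
  expect_gt(est$unique_fraction, 0.85)
  ## a genome dominated by one repeated 1-kb unit is called mostly
  ## repetitive (a small unique portion anchors the single-copy coverage
  ## peak; a genome with no unique sequence at all has no such peak)
  set.seed(5)
  unit <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  uniqTail <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE),
                    collapse = "")
  repReads <- simulateReads(Biostrings::DNAStringSet(
    c(r = paste0(strrep(unit, 100), uniqTail))),
    coverage = 20, readLength = 100, seed = 5)
  est2 <- kmerGenomeSize(repReads, k = 25)
  expect_gt(est2$repetitive_fraction, 0.9)
  ## k beyond the read length is an error
  expect_error(kmerGenomeSize(reads, k = 25 + 100), "exceeds")
})

test_that("N50 equals the definition scan on random inputs", {
  expect_identical(contigN50(c(1, 1, 1, 1, 6)), 6)
  expect_identical(contigN50(c(5, 5)), 5)
  set.seed(103)
  for (i in 1:20) {
    lens <- sample.int(1000, sample(2:40, 1), replace = TRUE)
    expect_identical(contigN50(lens), bruteForceN50(lens))
  }
})
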