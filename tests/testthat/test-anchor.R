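## small hand-built placement tables for the unit cases
mkPlac <- function(contig, lg, pos, cM = seq_along(pos), parent = "female") {
  S4Vectors::DataFrame(marker_id = sprintf("%s_m%d", contig, seq_along(lg)),
    contig = contig, position = as.integer(pos), strand = "+",
    matches = 70L, mismatches = 0L, linkage_group = as.integer(lg),
    cM = as.numeric(cM), parent = parent)
}

test_that("modal linkage-group assignment flags concordant and discordant markers", {
  p <- mkPlac("ctgA", c(2, 2, 3), c(100, 200, 300))
  a <- as.data.frame(assignLinkageGroups(p))
  expect_identical(a$modal_lg, 2L)
  expect_identical(a$concordant, 2L)
  expect_identical(a$discordant, 1L)
  expect_true(a$anchorable)

  ## one marker is not enough (anchoring needs more than one)
  a1 <- as.data.frame(assignLinkageGroups(mkPlac("ctgB", 1, 100)))
  expect_false(a1$anchorable)

  ## tie: no modal assignment
  a2 <- as.data.frame(assignLinkageGroups(
    mkPlac("ctgC", c(1, 1, 5, 5), c(10, 20, 40, 50) * 1000)))
  expect_true(a2$tied)
  expect_true(is.na(a2$modal_lg))
  expect_false(a2$anchorable)
})

test_that("two-block marker patterns yield split proposals with the stated interval", {
  p <- mkPlac("ctgC", c(1, 1, 5, 5), c(10, 20, 40, 50) * 1000)
  pr <- detectChimeras(p, probeLength = 70)
  expect_identical(nrow(pr), 1L)
  expect_identical(pr$left_lg[1], 1L)
  expect_identical(pr$right_lg[1], 5L)
  expect_identical(pr$break_left[1], 20000L + 69L)
  expect_identical(pr$break_right[1], 40000L)

  ## single-group contigs yield nothing
  expect_identical(nrow(detectChimeras(mkPlac("x", c(1, 1, 1), 1:3 * 100))),
                   0L)
  ## interleaved patterns are irresolvable, not split
  bad <- mkPlac("y", c(1, 5, 1, 5), c(1, 2, 3, 4) * 1000)
  prBad <- detectChimeras(bad)
  expect_identical(nrow(prBad), 0L)
  expect_identical(attr(prBad, "irresolvable"), "y")
})

test_that("splitting conserves residues and counts, and is the identity without proposals", {
  set.seed(61)
  ctg <- Biostrings::DNAStringSet(c(
    a = paste(sample(c("A", "C", "G", "T"), 100000, TRUE), collapse = ""),
    b = strrep("ACGT", 25)))
  pr <- S4Vectors::DataFrame(contig = "a", left_lg = 1L, right_lg = 2L,
                             break_left = 59999L, break_right = 60001L)
  out <- splitContigs(ctg, pr)
  expect_identical(length(out), 3L)
  expect_setequal(names(out), c("a_a", "a_b", "b"))
  expect_identical(Biostrings::width(out)[match("a_a", names(out))], 60000L)
  expect_identical(Biostrings::width(out)[match("a_b", names(out))], 40000L)
  expect_identical(sum(Biostrings::width(out)), sum(Biostrings::width(ctg)))
  expect_identical(paste0(as.character(out[["a_a"]]),
                          as.character(out[["a_b"]])),
                   as.character(ctg[["a"]]))
  ## identity without proposals
  expect_identical(splitContigs(ctg, pr[0, ]), ctg)
  ## unknown contig and double split are errors
  expect_error(splitContigs(ctg, S4Vectors::DataFrame(contig = "zz",
    left_lg = 1L, right_lg = 2L, break_left = 10L, break_right = 20L)),
    "unknown")
  expect_error(splitContigs(ctg, rbind(pr, pr)), "one split per contig")
})

test_that("contigs are ordered by mean cM with deterministic tie-breaking", {
  p <- rbind(mkPlac("slow", c(1, 1), c(100, 200), cM = c(3.0, 3.2)),
             mkPlac("fast", c(1, 1), c(100, 200), cM = c(7.3, 7.5)))
  a <- assignLinkageGroups(p)
  o <- as.data.frame(orderContigs(p, a, c(slow = 500L, fast = 400L)))
  expect_identical(o$contig, c("slow", "fast"))
  expect_equal(o$mean_cM, c(3.1, 7.4))
  ## equal means: longer contig first, then name
  q <- rbind(mkPlac("zzz", c(1, 1), c(100, 200), cM = c(5, 5)),
             mkPlac("aaa", c(1, 1), c(100, 200), cM = c(5, 5)),
             mkPlac("mmm", c(1, 1), c(100, 200), cM = c(5, 5)))
  oq <- as.data.frame(orderContigs(q, assignLinkageGroups(q),
    c(zzz = 900L, aaa = 100L, mmm = 100L)))
  expect_identical(oq$contig, c("zzz", "aaa", "mmm"))
})

test_that("orientation follows the physical-genetic correlation sign", {
  up <- mkPlac("u", c(1, 1), c(10000, 80000), cM = c(2, 5))
  a <- assignLinkageGroups(up)
  expect_identical(unname(orientContigs(up, a)["u"]), "+")
  down <- mkPlac("d", c(1, 1), c(10000, 80000), cM = c(5, 2))
  expect_identical(unname(orientContigs(down, assignLinkageGroups(down))["d"]),
                   "-")
  flat <- mkPlac("f", c(1, 1), c(10000, 80000), cM = c(3, 3))
  expect_identical(unname(orientContigs(flat, assignLinkageGroups(flat))["f"]),
                   "?")
  ## disagreement between maps gives "?"
  both <- rbind(mkPlac("x", c(1, 1), c(1000, 9000), cM = c(1, 2),
                       parent = "female"),
                mkPlac("x", c(1, 1), c(1000, 9000), cM = c(2, 1),
                       parent = "male"))
  expect_identical(unname(orientContigs(both,
    assignLinkageGroups(both))["x"]), "?")
})

test_that("map integration follows female priority with male-only insertion", {
  fo <- S4Vectors::DataFrame(linkage_group = c(1L, 1L), rank = c(1L, 2L),
    contig = c("f1", "f2"), mean_cM = c(1.0, 5.0), n_markers = c(3L, 3L))
  mo <- S4Vectors::DataFrame(linkage_group = c(1L, 1L),
    rank = c(1L, 2L), contig = c("f1", "mOnly"),
    mean_cM = c(0.8, 2.5), n_markers = c(2L, 2L))
  ori <- c(f1 = "+", f2 = "+", mOnly = "-")
  plan <- integrateMaps(fo, mo, ori, c("f1", "f2", "mOnly", "unanchored"))
  a <- as.data.frame(anchoredContigs(plan))
  expect_identical(a$contig, c("f1", "mOnly", "f2"))
  expect_identical(a$support, c("both", "male", "female"))
  expect_identical(a$orientation[2], "-")
  expect_true(is.na(a$female_cM[2]))
  expect_identical(chr0Contigs(plan), "unanchored")

  ## female-only contig placed by female mean cM
  planF <- integrateMaps(fo, mo[0, ], ori, c("f1", "f2"))
  expect_identical(as.data.frame(anchoredContigs(planF))$support,
                   c("female", "female"))

  ## linkage-group conflict excludes the contig and reports it
  moC <- S4Vectors::DataFrame(linkage_group = 5L, rank = 1L, contig = "f1",
    mean_cM = 2.0, n_markers = 2L)
  planC <- integrateMaps(fo, moC, ori, c("f1", "f2"))
  ex <- as.data.frame(excludedContigs(planC))
  expect_identical(ex$contig, "f1")
  expect_identical(ex$reason, "lg_conflict")
  expect_false("f1" %in% as.data.frame(anchoredContigs(planC))$contig)
})

test_that("noise-free anchoring recovers truth order and orientation exactly", {
  fx <- fixture("clean", cleanAnchorFixture)
  plan <- fx$res$plan
  a <- as.data.frame(anchoredContigs(plan))
  tr <- as.data.frame(contigTruth(fx$cs))
  for (ch in unique(a$chromosome)) {
    sub <- a[a$chromosome == ch, ]
    truthStart <- tr$start[match(sub$contig, tr$contig)]
    tau <- cor(sub$rank, truthStart, method = "kendall")
    expect_equal(tau, 1)
    expect_true(all(sub$orientation == "+"))
  }
  ## every clean contig was anchored
  expect_length(chr0Contigs(plan), 0L)
  expect_identical(nrow(excludedContigs(plan)), 0L)
})

test_that("planted chimeras are found, split at the junction, and splitting is idempotent", {
  fx <- fixture("chim", chimeraFixture)
  pf <- placeMarkers(fx$female, contigSeqs(fx$cs))
  pm <- placeMarkers(fx$male, contigSeqs(fx$cs))
  pr <- as.data.frame(detectChimeras(list(pf, pm)))
  tr <- as.data.frame(contigTruth(fx$cs))
  chim <- names(which(table(tr$contig) == 2L))
  expect_setequal(pr$contig, chim)
  for (ctg in chim) {
    seg <- tr[tr$contig == ctg, ]
    junction <- seg$contig_end[1]  # last base of segment 1
    row <- pr[pr$contig == ctg, ]
    expect_identical(nrow(row), 1L)
    expect_lte(row$break_left, junction + 70L)
    expect_gte(row$break_right, junction - 70L)
    cut <- (row$break_left + row$break_right) %/% 2L
    expect_gte(cut, row$break_left)
    expect_lte(cut, row$break_right)
  }
  ## idempotence: no further proposals after splitting
  split <- splitContigs(contigSeqs(fx$cs), pr)
  pf2 <- placeMarkers(fx$female, split)
  pm2 <- placeMarkers(fx$male, split)
  expect_identical(nrow(detectChimeras(list(pf2, pm2))), 0L)
})

test_that("the plan partitions the contig set", {
  fx <- fixture("chim", chimeraFixture)
  res <- anchorAssembly(contigSeqs(fx$cs), fx$female, fx$male)
  a <- as.data.frame(anchoredContigs(res$plan))
  ex <- as.data.frame(excludedContigs(res$plan))
  all3 <- c(a$contig, chr0Contigs(res$plan), ex$contig)
  expect_setequal(all3, names(res$contigs))
  expect_identical(anyDuplicated(all3), 0L)
})
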