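test_that("default geometry realizes the modeled locus exactly", {
  m <- defaultLocusModel()
  expect_s4_class(m, "LocusModel")
  expect_identical(unitLength(m), 7483L)

  chrA <- parentSeqs(m)[["chrA"]]
  u5 <- m@unitStart; u3 <- m@unitEnd

  ## junction-side 8 bp motif ends exactly at the 3' boundary and recurs
  ## 21 bp downstream of the 5' boundary; 7 bp motif flanks at -14 / +15
  expect_identical(as.character(Biostrings::subseq(chrA, u3 - 7L, u3)),
                   "GGAAAGGG")
  expect_identical(as.character(Biostrings::subseq(chrA, u5 + 22L, u5 + 29L)),
                   "GGAAAGGG")
  expect_identical(as.character(Biostrings::subseq(chrA, u5 - 13L, u5 - 7L)),
                   "TATGATG")
  expect_identical(as.character(Biostrings::subseq(chrA, u3 + 16L, u3 + 22L)),
                   "TATGATG")

  ## single-cutter: exactly one site inside the unit, outside cutter none
  hind <- m@enzymeSites[["hindIII-like"]]$sites
  expect_identical(sum(hind >= u5 & hind < u3), 1L)
  sac <- m@enzymeSites[["sacII-like"]]$sites
  expect_identical(sum(sac >= u5 & sac < u3), 0L)
  expect_true(any(sac < u5) && any(sac >= u3))
})

test_that("planted distances reproduce the diagnostic fragment and product sizes", {
  m <- defaultLocusModel()
  hind <- sort(cutSites(m, "hindIII-like"))
  sac <- sort(cutSites(m, "sacII-like"))
  u5 <- m@unitStart; u3 <- m@unitEnd
  hIn <- hind[hind >= u5 & hind < u3]
  hRight <- min(hind[hind >= u3])
  expect_identical(hRight - hIn, 4300L)          # boundary fragment
  expect_identical(diff(sac), 11000L)            # outside-cutter fragment

  p <- m@primerSites
  span <- function(set) {
    s <- p[p$set == set, ]
    s$end[s$role == "rev"] - s$start[s$role == "fwd"]
  }
  ## P1 is outward-facing: its junction product is (unit end - fwd start) +
  ## (rev end - unit start), the two arms that meet across the junction
  p1 <- p[p$set == "P1", ]
  expect_identical((u3 - p1$start[p1$role == "fwd"]) +
                     (p1$end[p1$role == "rev"] - u5), 1700L)
  expect_identical(span("P2"), 1100L)
  expect_identical(span("P3"), 9400L)
})

test_that("background is free of spurious sites and motifs near the locus", {
  m <- defaultLocusModel()
  chrA <- parentSeqs(m)[["chrA"]]
  for (enz in names(m@enzymeSites)) {
    e <- m@enzymeSites[[enz]]
    found <- Biostrings::start(Biostrings::matchPattern(e$recognition,
                                                        chrA)) - 1L
    expect_setequal(found, e$sites)
  }
  ## primers occur exactly once
  for (set in unique(m@primerSites$set)) {
    pr <- primerPair(m, set)
    expect_identical(
      length(Biostrings::matchPattern(pr[["fwd"]], chrA)), 1L)
  }
  ## no off-plan motif copies within 100 bp of the unit boundaries
  mh <- m@microhomologyPlan
  for (i in seq_len(nrow(mh))) {
    occ <- Biostrings::start(Biostrings::matchPattern(mh$motif[i], chrA)) - 1L
    near <- occ[abs(occ - m@unitStart) <= 100L | abs(occ - m@unitEnd) <= 100L]
    expect_setequal(near, c(mh$startA[i], mh$startB[i]))
  }
})

test_that("inconsistent geometry requests raise named conflicts", {
  expect_error(buildLocusModel(unitLength = 3000, internalFragment = 7400),
               "internal single-cutter fragment")
  expect_error(buildLocusModel(unitLength = 1000), "at least 2000")
  expect_error(smallModel()@geometry, NA)  # the scaled geometry is valid
  expect_error(buildLocusModel(unitLength = 3000, chromLength = 40000,
                               boundaryFragment = 1000, hindToEnd = 1200,
                               auxChromLength = 0, rdnaChromLength = 0),
               "boundaryFragment")
  expect_error(buildLocusModel(unitLength = 3000, chromLength = 40000,
                               hindToEnd = 1200, boundaryFragment = 2000,
                               sacLeftGap = 800, outsideFragment = 5000,
                               p3Product = 3100,
                               auxChromLength = 0, rdnaChromLength = 0),
               "p3Product")
})

test_that("model construction is seed-deterministic", {
  a <- buildLocusModel(unitLength = 3000, chromLength = 40000,
                       hindToEnd = 1200, boundaryFragment = 2000,
                       sacLeftGap = 800, outsideFragment = 5000,
                       p3Product = 4500, auxChromLength = 0,
                       rdnaChromLength = 0, seed = 42)
  b <- buildLocusModel(unitLength = 3000, chromLength = 40000,
                       hindToEnd = 1200, boundaryFragment = 2000,
                       sacLeftGap = 800, outsideFragment = 5000,
                       p3Product = 4500, auxChromLength = 0,
                       rdnaChromLength = 0, seed = 42)
  expect_identical(as.character(parentSeqs(a)), as.character(parentSeqs(b)))
  c <- buildLocusModel(unitLength = 3000, chromLength = 40000,
                       hindToEnd = 1200, boundaryFragment = 2000,
                       sacLeftGap = 800, outsideFragment = 5000,
                       p3Product = 4500, auxChromLength = 0,
                       rdnaChromLength = 0, seed = 43)
  expect_false(identical(as.character(parentSeqs(a)[["chrA"]]),
                         as.character(parentSeqs(c)[["chrA"]])))
})
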