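test_that("clip collection respects the minimum clip length", {
  a <- data.frame(
    qname = c("a", "b", "c"), sample = "s", chrom = "chr1",
    pos = c(100L, 200L, 300L), strand = "+",
    cigar = c("85M5S", "80M10S", "12S78M"),
    seq = c(paste0(strrep("A", 85), "CCCCC"),
            paste0(strrep("A", 80), strrep("G", 10)),
            paste0(strrep("T", 12), strrep("A", 78))),
    stringsAsFactors = FALSE)
  clips <- collectClipped(a, minClip = 10)
  expect_identical(clips$qname, c("c", "b"))   # 5 bp clip excluded
  expect_identical(clips$coord[clips$qname == "b"], 280L)
  expect_identical(clips$side[clips$qname == "b"], "right")
  expect_identical(clips$seq[clips$qname == "b"], strrep("G", 10))
  expect_identical(clips$coord[clips$qname == "c"], 300L)
  expect_identical(clips$seq[clips$qname == "c"], strrep("T", 12))
})

test_that("breakpoint clustering is single linkage with a support floor", {
  mkClips <- function(coords) data.frame(
    qname = paste0("r", seq_along(coords)), chrom = "chr1", coord = coords,
    side = "right", clipLen = 20L, seq = strrep("A", 20),
    stringsAsFactors = FALSE)
  c1 <- clusterBreakpoints(mkClips(rep(150L, 20)), tol = 5, minSupport = 3)
  expect_identical(nrow(c1), 1L)
  expect_identical(c1$support, 20L)
  expect_identical(c1$coord, 150L)
  c2 <- clusterBreakpoints(mkClips(c(100L, 101L, 103L)), tol = 5,
                           minSupport = 3)
  expect_identical(nrow(c2), 1L)
  c3 <- clusterBreakpoints(mkClips(c(100L, 100L, 100L, 200L, 200L, 200L)),
                           tol = 5, minSupport = 3)
  expect_identical(nrow(c3), 2L)
  ## below the support floor nothing is reported
  expect_identical(nrow(clusterBreakpoints(mkClips(c(100L, 101L)))), 0L)
})

test_that("episome junctions are reconstructed exactly", {
  m <- smallModel()
  b <- applyScenario(m, scenarioPreset("episome"))
  sim <- simulateReads(b, depth = 44, seed = 7)
  clusters <- clusterBreakpoints(collectClipped(sim$alignments))
  res <- crossMatch(clusters, m)
  expect_length(res$calls, 1)
  expect_identical(nrow(res$unresolved), 0L)
  call <- res$calls[[1]]
  expect_identical(call@leftBp, m@unitStart)
  expect_identical(call@rightBp, m@unitEnd)
  expect_identical(call@ambiguitySpan, 0L)
  expect_identical(inferUnitLength(call), unitLength(m))
  expect_identical(call@topologyHint, "circular-or-tandem")
  ## junction consensus reads through: 3'-flank then 5'-flank
  chrA <- parentSeqs(m)[["chrA"]]
  expect_identical(call@consensus, paste0(
    as.character(Biostrings::subseq(chrA, m@unitEnd - 39L, m@unitEnd)),
    as.character(Biostrings::subseq(chrA, m@unitStart + 1L,
                                    m@unitStart + 40L))))

  ## a tandem array produces the identical junction (cannot be told apart)
  bt <- applyScenario(m, ScenarioSpec(c(9L, 1L)))
  simT <- simulateReads(bt, depth = 44, seed = 8)
  resT <- crossMatch(clusterBreakpoints(collectClipped(simT$alignments)), m)
  expect_length(resT$calls, 1)
  expect_identical(resT$calls[[1]]@leftBp, call@leftBp)
  expect_identical(resT$calls[[1]]@rightBp, call@rightBp)

  ## symmetric: the call does not depend on cluster order
  resR <- crossMatch(clusters[rev(seq_len(nrow(clusters))), ], m)
  expect_identical(resR$calls[[1]]@leftBp, call@leftBp)
  expect_identical(resR$calls[[1]]@rightBp, call@rightBp)
})

test_that("non-matching clipped tails stay unresolved", {
  m <- smallModel()
  clusters <- data.frame(
    chrom = "chrA", coord = c(5000L, 9000L), side = c("left", "right"),
    support = 10L, meanClipLen = 25,
    consensus = c(strrep("ACGT", 7), strrep("TTGA", 7)),
    stringsAsFactors = FALSE)
  res <- crossMatch(clusters, m)
  expect_length(res$calls, 0)
  expect_identical(nrow(res$unresolved), 2L)
})

test_that("breakpoints shift leftmost within straddling homology", {
  set.seed(99)
  ref <- strsplit(randomDnaString(400), "")[[1]]
  l <- 100L; r <- 250L
  ## plant a 4 bp homology immediately left of both breakpoints (0-based
  ## [l-4,l) and [r-4,r)), and break any extension beyond it
  hom <- c("G", "G", "C", "C")
  ref[(l - 3):l] <- hom; ref[(r - 3):r] <- hom     # 1-based indexing
  ref[l - 4] <- "A"; ref[r - 4] <- "T"             # no 5th leftward match
  ref[l + 1] <- "A"; ref[r + 1] <- "T"             # no rightward slide
  ref <- paste(ref, collapse = "")
  refSet <- Biostrings::DNAStringSet(c(chrZ = ref))
  clusters <- data.frame(
    chrom = "chrZ", coord = c(l, r), side = c("left", "right"),
    support = 5L, meanClipLen = 20,
    consensus = c(substr(ref, r - 19, r),    # tail ending at the 3' bp
                  substr(ref, l + 1, l + 20)), # tail starting at the 5' bp
    stringsAsFactors = FALSE)
  res <- crossMatch(clusters, refSet)
  expect_length(res$calls, 1)
  call <- res$calls[[1]]
  expect_identical(call@leftBp, l - 4L)
  expect_identical(call@rightBp, r - 4L)
  expect_identical(call@ambiguitySpan, 4L)
  expect_identical(unitLength(call), r - l)
})

test_that("degenerate coinciding breakpoints are rejected", {
  expect_error(new("JunctionCall", chrom = "chr1", leftBp = 10L,
                   rightBp = 10L, ambiguitySpan = 0L, consensus = "",
                   supportLeft = 3L, supportRight = 3L,
                   microhomology = data.frame(),
                   topologyHint = "circular-or-tandem"),
               "positive")
})

test_that("parent scenarios produce no junction calls across seeds", {
  m <- smallModel()
  b <- applyScenario(m, scenarioPreset("parent"))
  for (seed in 1:20) {
    sim <- simulateReads(b, depth = 44, seed = 3000 + seed)
    clusters <- clusterBreakpoints(collectClipped(sim$alignments),
                                   minSupport = 3)
    expect_identical(nrow(clusters), 0L)
  }
})
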