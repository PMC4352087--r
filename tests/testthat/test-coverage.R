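## hand-built alignment rows for unit cases
.aln <- function(chrom, pos, cigar, seq = strrep("A", 90)) {
  data.frame(qname = "r", sample = "s", chrom = chrom, pos = pos,
             strand = "+", cigar = cigar, seq = seq,
             stringsAsFactors = FALSE)
}

test_that("window depth is per-base counting with true-width normalization", {
  lens <- c(chr1 = 1200L)
  ## one 90 bp read inside one 500 bp window
  t1 <- computeDepthTrack(.aln("chr1", 100L, "90M"), lens, window = 500)
  expect_equal(trackWindows(t1)$depth, c(90 / 500, 0, 0))
  ## read spanning two windows: contributions split, total conserved
  t2 <- computeDepthTrack(.aln("chr1", 460L, "90M"), lens, window = 500)
  w <- trackWindows(t2)
  expect_equal(w$depth[1], 40 / 500)
  expect_equal(w$depth[2], 50 / 500)
  expect_equal(sum(w$depth * (w$end - w$start)), 90)
  ## soft-clipped bases do not count; partial terminal window true width
  t3 <- computeDepthTrack(.aln("chr1", 1000L, "20S70M"), lens, window = 500)
  w3 <- trackWindows(t3)
  expect_equal(w3$end[3] - w3$start[3], 200)
  expect_equal(w3$depth[3], 70 / 200)
  expect_warning(computeDepthTrack(.aln("chr1", 1, "90M")[0, ], lens),
                 "empty alignment")
})

test_that("identical tracks give an all-zero ratio and grids must match", {
  lens <- c(chr1 = 5000L)
  a <- computeDepthTrack(.aln("chr1", c(10L, 600L, 2100L), "90M"), lens)
  lr <- log2Ratio(a, a, minRefDepth = 0)
  expect_true(all(abs(trackWindows(lr)$log2) < 1e-12))
  b <- computeDepthTrack(.aln("chr1", 10L, "90M"), lens, window = 250)
  expect_error(log2Ratio(a, b), "grid")
})

test_that("the ratio is scale-invariant and antisymmetric", {
  m <- smallModel()
  b9 <- applyScenario(m, ScenarioSpec(c(9L, 9L)))
  b0 <- applyScenario(m, scenarioPreset("parent"))
  ds <- computeDepthTrack(simulateReads(b9, depth = 20, seed = 3)$alignments, m)
  dr <- computeDepthTrack(simulateReads(b0, depth = 20, seed = 4)$alignments, m)
  lr <- log2Ratio(ds, dr)
  ## multiplying all sample depths by a constant changes nothing
  ds3 <- ds
  ds3@windows$depth <- ds3@windows$depth * 3
  ds3@totalBases <- ds3@totalBases * 3
  lr3 <- log2Ratio(ds3, dr)
  expect_lt(max(abs(trackWindows(lr3)$log2 - trackWindows(lr)$log2),
                na.rm = TRUE), 1e-6)
  ## antisymmetry on unmasked windows (exact up to pseudocount effects)
  bwd <- log2Ratio(dr, ds, minRefDepth = 0)
  fwd <- log2Ratio(ds, dr, minRefDepth = 0)
  expect_lt(max(abs(trackWindows(fwd)$log2 + trackWindows(bwd)$log2)), 5e-3)
})

test_that("smoothing matches a direct convolution oracle", {
  mkTrack <- function(vals, masked = rep(FALSE, length(vals))) {
    n <- length(vals)
    new("LogRatioTrack",
        windows = data.frame(chrom = "chr1", start = (0:(n - 1)) * 500,
                             end = (1:n) * 500, log2 = vals,
                             smoothed = NA_real_, masked = masked),
        windowSize = 500L, span = NA_real_, pseudocount = 0.1)
  }
  ## constant track unchanged
  sm <- smoothTrack(mkTrack(rep(0.7, 50)), span = 10000)
  expect_equal(trackWindows(sm)$smoothed, rep(0.7, 50))
  ## single spike of height h, span 20 windows: plateau of h/20
  vals <- rep(0, 60); vals[30] <- 2.4
  sm <- smoothTrack(mkTrack(vals), span = 10000)
  plateau <- trackWindows(sm)$smoothed[25:35]
  expect_true(all(abs(plateau - 2.4 / 20) < 1e-12))
  ## step function: smoothed transition width equals the span
  step <- c(rep(0, 40), rep(1, 40))
  smd <- trackWindows(smoothTrack(mkTrack(step), span = 10000))$smoothed
  expect_equal(sum(smd > 1e-9 & smd < 1 - 1e-9), 19)  # k - 1 windows
  ## random track against a double-loop convolution oracle (truncated edges)
  set.seed(1)
  vals <- rnorm(45)
  masked <- rep(FALSE, 45); masked[c(7, 20, 21)] <- TRUE
  smd <- trackWindows(smoothTrack(mkTrack(vals, masked), span = 10000))$smoothed
  k <- 20; left <- (k - 1) %/% 2; right <- k - 1 - left
  for (i in seq_along(vals)) {
    win <- max(1, i - left):min(45, i + right)
    win <- win[!masked[win]]
    expect_equal(smd[i], mean(vals[win]))
  }
  expect_error(smoothTrack(mkTrack(rep(0, 5)), span = 100), "window size")
})

test_that("segment calling finds threshold runs and estimates folds", {
  mkTrack <- function(vals) {
    n <- length(vals)
    t <- new("LogRatioTrack",
             windows = data.frame(chrom = "chr1", start = (0:(n - 1)) * 500,
                                  end = (1:n) * 500, log2 = vals,
                                  smoothed = NA_real_,
                                  masked = rep(FALSE, n)),
             windowSize = 500L, span = NA_real_, pseudocount = 0.1)
    smoothTrack(t, span = 1000)   # k = 2: nearly raw
  }
  expect_length(callSegments(mkTrack(rep(0, 50))), 0)
  expect_error(callSegments(new("LogRatioTrack",
                                windows = data.frame(), windowSize = 500L,
                                span = NA_real_, pseudocount = 0.1)),
               "smooth")
  vals <- rep(0, 60); vals[20:29] <- 1; vals[45:54] <- -1
  segs <- as.data.frame(callSegments(mkTrack(vals)))
  expect_identical(nrow(segs), 2L)
  expect_setequal(segs$direction, c("gain", "loss"))
  expect_equal(segs$fold[segs$direction == "gain"], 2, tolerance = 0.01)
  expect_equal(segs$fold[segs$direction == "loss"], 0.5, tolerance = 0.01)
  ## runs shorter than minWindows are not called
  vals <- rep(0, 60); vals[20:22] <- 1
  expect_length(callSegments(mkTrack(vals), minWindows = 5), 0)
})

test_that("a deletion allele reads as a ~0.5-fold loss", {
  m <- smallModel()
  bd <- applyScenario(m, scenarioPreset("deletion"))
  b0 <- applyScenario(m, scenarioPreset("parent"))
  ds <- computeDepthTrack(simulateReads(bd, depth = 44, seed = 21)$alignments, m)
  dr <- computeDepthTrack(simulateReads(b0, depth = 44, seed = 22)$alignments, m)
  ## smoothing span matched to the scaled 3 kb unit: a 2-fold event smeared
  ## over a span much wider than itself would fall below the threshold
  lr <- smoothTrack(log2Ratio(ds, dr), span = 3000)
  segs <- as.data.frame(callSegments(lr))
  loss <- segs[segs$seqnames == "chrA" & segs$direction == "loss", ]
  expect_identical(nrow(loss), 1L)
  expect_equal(loss$fold, 0.5, tolerance = 0.1)
})

test_that("planted folds are recovered within 10% across seeds", {
  m <- smallModel()
  b0 <- applyScenario(m, scenarioPreset("parent"))
  folds <- list(`1.5` = numeric(), `2` = numeric(), `9` = numeric())
  for (seed in 1:20) {
    bT <- applyScenario(m, ScenarioSpec(aneuploidy = c(chrT = 3)))
    bG <- applyScenario(m, ScenarioSpec(c(2L, 2L)))
    b9 <- applyScenario(m, ScenarioSpec(c(9L, 9L)))
    dr <- computeDepthTrack(
      simulateReads(b0, depth = 44, seed = 1000 + seed)$alignments, m)
    for (k in c("1.5", "2", "9")) {
      b <- switch(k, `1.5` = bT, `2` = bG, `9` = b9)
      ds <- computeDepthTrack(
        simulateReads(b, depth = 44, seed = 2000 + seed)$alignments, m)
      lr <- smoothTrack(log2Ratio(ds, dr), span = 3000)
      f <- if (k == "1.5") regionRatio(lr, "chrT") else {
        segs <- as.data.frame(callSegments(lr))
        segs$fold[segs$seqnames == "chrA" & segs$direction == "gain"][1]
      }
      folds[[k]] <- c(folds[[k]], f)
    }
  }
  for (k in c(1.5, 2, 9))
    expect_lt(abs(median(folds[[as.character(k)]]) - k) / k, 0.10)
})
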