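## Shared fixtures, built in code. The scaled-down geometry keeps the full
## structure of the default locus (single intra-unit cutter, outside cutter,
## three primer sets, planted microhomologies) on a 3 kb unit so that
## simulation-heavy tests run quickly; the acceptance tests use the default
## 7,483 bp geometry.

.fixtures <- new.env(parent = emptyenv())

smallModel <- function(seed = 1) {
  key <- paste0("small", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- buildLocusModel(
      unitLength = 3000, chromLength = 40000,
      hindToEnd = 1200, boundaryFragment = 2000, hindLeftGap = 2000,
      sacLeftGap = 800, outsideFragment = 5000,
      p3Product = 4500, p3LeftGap = 1000,
      auxChromLength = 20000, rdnaChromLength = 20000,
      rdnaStart = 5000, rdnaLength = 5000, seed = seed)
  .fixtures[[key]]
}

## default-geometry model, locus chromosome only (fast enough to share)
defaultLocusModel <- function() {
  if (is.null(.fixtures$default))
    .fixtures$default <- buildLocusModel(auxChromLength = 0,
                                         rdnaChromLength = 0, seed = 1)
  .fixtures$default
}

## the full study-scale two-sample CNV computation shared by the
## depth-ratio acceptance checks (parent vs 9-copies-both-alleles with
## trisomy and halved rDNA proxy, 44x, 90 bp reads)
fullScaleCnv <- function() {
  if (is.null(.fixtures$cnv)) {
    model <- buildLocusModel(seed = 1)
    bP <- applyScenario(model, scenarioPreset("parent"))
    bE <- applyScenario(model, scenarioPreset("tandem_both"))
    sP <- simulateReads(bP, depth = 44, seed = 101, sample = "parent")
    sE <- simulateReads(bE, depth = 44, seed = 102, sample = "evolved")
    dP <- computeDepthTrack(sP$alignments, model)
    dE <- computeDepthTrack(sE$alignments, model)
    ratio <- smoothTrack(log2Ratio(dE, dP))
    segs <- as.data.frame(callSegments(ratio))
    .fixtures$cnv <- list(model = model, ratio = ratio, segments = segs)
  }
  .fixtures$cnv
}

## independent brute-force oracle for microhomology search: enumerate every
## substring pair of the two windows by direct string comparison, keep
## diagonal-maximal pairs, then drop hits contained in a longer hit at both
## placements. Returns (startA, startB, len), 0-based.
bruteForceCommon <- function(A, B, minLen = 5L) {
  nA <- nchar(A); nB <- nchar(B)
  hits <- list()
  for (len in minLen:min(nA, nB)) {
    subsA <- substring(A, 1:(nA - len + 1L), len:nA)
    subsB <- substring(B, 1:(nB - len + 1L), len:nB)
    for (i in seq_along(subsA)) {
      js <- which(subsB == subsA[i])
      for (j in js) {
        extendable <-
          (i > 1L && j > 1L &&
             substr(A, i - 1L, i - 1L) == substr(B, j - 1L, j - 1L)) ||
          (i + len - 1L < nA && j + len - 1L < nB &&
             substr(A, i + len, i + len) == substr(B, j + len, j + len))
        if (!extendable)
          hits[[length(hits) + 1L]] <- c(i - 1L, j - 1L, len)
      }
    }
  }
  if (!length(hits))
    return(data.frame(startA = integer(), startB = integer(),
                      len = integer()))
  h <- as.data.frame(do.call(rbind, hits))
  names(h) <- c("startA", "startB", "len")
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    contained <- h$len > h$len[i] &
      h$startA <= h$startA[i] & h$startA + h$len >= h$startA[i] + h$len[i] &
      h$startB <= h$startB[i] & h$startB + h$len >= h$startB[i] + h$len[i]
    if (any(contained)) keep[i] <- FALSE
  }
  h <- h[keep, , drop = FALSE]
  h[order(h$startA, h$startB, h$len), , drop = FALSE]
}

randomDnaString <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## run the template-level assays for a named preset and classify
classifyPreset <- function(model, preset) {
  build <- applyScenario(model, scenarioPreset(preset))
  classifyTopology(gatherAssayEvidence(build))@verdict
}
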