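#' @include insilico.R
NULL

#' Run the diagnostic assays in silico on a sample genome
#'
#' Emulates, on the molecules of a \linkS4class{GenomeBuild}, the wet-lab
#' assays used to discriminate locus topologies: PCR with the outward P1
#' pair (positive only across a circular/tandem junction), the locus-anchor
#' P2 pair, the locus-spanning P3 pair under short and long extension, a
#' single intra-unit cutter digest and an outside-cutter digest, both
#' probed and copy-weighted across all molecules carrying locus sequence.
#'
#' @param build a \linkS4class{GenomeBuild}.
#' @param shortCap,longCap extension caps in bp (see [extensionCap()]).
#' @return named list of evidence consumed by [classifyTopology()]:
#'   logical \code{p1}, \code{p2}, \code{p3Short}, \code{p3Long}; product
#'   size lists; combined band tables \code{singleCutter} and
#'   \code{outsideCutter}; \code{has11kb} / \code{hasHighMW} flags relative
#'   to the model's expected single-copy fragment; \code{intensityRatio};
#'   \code{uncutCircle} flag.
#' @export
gatherAssayEvidence <- function(build, shortCap = extensionCap("short"),
                                longCap = extensionCap("long")) {
  model <- build@model
  locusMols <- unique(build@coordMap$molecule[
    build@coordMap$chrom == model@unitChrom])
  idx <- which(names(build@seqs) %in% locusMols)

  runPcr <- function(set, cap) {
    pr <- primerPair(model, set)
    lapply(idx, function(i)
      insilicoPcr(build@seqs[[i]], pr[["fwd"]], pr[["rev"]], cap,
                  circular = build@circular[i], primerSet = set,
                  templateId = names(build@seqs)[i]))
  }
  sizes <- function(preds)
    sort(unique(unlist(lapply(preds, function(p) p@products$size))))

  p1 <- runPcr("P1", shortCap)
  p2 <- runPcr("P2", shortCap)
  p3s <- runPcr("P3", shortCap)
  p3l <- runPcr("P3", longCap)

  chrA <- model@parentSeqs[[model@unitChrom]]
  probeSeq <- setNames(
    vapply(seq_len(nrow(model@probes)), function(i)
      .as_chr0(chrA, model@probes$start[i], model@probes$end[i]), ""),
    model@probes$name)
  runDigest <- function(enzyme, probes)
    lapply(idx, function(i)
      insilicoDigest(build@seqs[[i]], enzyme, probes = probes,
                     model = model, circular = build@circular[i],
                     copyWeight = build@weights[i],
                     templateId = names(build@seqs)[i]))
  ## the single-cutter blot is probed inside the unit only (the probe lies in
  ## the XylA-like feature); the outside-cutter blot uses both probes
  dHind <- runDigest("hindIII-like", probeSeq["inside"])
  dSac <- runDigest("sacII-like", probeSeq)
  singleCutter <- combineBands(dHind)
  outsideCutter <- combineBands(dSac)

  expected11 <- model@geometry$outsideFragment
  highMWfloor <- expected11 + unitLength(model) %/% 2L
  has11kb <- any(outsideCutter$sizeKb == .displayKb(expected11))
  hasHighMW <- any(outsideCutter$sizeKb > .displayKb(highMWfloor))

  ir <- if (nrow(singleCutter) >= 2L) intensityRatio(singleCutter)
        else NA_real_
  list(
    p1 = length(sizes(p1)) > 0L, p1Sizes = sizes(p1),
    p2 = length(sizes(p2)) > 0L, p2Sizes = sizes(p2),
    p3Short = length(sizes(p3s)) > 0L, p3ShortSizes = sizes(p3s),
    p3Long = length(sizes(p3l)) > 0L, p3LongSizes = sizes(p3l),
    singleCutter = singleCutter, outsideCutter = outsideCutter,
    has11kb = has11kb, hasHighMW = hasHighMW,
    intensityRatio = ir,
    uncutCircle = any(vapply(dSac, function(p) p@uncutCircle, TRUE)),
    expectedSingleCopyKb = .displayKb(expected11),
    expectedUnitKb = .displayKb(unitLength(model)),
    expectedBoundaryKb = .displayKb(model@geometry$boundaryFragment))
}

#' Classify the locus topology from assay evidence
#'
#' Applies the decision logic of the original inference: the P1 junction
#' PCR distinguishes "some circular or tandem structure exists" from none;
#' the outside-cutter Southern separates chromosomal tandem arrays (a
#' high-molecular-weight band that grows with copy number) from intact
#' single-copy alleles (the expected single-copy fragment); the P3
#' short-extension product reports a deleted allele. Evidence combinations:
#'
#' \tabular{ll}{
#'   P1-, single-copy band only \tab \code{single_copy} \cr
#'   P1-, P3-short product \tab \code{deleted} \cr
#'   P1+, single-copy band only \tab \code{episomal_circle} \cr
#'   P1+, single-copy band + P3-short \tab \code{circle_plus_single_copy} \cr
#'   P1+, single-copy band + high-MW \tab \code{tandem_one_allele} \cr
#'   P1+, high-MW only \tab \code{tandem_both_alleles} \cr
#'   contradictory evidence \tab \code{inconsistent} (with the clash list)
#' }
#'
#' Copies per amplified allele are estimated two ways when available: from
#' the coverage fold over the unit (fold = n for both-allele arrays,
#' (n+1)/2 for one amplified allele) and from the single-cutter intensity
#' ratio (n = ratio + 1 for both-allele arrays, n = 2*ratio + 1 for one),
#' with an agreement flag.
#'
#' @param evidence list from [gatherAssayEvidence()] (or hand-built with
#'   the same fields; \code{p1} and at least one digest flag are required).
#' @param coverageFold CNV fold estimate over the unit (optional, NA to
#'   omit the coverage-based copy estimate).
#' @return a \linkS4class{TopologyCall}.
#' @export
classifyTopology <- function(evidence, coverageFold = NA_real_) {
  need <- c("p1", "has11kb", "hasHighMW")
  if (!all(need %in% names(evidence)) || is.na(evidence$p1))
    stop("classification needs at least the P1 result and one digest")
  p1 <- isTRUE(evidence$p1)
  has11 <- isTRUE(evidence$has11kb)
  highMW <- isTRUE(evidence$hasHighMW)
  p3s <- isTRUE(evidence$p3Short)
  ir <- if (is.null(evidence$intensityRatio)) NA_real_
        else evidence$intensityRatio
  nBands <- if (is.null(evidence$singleCutter)) NA_integer_
            else nrow(evidence$singleCutter)

  notes <- character()
  verdict <- NULL
  if (!p1) {
    clash <- character()
    if (highMW)
      clash <- c(clash, "high-MW outside-cutter band without a P1 product")
    if (!is.na(nBands) && nBands >= 2L)
      clash <- c(clash, "two single-cutter probe bands without a P1 product")
    if (length(clash)) {
      verdict <- "inconsistent"; notes <- clash
    } else if (p3s) {
      verdict <- "deleted"
    } else if (has11) {
      verdict <- "single_copy"
    } else {
      verdict <- "inconsistent"
      notes <- "no probe-bearing locus evidence at all"
    }
  } else {
    if (highMW && has11) verdict <- "tandem_one_allele"
    else if (highMW) verdict <- "tandem_both_alleles"
    else if (has11 && p3s) verdict <- "circle_plus_single_copy"
    else if (has11) verdict <- "episomal_circle"
    else {
      verdict <- "episomal_circle"
      notes <- "no intact chromosomal allele detected alongside the circle"
    }
  }

  covCopies <- intCopies <- NA_real_
  if (verdict == "tandem_both_alleles") {
    if (!is.na(coverageFold)) covCopies <- round(coverageFold)
    if (!is.na(ir)) intCopies <- ir + 1
  } else if (verdict == "tandem_one_allele") {
    if (!is.na(coverageFold)) covCopies <- round(2 * coverageFold - 1)
    if (!is.na(ir)) intCopies <- 2 * ir + 1
  }
  agreement <- !is.na(covCopies) && !is.na(intCopies) &&
    covCopies == round(intCopies)

  new("TopologyCall", verdict = verdict, evidence = evidence,
      copiesPerAllele = covCopies, copiesFromIntensity = intCopies,
      agreement = agreement, notes = notes)
}
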