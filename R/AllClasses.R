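#' @include utils.R
NULL

#' LocusModel: an annotated amplifiable cassette locus on a toy parent genome
#'
#' A \code{LocusModel} holds the parent reference sequences together with the
#' geometry of the amplifiable unit: its interval, internal features
#' (REV1-like, tRNA-like, ARS-like and XylA-like placeholders), the planted
#' microhomology motifs at the unit boundaries, restriction-enzyme cut sites,
#' primer annealing sites, Southern probes, and a tandem-repeat proxy region
#' whose copy number can be scaled (the rDNA stand-in).
#'
#' All coordinates in the slots are 0-based, half-open. Accessors that return
#' \link[GenomicRanges]{GRanges} convert to the usual 1-based closed
#' convention.
#'
#' @slot parentSeqs \link[Biostrings]{DNAStringSet} of parent chromosomes.
#' @slot unitChrom chromosome carrying the amplifiable unit.
#' @slot unitStart,unitEnd 0-based half-open unit interval; the unit length is
#'   \code{unitEnd - unitStart}.
#' @slot features data.frame (name, chrom, start, end) of feature placeholders.
#' @slot microhomologyPlan data.frame (motif, startA, startB, offsetA, offsetB)
#'   of planted boundary microhomologies; offsets are motif starts relative to
#'   the 5' and 3' unit boundaries.
#' @slot enzymeSites named list; each element has \code{recognition},
#'   \code{cutOffset} and integer \code{sites} (recognition-start positions).
#' @slot primerSites data.frame (set, role, start, end, strand); primer
#'   sequences are read off the parent reference (reverse primers are the
#'   reverse complement of their plus-strand site).
#' @slot probes data.frame (name, chrom, start, end) of Southern probes.
#' @slot rdnaChrom,rdnaStart,rdnaEnd the tandem-repeat proxy region.
#' @slot geometry named list of the constructor parameters actually used.
#' @slot seed integer seed that produced the background sequence.
#'
#' @seealso [buildLocusModel()]
#' @export
setClass("LocusModel",
  representation(
    parentSeqs = "DNAStringSet",
    unitChrom = "character",
    unitStart = "integer",
    unitEnd = "integer",
    features = "data.frame",
    microhomologyPlan = "data.frame",
    enzymeSites = "list",
    primerSites = "data.frame",
    probes = "data.frame",
    rdnaChrom = "character",
    rdnaStart = "integer",
    rdnaEnd = "integer",
    geometry = "list",
    seed = "integer"
  )
)

setValidity("LocusModel", function(object) {
  msg <- character()
  chrA <- object@parentSeqs[[object@unitChrom]]
  u5 <- object@unitStart; u3 <- object@unitEnd
  if (u3 <= u5) msg <- c(msg, "unit interval is empty")
  ## single intra-unit cutter / outside cutter geometry
  hind <- object@enzymeSites[["hindIII-like"]]
  sac <- object@enzymeSites[["sacII-like"]]
  inUnit <- function(p) p >= u5 & p < u3
  if (sum(inUnit(hind$sites)) != 1L)
    msg <- c(msg, "hindIII-like must cut exactly once inside the unit")
  if (any(inUnit(sac$sites)))
    msg <- c(msg, "sacII-like must not cut inside the unit")
  if (!any(sac$sites < u5) || !any(sac$sites >= u3))
    msg <- c(msg, "sacII-like needs at least one site on each flank")
  ## planted microhomologies at their stated placements
  mh <- object@microhomologyPlan
  for (i in seq_len(nrow(mh))) {
    m <- mh$motif[i]; w <- nchar(m)
    if (.as_chr0(chrA, mh$startA[i], mh$startA[i] + w) != m ||
        .as_chr0(chrA, mh$startB[i], mh$startB[i] + w) != m)
      msg <- c(msg, sprintf("motif %s absent from a planned placement", m))
  }
  ## junction-side 8 bp motif ends exactly at the 3' boundary, second copy
  ## 21 bp downstream of the 5' boundary
  j <- which(nchar(mh$motif) == max(nchar(mh$motif)))[1]
  if (mh$startB[j] + nchar(mh$motif[j]) != u3)
    msg <- c(msg, "junction motif must abut the 3' unit boundary")
  if (length(msg)) msg else TRUE
})

#' ScenarioSpec: a declared rearrangement of the parent genome
#'
#' Describes the sample genome as a derivation from the parent reference:
#' tandem copy number of the amplifiable unit on each homolog, mean episome
#' count per cell (real-valued, a population average), per-chromosome copy
#' numbers (aneuploidy), and a multiplicative copy factor for the rDNA proxy
#' region. \code{copiesPerAllele = c(1, 1)} with no episomes, all-disomic
#' chromosomes and \code{rdnaFactor = 1} reproduces the parent genome exactly.
#'
#' @slot copiesPerAllele integer(2), tandem unit copies on each homolog
#'   (0 = deletion allele).
#' @slot episomeCount numeric(1), mean circular episomes per cell.
#' @slot aneuploidy named numeric of chromosome copy counts (default 2 for
#'   chromosomes not listed).
#' @slot rdnaFactor numeric(1), copy factor for the rDNA proxy region.
#' @slot seed integer, default seed for read simulation from this scenario.
#'
#' @seealso [ScenarioSpec()], [applyScenario()], [scenarioPreset()]
#' @export
setClass("ScenarioSpec",
  representation(
    copiesPerAllele = "integer",
    episomeCount = "numeric",
    aneuploidy = "numeric",
    rdnaFactor = "numeric",
    seed = "integer"
  )
)

setValidity("ScenarioSpec", function(object) {
  msg <- character()
  if (length(object@copiesPerAllele) != 2L || any(object@copiesPerAllele < 0L))
    msg <- c(msg, "copiesPerAllele must be two non-negative integers")
  if (object@episomeCount < 0) msg <- c(msg, "episomeCount must be >= 0")
  if (object@rdnaFactor < 0) msg <- c(msg, "rdnaFactor must be >= 0")
  if (length(msg)) msg else TRUE
})

#' GenomeBuild: a realized sample genome with its coordinate map
#'
#' The molecules of a sample genome derived from a \linkS4class{LocusModel}
#' by a \linkS4class{ScenarioSpec}: one molecule per homolog of the locus
#' chromosome, one weighted molecule per remaining chromosome, and optionally
#' a circular episome of exactly one unit length. The coordinate map is a
#' total piecewise mapping from sample-molecule positions back to the parent
#' reference, which the read simulator uses to emit truth alignments
#' (including exact soft-clips for junction-spanning reads).
#'
#' @slot model the \linkS4class{LocusModel} the build derives from.
#' @slot scenario the \linkS4class{ScenarioSpec} applied.
#' @slot seqs \link[Biostrings]{DNAStringSet} of sample molecules.
#' @slot circular logical, per molecule.
#' @slot weights numeric copy weight per molecule (episomes may be
#'   fractional: a population mean).
#' @slot regionWeights list of per-molecule data.frames (start, end, weight)
#'   for sub-molecule depth scaling (the rDNA proxy).
#' @slot coordMap data.frame (molecule, start, end, chrom, parentStart,
#'   strand) of mapping blocks, 0-based half-open.
#'
#' @seealso [applyScenario()], [simulateReads()]
#' @export
setClass("GenomeBuild",
  representation(
    model = "LocusModel",
    scenario = "ScenarioSpec",
    seqs = "DNAStringSet",
    circular = "logical",
    weights = "numeric",
    regionWeights = "list",
    coordMap = "data.frame"
  )
)

setValidity("GenomeBuild", function(object) {
  msg <- character()
  n <- length(object@seqs)
  if (length(object@circular) != n || length(object@weights) != n)
    msg <- c(msg, "circular/weights must match the number of molecules")
  ## coordinate map must be total: blocks tile every molecule
  cm <- object@coordMap
  for (i in seq_len(n)) {
    nm <- names(object@seqs)[i]
    b <- cm[cm$molecule == nm, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    len <- Biostrings::width(object@seqs)[i]
    ok <- nrow(b) > 0L && b$start[1] == 0L && b$end[nrow(b)] == len &&
      (nrow(b) == 1L || all(b$start[-1] == b$end[-nrow(b)]))
    if (!ok) msg <- c(msg, sprintf("coordinate map does not tile %s", nm))
  }
  if (length(msg)) msg else TRUE
})

#' DepthTrack: per-window mean per-base depth
#'
#' Windowed coverage for one sample over the parent reference grid. Each
#' aligned (non-clipped) base of every alignment contributes 1 to the window
#' containing it; the window value is summed bases divided by the true window
#' width (partial terminal windows use their actual width).
#'
#' @slot windows data.frame (chrom, start, end, depth), 0-based half-open.
#' @slot windowSize integer target window size in bp.
#' @slot totalBases numeric, total aligned bases (library size used for
#'   between-sample normalization).
#'
#' @seealso [computeDepthTrack()]
#' @export
setClass("DepthTrack",
  representation(windows = "data.frame", windowSize = "integer",
                 totalBases = "numeric")
)

#' LogRatioTrack: two-sample log2 depth ratio with smoothing
#'
#' Per-window log2(sample/reference) after library-size scaling and median
#' re-centring, plus a centred moving-average smoothed series and mask flags
#' for windows with insufficient reference depth.
#'
#' @slot windows data.frame (chrom, start, end, log2, smoothed, masked).
#' @slot windowSize integer window size in bp.
#' @slot span numeric smoothing span in bp (NA before smoothing).
#' @slot pseudocount numeric depth pseudocount used in the ratio.
#'
#' @seealso [log2Ratio()], [smoothTrack()], [callSegments()]
#' @export
setClass("LogRatioTrack",
  representation(windows = "data.frame", windowSize = "integer",
                 span = "numeric", pseudocount = "numeric")
)

#' JunctionCall: a reconstructed amplicon junction
#'
#' The two breakpoints of a circular-or-tandem junction on the parent
#' reference, under the leftmost-shift convention when microhomology makes
#' the exact coordinate ambiguous. The implied unit length equals the
#' circular molecule length for an episome and the repeat period for a
#' tandem array; the topology itself is not decided here (identical
#' junctions arise from both), only by [classifyTopology()].
#'
#' @slot chrom chromosome of both breakpoints.
#' @slot leftBp,rightBp 0-based breakpoints (5' and 3' unit boundaries).
#' @slot ambiguitySpan bp over which the breakpoint pair can slide.
#' @slot consensus reconstructed read-through sequence across the junction
#'   (right-breakpoint flank followed by left-breakpoint flank).
#' @slot supportLeft,supportRight clipped-read support on each side.
#' @slot microhomology data.frame of [findMicrohomology()] hits (may be
#'   empty until annotated).
#' @slot topologyHint always \code{"circular-or-tandem"}.
#'
#' @seealso [crossMatch()], [inferUnitLength()]
#' @export
setClass("JunctionCall",
  representation(
    chrom = "character", leftBp = "integer", rightBp = "integer",
    ambiguitySpan = "integer", consensus = "character",
    supportLeft = "integer", supportRight = "integer",
    microhomology = "data.frame", topologyHint = "character"
  )
)

setValidity("JunctionCall", function(object) {
  if (object@rightBp <= object@leftBp) "unit length must be positive" else TRUE
})

#' PcrPrediction: products of an in-silico PCR
#'
#' @slot primerSet name of the primer set.
#' @slot template template molecule id.
#' @slot topology "linear" or "circular".
#' @slot products data.frame (start, end, size, wrapped); on circular
#'   templates a product may wrap the origin exactly once.
#' @slot extensionCap maximum product size (bp) permitted by the emulated
#'   extension time.
#' @slot primersFound logical, FALSE when a primer has no site on the
#'   template (an empty prediction, flagged rather than an error).
#' @seealso [insilicoPcr()]
#' @export
setClass("PcrPrediction",
  representation(primerSet = "character", template = "character",
                 topology = "character", products = "data.frame",
                 extensionCap = "numeric", primersFound = "logical")
)

#' DigestPrediction: fragments and Southern bands of an in-silico digest
#'
#' @slot enzyme enzyme name.
#' @slot template template molecule id.
#' @slot topology "linear" or "circular".
#' @slot fragments data.frame (start, end, size, plus one probe-hit count
#'   column per probe).
#' @slot bands data.frame (sizeKb, intensity, probes): copy-weighted counts
#'   of probe-bearing fragments grouped by display size (0.1 kb, truncated
#'   as read off a gel).
#' @slot copyWeight weight applied to this template's fragments.
#' @slot uncutCircle TRUE for a zero-cut circular template (not band-forming).
#' @seealso [insilicoDigest()], [intensityRatio()]
#' @export
setClass("DigestPrediction",
  representation(enzyme = "character", template = "character",
                 topology = "character", fragments = "data.frame",
                 bands = "data.frame", copyWeight = "numeric",
                 uncutCircle = "logical")
)

#' TopologyCall: inferred locus topology with its evidence
#'
#' @slot verdict one of single_copy, deleted, episomal_circle,
#'   tandem_one_allele, tandem_both_alleles, circle_plus_single_copy,
#'   inconsistent.
#' @slot evidence named list of the assay observations used.
#' @slot copiesPerAllele estimated tandem copies per amplified allele from
#'   the coverage fold (NA when coverage evidence was not supplied).
#' @slot copiesFromIntensity estimate from the single-cutter band intensity
#'   ratio (NA when unavailable).
#' @slot agreement TRUE when both copy estimates are available and equal.
#' @slot notes character vector, e.g. the clash list for an inconsistent
#'   verdict.
#' @seealso [classifyTopology()]
#' @export
setClass("TopologyCall",
  representation(verdict = "character", evidence = "list",
                 copiesPerAllele = "numeric", copiesFromIntensity = "numeric",
                 agreement = "logical", notes = "character")
)
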