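#' @include AllClasses.R
NULL

#' Length of the amplifiable unit
#'
#' For a \linkS4class{LocusModel}, the length of the modeled unit interval;
#' for a \linkS4class{JunctionCall}, the implied repeat-unit / circle length
#' \code{rightBp - leftBp} under the leftmost-shift convention.
#'
#' @param x a LocusModel or JunctionCall.
#' @return integer length in bp.
#' @examples
#' model <- buildLocusModel(chromLength = 40000, unitLength = 3000,
#'                          boundaryFragment = 2000, hindToEnd = 1200,
#'                          outsideFragment = 5000, p3Product = 4500,
#'                          auxChromLength = 0, rdnaChromLength = 0)
#' unitLength(model)
#' @export
setGeneric("unitLength", function(x) standardGeneric("unitLength"))

#' @rdname unitLength
#' @export
setMethod("unitLength", "LocusModel", function(x) x@unitEnd - x@unitStart)

#' @rdname unitLength
#' @export
setMethod("unitLength", "JunctionCall", function(x) {
  if (x@rightBp == x@leftBp)
    stop("degenerate junction: left and right breakpoints coincide")
  x@rightBp - x@leftBp
})

#' Parent reference sequences of a model or build
#' @param x a LocusModel or GenomeBuild.
#' @return a \link[Biostrings]{DNAStringSet}.
#' @export
setGeneric("parentSeqs", function(x) standardGeneric("parentSeqs"))

#' @rdname parentSeqs
#' @export
setMethod("parentSeqs", "LocusModel", function(x) x@parentSeqs)

#' @rdname parentSeqs
#' @export
setMethod("parentSeqs", "GenomeBuild", function(x) x@model@parentSeqs)

#' Unit interval as a GRanges (1-based, closed)
#' @param x a LocusModel.
#' @return a length-1 \link[GenomicRanges]{GRanges}.
#' @export
setGeneric("unitRange", function(x) standardGeneric("unitRange"))

#' @rdname unitRange
#' @export
setMethod("unitRange", "LocusModel", function(x) {
  GenomicRanges::GRanges(x@unitChrom,
                         IRanges::IRanges(x@unitStart + 1L, x@unitEnd))
})

#' Feature annotations as a GRanges (1-based, closed)
#' @param x a LocusModel.
#' @return a named \link[GenomicRanges]{GRanges}.
#' @export
setGeneric("featureRanges", function(x) standardGeneric("featureRanges"))

#' @rdname featureRanges
#' @export
setMethod("featureRanges", "LocusModel", function(x) {
  f <- x@features
  gr <- GenomicRanges::GRanges(f$chrom, IRanges::IRanges(f$start + 1L, f$end))
  names(gr) <- f$name
  gr
})

#' Enzyme cut coordinates (0-based) on the parent reference
#' @param x a LocusModel.
#' @param enzyme enzyme name, e.g. \code{"hindIII-like"}.
#' @return integer vector of cut coordinates.
#' @export
setGeneric("cutSites", function(x, enzyme) standardGeneric("cutSites"))

#' @rdname cutSites
#' @export
setMethod("cutSites", "LocusModel", function(x, enzyme) {
  e <- x@enzymeSites[[enzyme]]
  if (is.null(e)) stop("unknown enzyme: ", enzyme)
  sort(e$sites + e$cutOffset)
})

#' Primer oligo sequences for a primer set
#'
#' Forward primer is the plus-strand site sequence; reverse primer is the
#' reverse complement of its plus-strand site.
#' @param x a LocusModel.
#' @param set primer-set name ("P1", "P2", "P3").
#' @return named character vector with elements \code{fwd} and \code{rev}.
#' @export
setGeneric("primerPair", function(x, set) standardGeneric("primerPair"))

#' @rdname primerPair
#' @export
setMethod("primerPair", "LocusModel", function(x, set) {
  p <- x@primerSites[x@primerSites$set == set, , drop = FALSE]
  if (nrow(p) != 2L) stop("unknown primer set: ", set)
  chrA <- x@parentSeqs[[x@unitChrom]]
  fwd <- p[p$role == "fwd", ]; rev <- p[p$role == "rev", ]
  c(fwd = .as_chr0(chrA, fwd$start, fwd$end),
    rev = .revcomp(.as_chr0(chrA, rev$start, rev$end)))
})

#' Sample molecules of a genome build
#' @param x a GenomeBuild.
#' @return a \link[Biostrings]{DNAStringSet} of molecules.
#' @export
setGeneric("molecules", function(x) standardGeneric("molecules"))

#' @rdname molecules
#' @export
setMethod("molecules", "GenomeBuild", function(x) x@seqs)

#' Windowed values of a track as a data.frame
#' @param x a DepthTrack or LogRatioTrack.
#' @return data.frame of windows (0-based half-open coordinates).
#' @export
setGeneric("trackWindows", function(x) standardGeneric("trackWindows"))

#' @rdname trackWindows
#' @export
setMethod("trackWindows", "DepthTrack", function(x) x@windows)

#' @rdname trackWindows
#' @export
setMethod("trackWindows", "LogRatioTrack", function(x) x@windows)

## ---- show methods ----------------------------------------------------------

setMethod("show", "LocusModel", function(object) {
  cat("LocusModel on", length(object@parentSeqs), "parent chromosome(s)\n")
  cat(sprintf("  unit: %s:%d-%d (%d bp, 1-based shown)\n", object@unitChrom,
              object@unitStart + 1L, object@unitEnd, unitLength(object)))
  cat("  features:", paste(object@features$name, collapse = ", "), "\n")
  cat("  enzymes:", paste(names(object@enzymeSites), collapse = ", "), "\n")
  cat("  primer sets:", paste(unique(object@primerSites$set), collapse = ", "),
      "\n")
  cat("  microhomologies:",
      paste(object@microhomologyPlan$motif, collapse = ", "), "\n")
})

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf(
    "ScenarioSpec: copies/allele (%d,%d), episomes %.2f, rdnaFactor %.2f\n",
    object@copiesPerAllele[1], object@copiesPerAllele[2],
    object@episomeCount, object@rdnaFactor))
  an <- object@aneuploidy[object@aneuploidy != 2]
  if (length(an))
    cat("  aneuploidy:",
        paste(sprintf("%s=%g", names(an), an), collapse = ", "), "\n")
})

setMethod("show", "GenomeBuild", function(object) {
  w <- Biostrings::width(object@seqs)
  cat("GenomeBuild with", length(object@seqs), "molecule(s)\n")
  for (i in seq_along(object@seqs))
    cat(sprintf("  %s: %d bp, weight %.2f%s\n", names(object@seqs)[i], w[i],
                object@weights[i],
                if (object@circular[i]) ", circular" else ""))
})

setMethod("show", "DepthTrack", function(object) {
  cat(sprintf("DepthTrack: %d windows of %d bp, %.3g aligned bases\n",
              nrow(object@windows), object@windowSize, object@totalBases))
})

setMethod("show", "LogRatioTrack", function(object) {
  sm <- if (all(is.na(object@windows$smoothed))) "raw only"
        else sprintf("smoothed at %g bp", object@span)
  cat(sprintf("LogRatioTrack: %d windows of %d bp (%s), %d masked\n",
              nrow(object@windows), object@windowSize, sm,
              sum(object@windows$masked)))
})

setMethod("show", "JunctionCall", function(object) {
  cat(sprintf(
    "JunctionCall %s:%d|%d (unit %d bp, ambiguity %d bp, support %d+%d)\n",
    object@chrom, object@leftBp, object@rightBp, unitLength(object),
    object@ambiguitySpan, object@supportLeft, object@supportRight))
  if (nrow(object@microhomology))
    cat("  microhomology:",
        paste(sprintf("%s(%s)", object@microhomology$motif,
                      object@microhomology$class), collapse = ", "), "\n")
})

setMethod("show", "PcrPrediction", function(object) {
  cat(sprintf("PcrPrediction %s on %s (%s, cap %g bp): ", object@primerSet,
              object@template, object@topology, object@extensionCap))
  if (!object@primersFound) cat("primer(s) absent from template\n")
  else if (!nrow(object@products)) cat("no product\n")
  else cat(paste(sprintf("%.1f kb", .displayKb(object@products$size)),
                 collapse = ", "), "\n")
})

setMethod("show", "DigestPrediction", function(object) {
  cat(sprintf("DigestPrediction %s on %s (%s): ", object@enzyme,
              object@template, object@topology))
  if (object@uncutCircle) cat("uncut circle (not band-forming)\n")
  else cat(nrow(object@fragments), "fragment(s),",
           nrow(object@bands), "probe-bearing band size(s)\n")
})

setMethod("show", "TopologyCall", function(object) {
  cat("TopologyCall:", object@verdict, "\n")
  if (!is.na(object@copiesPerAllele))
    cat(sprintf("  copies/allele: %g (coverage), %g (band intensity)%s\n",
                object@copiesPerAllele, object@copiesFromIntensity,
                if (isTRUE(object@agreement)) " [agree]" else ""))
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "),
                                "\n")
})
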