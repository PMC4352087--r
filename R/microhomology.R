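#' @include AllGenerics.R
NULL

## All maximal exact common substrings of length >= minLen between two
## character strings, as 0-based (startA, startB, len) triples. A hit is a
## maximal run along one alignment diagonal; containment across diagonals is
## handled by the caller.
.commonSubstrings <- function(A, B, minLen = 5L) {
  a <- strsplit(A, "")[[1]]; b <- strsplit(B, "")[[1]]
  m <- length(a); n <- length(b)
  out <- list()
  if (m >= minLen && n >= minLen) {
    for (d in seq(-(m - 1L), n - 1L)) {
      i0 <- max(0L, -d); j0 <- i0 + d                  # 0-based diagonal start
      len <- min(m - i0, n - j0)
      if (len < minLen) next
      eq <- a[i0 + seq_len(len)] == b[j0 + seq_len(len)]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values & r$lengths >= minLen
      if (any(keep))
        out[[length(out) + 1L]] <- data.frame(
          startA = i0 + starts[keep], startB = j0 + starts[keep],
          len = r$lengths[keep])
    }
  }
  if (!length(out))
    return(data.frame(startA = integer(), startB = integer(),
                      len = integer()))
  do.call(rbind, out)
}

#' Find microhomologies at and around a junction's breakpoints
#'
#' Enumerates all maximal exact common substrings of at least \code{minLen}
#' bases between the windows \code{[leftBp - searchRadius, leftBp +
#' searchRadius)} and \code{[rightBp - searchRadius, rightBp +
#' searchRadius)} on the reference. Microhomologies of roughly 5-25 bp are
#' the signature of microhomology-mediated break-induced replication
#' (MMBIR), the mechanism suspected to excise the amplifiable unit as a
#' circle; the defaults cover that range.
#'
#' Hits are classified \code{"junctional"} when one occurrence abuts a
#' breakpoint (motif start or end exactly at the breakpoint coordinate) and
#' \code{"flanking"} otherwise, and are sorted junctional-first, then by
#' decreasing length. Hits contained in a longer reported hit at both
#' placements are suppressed as redundant sub-motifs. Matching is exact:
#' the motifs this analysis reports are verbatim repeats, and any
#' mismatch-tolerant scoring would be an unstated extra assumption.
#'
#' @param reference the reference chromosome sequence
#'   (\link[Biostrings]{DNAString} or character scalar).
#' @param leftBp,rightBp 0-based breakpoint coordinates (the 5' and 3' unit
#'   boundaries of a junction call).
#' @param searchRadius half-width of the window scanned around each
#'   breakpoint (bp); must be at least \code{minLen}.
#' @param minLen minimum microhomology length to report.
#' @return data.frame with columns \code{motif}, \code{length},
#'   \code{offsetA} (motif start relative to \code{leftBp}), \code{offsetB}
#'   (relative to \code{rightBp}) and \code{class}; zero rows when the
#'   windows share no substring of \code{minLen} bases.
#' @examples
#' ref <- paste0(strrep("ACGT", 30), "GGAAAGGG", strrep("TTCA", 30))
#' ## trivially shares the planted motif around positions 120 and 120
#' @export
findMicrohomology <- function(reference, leftBp, rightBp, searchRadius = 30L,
                              minLen = 5L) {
  if (searchRadius < minLen)
    stop("searchRadius must be at least minLen")
  if (is(reference, "DNAString")) reference <- as.character(reference)
  stopifnot(is.character(reference), length(reference) == 1L)
  L <- nchar(reference)
  clamp <- function(lo, hi) {
    if (lo < 0L || hi > L) {
      warning("search window truncated at reference bounds")
      c(max(0L, lo), min(L, hi))
    } else c(lo, hi)
  }
  wa <- clamp(leftBp - searchRadius, leftBp + searchRadius)
  wb <- clamp(rightBp - searchRadius, rightBp + searchRadius)
  A <- substr(reference, wa[1] + 1L, wa[2])
  B <- substr(reference, wb[1] + 1L, wb[2])

  hits <- .commonSubstrings(A, B, minLen = minLen)
  if (!nrow(hits))
    return(data.frame(motif = character(), length = integer(),
                      offsetA = integer(), offsetB = integer(),
                      class = character()))
  gA <- wa[1] + hits$startA; gB <- wb[1] + hits$startB
  ## suppress sub-motifs contained in a longer hit at both placements
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    contained <- hits$len > hits$len[i] &
      gA <= gA[i] & gA + hits$len >= gA[i] + hits$len[i] &
      gB <= gB[i] & gB + hits$len >= gB[i] + hits$len[i]
    if (any(contained)) keep[i] <- FALSE
  }
  hits <- hits[keep, , drop = FALSE]; gA <- gA[keep]; gB <- gB[keep]

  abuts <- (gA == leftBp | gA + hits$len == leftBp) |
    (gB == rightBp | gB + hits$len == rightBp)
  out <- data.frame(
    motif = substring(A, hits$startA + 1L, hits$startA + hits$len),
    length = hits$len,
    offsetA = gA - leftBp,
    offsetB = gB - rightBp,
    class = ifelse(abuts, "junctional", "flanking"),
    stringsAsFactors = FALSE)
  out <- out[order(out$class != "junctional", -out$length, out$offsetA), ]
  rownames(out) <- NULL
  out
}

#' Annotate a junction call with its breakpoint microhomologies
#'
#' Convenience wrapper running [findMicrohomology()] on the reference
#' chromosome of a \linkS4class{JunctionCall} and storing the hits in the
#' call.
#'
#' @param call a \linkS4class{JunctionCall}.
#' @param model the \linkS4class{LocusModel} providing the parent reference.
#' @param ... passed to [findMicrohomology()].
#' @return the call with its \code{microhomology} slot filled.
#' @export
annotateJunction <- function(call, model, ...) {
  ref <- as.character(parentSeqs(model)[[call@chrom]])
  call@microhomology <- findMicrohomology(ref, call@leftBp, call@rightBp, ...)
  call
}
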