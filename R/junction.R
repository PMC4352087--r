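#' @include coverage.R
NULL

#' Collect soft-clipped reads from an alignment stream
#'
#' Returns the reads carrying a terminal soft-clip of at least
#' \code{minClip} bases -- the split-read evidence of a breakpoint. The clip
#' coordinate is the reference position of the junction: for a trailing
#' clip it is the position after the last aligned base (the clipped tail
#' continues to the \code{"right"} of it), for a leading clip the position
#' of the first aligned base (tail to the \code{"left"}). Fully matched
#' reads are excluded. A read clipped at both ends contributes two entries.
#'
#' @param alignments alignment data.frame with M/S-only CIGARs.
#' @param minClip minimum clip length to keep (default 10).
#' @return data.frame (qname, chrom, coord, side, clipLen, seq) with the
#'   clipped substring in reference orientation.
#' @export
collectClipped <- function(alignments, minClip = 10L) {
  stopifnot(minClip >= 1L)
  cg <- alignments$cigar
  leadS <- suppressWarnings(as.integer(sub("^([0-9]+)S.*$", "\\1", cg)))
  leadS[!grepl("^[0-9]+S", cg)] <- 0L
  trailS <- suppressWarnings(as.integer(sub("^.*[M]([0-9]+)S$", "\\1", cg)))
  trailS[!grepl("M[0-9]+S$", cg)] <- 0L
  m <- .cigarM(cg)
  out <- list()
  iL <- which(leadS >= minClip)
  if (length(iL))
    out$left <- data.frame(
      qname = alignments$qname[iL], chrom = alignments$chrom[iL],
      coord = alignments$pos[iL], side = "left",
      clipLen = leadS[iL],
      seq = substr(alignments$seq[iL], 1L, leadS[iL]),
      stringsAsFactors = FALSE)
  iR <- which(trailS >= minClip)
  if (length(iR))
    out$right <- data.frame(
      qname = alignments$qname[iR], chrom = alignments$chrom[iR],
      coord = alignments$pos[iR] + m[iR], side = "right",
      clipLen = trailS[iR],
      seq = substr(alignments$seq[iR], leadS[iR] + m[iR] + 1L,
                   leadS[iR] + m[iR] + trailS[iR]),
      stringsAsFactors = FALSE)
  if (!length(out))
    return(data.frame(qname = character(), chrom = character(),
                      coord = integer(), side = character(),
                      clipLen = integer(), seq = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## majority-vote consensus of clipped tails; "right" tails are anchored at
## their first base (junction side), "left" tails at their last base
.clipConsensus <- function(seqs, side) {
  if (side == "left")
    seqs <- vapply(lapply(strsplit(seqs, ""), rev), paste, "", collapse = "")
  lens <- nchar(seqs)
  L <- as.integer(median(lens))
  cons <- character(L)
  mat <- strsplit(seqs, "")
  for (p in seq_len(L)) {
    col <- vapply(mat[lens >= p], `[[`, "", p)
    tab <- sort(table(col), decreasing = TRUE)
    cons[p] <- names(tab)[1]
  }
  s <- paste(cons, collapse = "")
  if (side == "left")
    s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  s
}

#' Cluster soft-clip evidence into breakpoints
#'
#' Single-linkage clustering of clipped reads on (chromosome, clip side,
#' coordinate) with link distance \code{tol}; clusters supported by fewer
#' than \code{minSupport} reads are dropped. The cluster coordinate is the
#' member median; the consensus clipped sequence is a per-position majority
#' vote over the member tails, anchored at the junction side.
#'
#' @param clips output of [collectClipped()].
#' @param tol maximum coordinate gap linking two clips (default 5).
#' @param minSupport minimum supporting reads per cluster (default 3).
#' @return data.frame (chrom, coord, side, support, meanClipLen, consensus).
#' @export
clusterBreakpoints <- function(clips, tol = 5L, minSupport = 3L) {
  empty <- data.frame(chrom = character(), coord = integer(),
                      side = character(), support = integer(),
                      meanClipLen = numeric(), consensus = character())
  if (!nrow(clips)) return(empty)
  out <- list()
  for (key in unique(paste(clips$chrom, clips$side))) {
    sel <- clips[paste(clips$chrom, clips$side) == key, , drop = FALSE]
    sel <- sel[order(sel$coord), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(diff(sel$coord) > tol)))
    for (g in unique(grp)) {
      mem <- sel[grp == g, , drop = FALSE]
      if (nrow(mem) < minSupport) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = mem$chrom[1],
        coord = as.integer(round(median(mem$coord))),
        side = mem$side[1],
        support = nrow(mem),
        meanClipLen = mean(mem$clipLen),
        consensus = .clipConsensus(mem$seq, mem$side[1]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$chrom, res$coord), , drop = FALSE]
}

## prefix/suffix comparison allowing `perBase` mismatches per 20 bases
.tailMatches <- function(tail, refSeq, minClip, mismatchPer20 = 1L) {
  len <- min(nchar(tail), nchar(refSeq))
  if (len < minClip) return(FALSE)
  mm <- .nMismatch(substr(tail, 1L, len), substr(refSeq, 1L, len))
  mm <= (len %/% 20L) * mismatchPer20
}

#' Cross-match breakpoint clusters into junction calls
#'
#' For each ordered pair of a right-side (3') and a left-side (5') cluster
#' on the same chromosome, tests whether the clipped tails of each cluster
#' read into the reference sequence at the other breakpoint: the trailing
#' tail at the 3' breakpoint must match the reference starting at the 5'
#' breakpoint, and the leading tail at the 5' breakpoint must match the
#' reference ending at the 3' breakpoint. This is the "partially unmatched
#' sequence matches the opposite end" signature of a circular or tandem
#' junction. Matching is exact up to one mismatch per 20 bases and is
#' evaluated from both sides, so the call is identical whichever cluster is
#' considered first.
#'
#' Successful pairs become \linkS4class{JunctionCall}s with
#' leftmost-shifted breakpoints (when homology makes the pair slidable, the
#' slide range is recorded as the ambiguity span) and a reconstructed
#' junction consensus (3'-flank followed by 5'-flank). Clusters whose tails
#' match no candidate are reported as unresolved breakpoints.
#'
#' @param clusters output of [clusterBreakpoints()] (at least two).
#' @param reference parent reference (\link[Biostrings]{DNAStringSet} or
#'   \linkS4class{LocusModel}).
#' @param minClip minimum matched bases required (default 10).
#' @param flank flank length kept in the junction consensus (default 40).
#' @return list with \code{calls} (list of \linkS4class{JunctionCall}) and
#'   \code{unresolved} (data.frame of unmatched clusters).
#' @export
crossMatch <- function(clusters, reference, minClip = 10L, flank = 40L) {
  if (is(reference, "LocusModel")) reference <- parentSeqs(reference)
  calls <- list()
  used <- rep(FALSE, nrow(clusters))
  right <- which(clusters$side == "right")
  left <- which(clusters$side == "left")
  for (ir in right) for (il in left) {
    if (clusters$chrom[ir] != clusters$chrom[il]) next
    cr <- clusters$coord[ir]; cl <- clusters$coord[il]
    if (cr <= cl) next
    ref <- reference[[clusters$chrom[ir]]]
    L <- length(ref)
    tailR <- clusters$consensus[ir]   # continues at the 5' breakpoint
    tailL <- clusters$consensus[il]   # ends at the 3' breakpoint
    lenR <- min(nchar(tailR), L - cl)
    okR <- .tailMatches(tailR, .as_chr0(ref, cl, cl + lenR), minClip)
    lenL <- min(nchar(tailL), cr)
    refL <- .as_chr0(ref, cr - lenL, cr)
    tl <- substr(tailL, nchar(tailL) - lenL + 1L, nchar(tailL))
    mmL <- if (lenL >= minClip) .nMismatch(tl, refL) else Inf
    okL <- mmL <= (lenL %/% 20L)
    if (!okR || !okL) next
    ## leftmost shift within any breakpoint-straddling homology
    shiftL <- 0L
    while (cl - shiftL - 1L >= 0L &&
           .as_chr0(ref, cl - shiftL - 1L, cl - shiftL) ==
           .as_chr0(ref, cr - shiftL - 1L, cr - shiftL))
      shiftL <- shiftL + 1L
    shiftR <- 0L
    while (cr + shiftR < L &&
           .as_chr0(ref, cl + shiftR, cl + shiftR + 1L) ==
           .as_chr0(ref, cr + shiftR, cr + shiftR + 1L))
      shiftR <- shiftR + 1L
    cl2 <- cl - shiftL; cr2 <- cr - shiftL
    cons <- paste0(.as_chr0(ref, max(0L, cr2 - flank), cr2),
                   .as_chr0(ref, cl2, min(L, cl2 + flank)))
    calls[[length(calls) + 1L]] <- new("JunctionCall",
      chrom = clusters$chrom[ir], leftBp = as.integer(cl2),
      rightBp = as.integer(cr2),
      ambiguitySpan = shiftL + shiftR,
      consensus = cons,
      supportLeft = as.integer(clusters$support[il]),
      supportRight = as.integer(clusters$support[ir]),
      microhomology = data.frame(),
      topologyHint = "circular-or-tandem")
    used[c(ir, il)] <- TRUE
  }
  list(calls = calls, unresolved = clusters[!used, , drop = FALSE])
}

#' Repeat-unit length implied by a junction call
#'
#' \code{rightBp - leftBp} under the leftmost-shift convention: the length
#' of the circular molecule for an episome and the repeat period for a
#' tandem array (identical by construction -- the junction cannot tell the
#' two apart).
#'
#' @param call a \linkS4class{JunctionCall}.
#' @return integer bp.
#' @export
inferUnitLength <- function(call) unitLength(call)
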