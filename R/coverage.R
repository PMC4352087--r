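#' @include AllGenerics.R
NULL

## parse the aligned (M) span out of M/S-only CIGAR strings
.cigarM <- function(cigar) {
  as.integer(sub("^(?:[0-9]+S)?([0-9]+)M.*$", "\\1", cigar))
}

#' Compute a windowed depth track from alignments
#'
#' Every aligned (non-clipped) base of every record contributes 1 to the
#' window containing it; soft-clipped tails do not count. Window values are
#' summed bases divided by the true window width, so a partial terminal
#' window is normalized by its actual size and a read spanning two windows
#' splits its contribution proportionally.
#'
#' @param alignments alignment data.frame ([simulateReads()] or
#'   [readSamLike()]).
#' @param model a \linkS4class{LocusModel}, or a named integer vector of
#'   chromosome lengths.
#' @param window window size in bp (default 500, the averaging window used
#'   for CNV scanning).
#' @return a \linkS4class{DepthTrack} over all chromosomes.
#' @export
computeDepthTrack <- function(alignments, model, window = 500L) {
  stopifnot(window >= 1L)
  seqlens <- if (is(model, "LocusModel"))
    setNames(Biostrings::width(parentSeqs(model)), names(parentSeqs(model)))
  else model
  if (nrow(alignments) == 0L)
    warning("empty alignment stream: depth track is all zero")
  mlen <- if (nrow(alignments)) .cigarM(alignments$cigar) else integer()
  gr <- GenomicRanges::GRanges(
    factor(alignments$chrom, levels = names(seqlens)),
    IRanges::IRanges(alignments$pos + 1L, width = mlen),
    seqlengths = seqlens)
  cov <- GenomicRanges::coverage(gr)
  out <- lapply(names(seqlens), function(chrom) {
    len <- seqlens[[chrom]]
    starts <- seq.int(0L, len - 1L, by = window)
    ends <- pmin(starts + window, len)
    v <- IRanges::Views(cov[[chrom]], start = starts + 1L, end = ends)
    data.frame(chrom = chrom, start = starts, end = ends,
               depth = IRanges::viewMeans(v), stringsAsFactors = FALSE)
  })
  new("DepthTrack", windows = do.call(rbind, out),
      windowSize = as.integer(window), totalBases = sum(as.numeric(mlen)))
}

#' Two-sample log2 depth ratio
#'
#' Computes per-window \code{log2(sample/reference)} after two
#' normalizations: (i) both tracks are scaled to the same library size
#' (total aligned bases -- robust to read-length differences between
#' libraries), and (ii) the genome-wide median log2 ratio of unmasked
#' windows is re-centred to zero, which anchors the ratio on copy-neutral
#' background so that a k-fold copy change reads as log2(k) even when the
#' amplification itself is a visible fraction of the library. Windows with
#' reference depth below \code{minRefDepth} are masked: log ratios explode
#' at near-zero denominators.
#'
#' @param sample,reference \linkS4class{DepthTrack}s on identical window
#'   grids.
#' @param pseudocount depth pseudocount added to both terms (default 0.1).
#' @param minRefDepth masking floor on reference depth (default 5).
#' @return a \linkS4class{LogRatioTrack} (raw only; see [smoothTrack()]).
#' @export
log2Ratio <- function(sample, reference, pseudocount = 0.1, minRefDepth = 5) {
  ws <- sample@windows; wr <- reference@windows
  if (nrow(ws) != nrow(wr) ||
      !all(ws$chrom == wr$chrom & ws$start == wr$start & ws$end == wr$end) ||
      sample@windowSize != reference@windowSize)
    stop("sample and reference tracks are on different window grids")
  ## scale the sample onto the reference library size; the constant offset
  ## this leaves in the log ratio is absorbed by the re-centring below, and
  ## rescaling all sample depths by any constant is then an exact no-op
  s <- ws$depth * reference@totalBases / sample@totalBases
  r <- wr$depth
  masked <- r < minRefDepth
  log2r <- log2((s + pseudocount) / (r + pseudocount))
  ## re-centre on the copy-neutral mode: start from the global median and
  ## refine it as the median of windows within +/-0.3 log2 units, which
  ## converges onto the neutral peak even when aneuploid or amplified
  ## windows are a sizeable, one-sided fraction of the genome
  centre <- median(log2r[!masked])
  for (it in 1:3)
    centre <- median(log2r[!masked & abs(log2r - centre) <= 0.3])
  log2r <- log2r - centre
  new("LogRatioTrack",
      windows = data.frame(chrom = ws$chrom, start = ws$start, end = ws$end,
                           log2 = log2r, smoothed = NA_real_,
                           masked = masked, stringsAsFactors = FALSE),
      windowSize = sample@windowSize, span = NA_real_,
      pseudocount = pseudocount)
}

#' Moving-average smoothing of a log-ratio track
#'
#' Centred moving average over \code{span / windowSize} windows, computed
#' per chromosome. Edge windows use the truncated overlap with the
#' chromosome; masked windows are excluded from the means (and stay masked).
#'
#' @param track a \linkS4class{LogRatioTrack}.
#' @param span smoothing span in bp (default 10000); must be at least the
#'   window size.
#' @return the track with its \code{smoothed} series filled.
#' @export
smoothTrack <- function(track, span = 10000) {
  if (span < track@windowSize)
    stop("span must be at least the window size")
  k <- max(1L, as.integer(round(span / track@windowSize)))
  left <- (k - 1L) %/% 2L; right <- k - 1L - left
  w <- track@windows
  for (chrom in unique(w$chrom)) {
    i <- which(w$chrom == chrom)
    x <- w$log2[i]; ok <- !w$masked[i]
    n <- length(x)
    cx <- cumsum(c(0, ifelse(ok, x, 0)))
    cn <- cumsum(c(0, as.numeric(ok)))
    lo <- pmax(seq_len(n) - left, 1L); hi <- pmin(seq_len(n) + right, n)
    cnt <- cn[hi + 1L] - cn[lo]
    sm <- ifelse(cnt > 0, (cx[hi + 1L] - cx[lo]) / cnt, NA_real_)
    w$smoothed[i] <- sm
  }
  track@windows <- w
  track@span <- as.numeric(span)
  track
}

#' Call copy-number segments from a smoothed log-ratio track
#'
#' Segments are maximal runs of at least \code{minWindows} consecutive
#' unmasked windows whose smoothed |log2 ratio| exceeds \code{threshold}
#' with a consistent sign. The fold estimate is \code{2^mean} over the raw
#' 500 bp windows inside the run after trimming sub-threshold edge windows:
#' the smoother is wider (10 kb) than a short amplicon (7.5 kb), so the
#' smoothed mean systematically dilutes short events, while the raw windows
#' inside the event carry the undiluted ratio (this is how a fold is read
#' off the zoomed locus plot). Both the smoothed mean and the raw-core mean
#' are reported.
#'
#' @param track a smoothed \linkS4class{LogRatioTrack}.
#' @param threshold calling threshold in log2 units (default 0.4).
#' @param minWindows minimum run length in windows (default 5).
#' @return a \link[GenomicRanges]{GRanges} (1-based) with metadata columns
#'   \code{meanSmoothed}, \code{meanRaw}, \code{fold} (2^meanRaw),
#'   \code{foldRounded} (nearest-integer copy ratio), \code{direction} and
#'   \code{nWindows}; zero-length when no run qualifies.
#' @export
callSegments <- function(track, threshold = 0.4, minWindows = 5L) {
  if (is.na(track@span))
    stop("smooth the track first (see smoothTrack)")
  w <- track@windows
  segs <- list()
  for (chrom in unique(w$chrom)) {
    i <- which(w$chrom == chrom)
    sm <- w$smoothed[i]
    state <- ifelse(w$masked[i] | is.na(sm) | abs(sm) < threshold, 0L,
                    ifelse(sm > 0, 1L, -1L))
    r <- rle(state)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values != 0L & r$lengths >= minWindows)) {
      idx <- i[starts[j]:ends[j]]
      raw <- w$log2[idx]
      ## direction-consistent core: raw windows exceeding the threshold on
      ## the segment's own side (an opposite-sign noise dip is not signal)
      core <- idx[r$values[j] * raw >= threshold & !w$masked[idx]]
      if (!length(core)) core <- idx
      meanRaw <- mean(w$log2[core])
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chrom, start = w$start[idx[1]], end = w$end[idx[length(idx)]],
        meanSmoothed = mean(w$smoothed[idx]), meanRaw = meanRaw,
        fold = 2^meanRaw, foldRounded = round(2^meanRaw),
        direction = if (r$values[j] > 0) "gain" else "loss",
        nWindows = length(idx), stringsAsFactors = FALSE)
    }
  }
  if (!length(segs))
    return(GenomicRanges::GRanges())
  d <- do.call(rbind, segs)
  GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end),
                         meanSmoothed = d$meanSmoothed, meanRaw = d$meanRaw,
                         fold = d$fold, foldRounded = d$foldRounded,
                         direction = d$direction, nWindows = d$nWindows)
}

#' Median smoothed ratio over a region
#'
#' The median of the smoothed log2 ratio over the windows overlapping
#' \code{[start, end)} of \code{chrom}, returned on the linear ratio scale
#' (\code{2^median}). This is the robust per-region copy-ratio summary used
#' for whole-chromosome (aneuploidy) and repeat-region comparisons.
#'
#' @param track a smoothed \linkS4class{LogRatioTrack}.
#' @param chrom chromosome.
#' @param start,end 0-based half-open region; defaults to the whole
#'   chromosome.
#' @return numeric ratio (1 = copy-neutral).
#' @export
regionRatio <- function(track, chrom, start = 0L, end = Inf) {
  w <- track@windows
  sel <- w$chrom == chrom & w$end > start & w$start < end & !w$masked
  2^median(w$smoothed[sel], na.rm = TRUE)
}

#' Plot a log-ratio track for one chromosome
#'
#' Raw per-window values as grey points with the moving-average trend as a
#' red line, the standard visualization of two-sample CNV scans.
#'
#' @param track a smoothed \linkS4class{LogRatioTrack}.
#' @param chrom chromosome to plot.
#' @param ylim y-axis limits.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted data.frame.
#' @importFrom graphics lines points
#' @export
plotLogRatio <- function(track, chrom, ylim = c(-2, 4), ...) {
  w <- track@windows[track@windows$chrom == chrom, ]
  mid <- (w$start + w$end) / 2
  plot(mid[!w$masked], w$log2[!w$masked], pch = 16, cex = 0.3,
       col = "grey60", xlab = paste(chrom, "position (bp)"),
       ylab = "log2 depth ratio", ylim = ylim, ...)
  lines(mid, w$smoothed, col = "red", lwd = 2)
  invisible(w)
}
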