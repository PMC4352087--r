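#' @include scenario.R
NULL

## Map a molecule interval [a, a+width) (0-based, already wrap-reduced so
## that a < len) to parent-reference pieces through the molecule's coordinate
## blocks. Returns data.frame(chrom, parentStart, len) in read order.
.mapInterval <- function(blocks, molLen, circular, a, width) {
  pieces <- list()
  remaining <- width
  pos <- a
  while (remaining > 0L) {
    if (pos >= molLen) {
      if (!circular) stop("interval runs off a linear molecule")
      pos <- pos - molLen
    }
    bi <- findInterval(pos, blocks$start)
    take <- min(remaining, blocks$end[bi] - pos)
    pieces[[length(pieces) + 1L]] <- data.frame(
      chrom = blocks$chrom[bi],
      parentStart = blocks$parentStart[bi] + (pos - blocks$start[bi]),
      len = take, stringsAsFactors = FALSE)
    pos <- pos + take
    remaining <- remaining - take
  }
  p <- do.call(rbind, pieces)
  ## coalesce pieces that are contiguous on the parent (block boundaries of
  ## the map are not necessarily junctions)
  if (nrow(p) > 1L) {
    keep <- c(TRUE, !(p$chrom[-1] == p$chrom[-nrow(p)] &
                      p$parentStart[-1] ==
                        p$parentStart[-nrow(p)] + p$len[-nrow(p)]))
    grp <- cumsum(keep)
    p <- data.frame(
      chrom = p$chrom[keep],
      parentStart = p$parentStart[keep],
      len = as.integer(tapply(p$len, grp, sum)),
      stringsAsFactors = FALSE)
  }
  p
}

## CIGAR and anchor position for a read whose parent mapping has >1 piece:
## the longest piece is the aligned (M) block, everything before/after is a
## terminal soft-clip. Ties anchor on the leftmost piece (deterministic).
.clipAlignment <- function(pieces) {
  k <- which.max(pieces$len)
  lead <- if (k > 1L) sum(pieces$len[seq_len(k - 1L)]) else 0L
  trail <- sum(pieces$len) - lead - pieces$len[k]
  cigar <- paste0(if (lead) paste0(lead, "S") else "",
                  pieces$len[k], "M",
                  if (trail) paste0(trail, "S") else "")
  list(chrom = pieces$chrom[k], pos = pieces$parentStart[k], cigar = cigar)
}

## Sample n fragment start positions on [0, lim) honoring piecewise region
## weights (weight 1 outside declared regions).
.sampleStarts <- function(n, lim, regions) {
  if (n == 0L) return(integer())
  if (!nrow(regions)) return(as.integer(floor(runif(n, 0, lim))))
  bnd <- sort(unique(c(0, pmin(regions$start, lim), pmin(regions$end, lim),
                       lim)))
  segLen <- diff(bnd)
  segW <- rep(1, length(segLen))
  mid <- bnd[-length(bnd)] + segLen / 2
  for (i in seq_len(nrow(regions)))
    segW[mid >= regions$start[i] & mid < regions$end[i]] <- regions$weight[i]
  mass <- segLen * segW
  seg <- sample.int(length(mass), n, replace = TRUE, prob = mass)
  as.integer(floor(bnd[seg] + runif(n) * segLen[seg]))
}

## Inject uniform substitution errors into a fixed-width DNAStringSet.
.injectErrors <- function(dss, errRate) {
  if (errRate <= 0 || !length(dss)) return(dss)
  w <- Biostrings::width(dss)[1]
  total <- length(dss) * w
  nErr <- rpois(1L, total * errRate)
  if (nErr == 0L) return(dss)
  nErr <- min(nErr, total)
  at <- sort(sample.int(total, nErr))
  big <- unlist(dss)
  orig <- strsplit(as.character(Biostrings::extractAt(
    big, IRanges::IRanges(at, width = 1L))), "")
  orig <- unlist(orig)
  bases <- c("A", "C", "G", "T")
  idx <- match(orig, bases)
  idx[is.na(idx)] <- 1L                      # ambiguity codes: overwrite
  shift <- sample.int(3L, nErr, replace = TRUE)
  newLetter <- bases[((idx - 1L + shift) %% 4L) + 1L]
  big <- Biostrings::replaceLetterAt(big, at, paste(newLetter, collapse = ""))
  out <- Biostrings::DNAStringSet(
    Biostrings::Views(big, start = seq(1L, total, by = w), width = w))
  names(out) <- names(dss)
  out
}

#' Simulate paired-end reads with truth alignments
#'
#' Samples read pairs from every molecule of a \linkS4class{GenomeBuild},
#' weighted by molecule copy number (and by region weights for the rDNA
#' proxy), and emits for each read its truth alignment against the
#' \emph{parent} reference derived through the build's coordinate map.
#' Reads crossing a junction (circle origin or tandem join) are aligned on
#' their longest parent-contiguous piece, with the remainder soft-clipped at
#' the junction coordinate -- exactly what a read aligner produces at an
#' amplicon breakpoint. Fragment length is Gaussian; errors are uniform
#' substitutions (no indels), which keeps truth CIGARs exact while still
#' exercising mismatch tolerance downstream.
#'
#' Per-molecule pair counts are Poisson with mean
#' \code{depth * weight/2 * length / (2 * readLen)}, so a locus present at
#' copy number 2 is covered at \code{depth}. Identical inputs and seed give
#' byte-identical output.
#'
#' @param build a \linkS4class{GenomeBuild}.
#' @param depth target fold-coverage of a copy-number-2 locus (default 44).
#' @param readLen read length in bp (default 90).
#' @param fragMean,fragSd fragment length mean and sd (default 500 / 50,
#'   a 500 bp paired-end library).
#' @param errRate per-base substitution rate (default 0.002).
#' @param seed integer seed; defaults to the scenario's seed.
#' @param sample sample label recorded in the alignments.
#' @return a list with elements \code{alignments} (data.frame with one row
#'   per read: qname, sample, molecule, chrom, pos (0-based), strand, cigar,
#'   seq in alignment orientation, mate fields), \code{reads1} and
#'   \code{reads2} (\link[Biostrings]{DNAStringSet} in sequencing
#'   orientation), \code{readLen} and \code{sample}.
#' @seealso [writeSimFastq()], [writeSimSam()], [computeDepthTrack()]
#' @export
simulateReads <- function(build, depth = 44, readLen = 90L, fragMean = 500,
                          fragSd = 50, errRate = 0.002,
                          seed = build@scenario@seed, sample = "sample") {
  stopifnot(is(build, "GenomeBuild"), depth > 0, fragMean >= readLen)
  .withSeed(seed, {
    molNames <- names(build@seqs)
    lens <- Biostrings::width(build@seqs)
    out <- vector("list", length(molNames))
    r1all <- r2all <- vector("list", length(molNames))

    for (i in seq_along(molNames)) {
      mol <- molNames[i]; len <- lens[i]
      circular <- build@circular[i]; w <- build@weights[i]
      if (readLen > len)
        stop("read length exceeds molecule ", mol)
      ## effective length under region weights: a down-weighted region must
      ## reduce the molecule's read total, not redistribute it
      rg <- build@regionWeights[[mol]]
      effLen <- len
      if (nrow(rg))
        effLen <- len + sum((pmin(rg$end, len) - pmax(rg$start, 0L)) *
                              (rg$weight - 1))
      lambda <- depth * (w / 2) * effLen / (2 * readLen)
      n <- rpois(1L, lambda)
      if (n == 0L) next
      fragLen <- as.integer(pmax(readLen, round(rnorm(n, fragMean, fragSd))))
      if (!circular && any(fragLen > len))
        stop("linear molecule ", mol, " is shorter than a sampled fragment; ",
             "fragments wrap only on circular molecules")
      if (circular) fragLen <- pmin(fragLen, len)
      starts <- .sampleStarts(n, len, build@regionWeights[[mol]])
      if (!circular) starts <- pmin(starts, len - fragLen)

      ## read intervals on the molecule (0-based), wrap-reduced
      a1 <- starts
      a2 <- (starts + fragLen - readLen) %% len

      ext <- if (circular) Biostrings::xscat(build@seqs[[i]], build@seqs[[i]])
             else build@seqs[[i]]
      fwd1 <- Biostrings::extractAt(ext,
        IRanges::IRanges(a1 + 1L, width = readLen))
      fwd2 <- Biostrings::extractAt(ext,
        IRanges::IRanges(a2 + 1L, width = readLen))
      fwd1 <- .injectErrors(fwd1, errRate)
      fwd2 <- .injectErrors(fwd2, errRate)

      blocks <- build@coordMap[build@coordMap$molecule == mol, , drop = FALSE]
      blocks <- blocks[order(blocks$start), , drop = FALSE]

      mapReads <- function(a) {
        ## vectorized single-block mapping; junction/wrap crossers by loop
        chrom <- character(n); pos <- integer(n); cigar <- character(n)
        endPos <- a + readLen
        bi <- findInterval(a, blocks$start)
        simple <- endPos <= blocks$end[bi]
        chrom[simple] <- blocks$chrom[bi[simple]]
        pos[simple] <- blocks$parentStart[bi[simple]] +
          (a[simple] - blocks$start[bi[simple]])
        cigar[simple] <- paste0(readLen, "M")
        for (j in which(!simple)) {
          p <- .mapInterval(blocks, len, circular, a[j], readLen)
          if (nrow(p) == 1L) {
            chrom[j] <- p$chrom; pos[j] <- p$parentStart
            cigar[j] <- paste0(readLen, "M")
          } else {
            al <- .clipAlignment(p)
            chrom[j] <- al$chrom; pos[j] <- al$pos; cigar[j] <- al$cigar
          }
        }
        list(chrom = chrom, pos = pos, cigar = cigar)
      }
      m1 <- mapReads(a1); m2 <- mapReads(a2)

      qname <- sprintf("%s_%s_%07d", sample, mol, seq_len(n))
      out[[i]] <- data.frame(
        qname = rep(qname, 2L),
        sample = sample,
        molecule = mol,
        chrom = c(m1$chrom, m2$chrom),
        pos = c(m1$pos, m2$pos),
        strand = rep(c("+", "-"), each = n),
        cigar = c(m1$cigar, m2$cigar),
        seq = c(as.character(fwd1), as.character(fwd2)),
        mateChrom = c(m2$chrom, m1$chrom),
        matePos = c(m2$pos, m1$pos),
        mateStrand = rep(c("-", "+"), each = n),
        mate = rep(1:2, each = n),
        stringsAsFactors = FALSE)
      names(fwd1) <- names(fwd2) <- qname
      r1all[[i]] <- fwd1
      r2all[[i]] <- Biostrings::reverseComplement(fwd2)
    }
    aln <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
    if (is.null(aln))
      aln <- data.frame(qname = character(), sample = character(),
                        molecule = character(), chrom = character(),
                        pos = integer(), strand = character(),
                        cigar = character(), seq = character(),
                        mateChrom = character(), matePos = integer(),
                        mateStrand = character(), mate = integer())
    keep <- !vapply(r1all, is.null, TRUE)
    list(alignments = aln,
         reads1 = do.call(c, r1all[keep]),
         reads2 = do.call(c, r2all[keep]),
         readLen = as.integer(readLen), sample = sample)
  })
}
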